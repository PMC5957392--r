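#' Stage-2 trait-interaction model
#'
#' Regresses the stage-1 coefficient estimates of one landscape metric (one
#' value per invader trait combination) on the four invasiveness traits with
#' a Bayesian linear model: normal likelihood, vague normal priors
#' (precision 0.001) on the intercept and the four trait coefficients, and a
#' uniform prior on the residual scale. Trait columns are centered and
#' scaled before fitting so coefficient magnitudes are comparable across
#' traits with different raw scales. A trait's effect is flagged significant
#' when its 95% equal-tailed credible interval excludes 0.
#'
#' @param data A data frame with one row per trait combination.
#' @param response Name of the column holding the stage-1 coefficient
#'   estimates (default `"beta_hat"`).
#' @param traits Names of the four trait columns.
#' @param control An [mcmc_control()].
#' @param seed Optional seed.
#' @return An object of class `interaction_fit`; use [tidy()] for the
#'   coefficient table.
#' @export
#' @examples
#' grid <- build_trait_grid()[1:40, ]
#' grid$beta_hat <- rnorm(40)
#' fit <- fit_interaction_model(grid, seed = 1)
#' tidy(fit)
fit_interaction_model <- function(data, response = "beta_hat",
                                  traits = c(
                                    "dispersal_mult", "growth_mult",
                                    "establishment_freq", "corridor_usage"
                                  ),
                                  control = mcmc_control(), seed = NULL) {
  if (!response %in% names(data)) {
    stop(sprintf("column '%s' not found", response), call. = FALSE)
  }
  if (!all(traits %in% names(data))) {
    stop("trait columns missing from `data`", call. = FALSE)
  }
  y <- data[[response]]
  Z <- as.matrix(data[, traits])
  if (nrow(Z) != length(y)) {
    stop("trait matrix and coefficient vector lengths disagree",
      call. = FALSE
    )
  }
  if (nrow(Z) < 8) {
    stop("at least 8 trait combinations are required", call. = FALSE)
  }
  if (nrow(Z) < 30) {
    rlang::inform(
      sprintf("fitting the interaction model on only %d rows", nrow(Z)),
      .frequency = "once", .frequency_id = "invadescape_small_stage2"
    )
  }
  sdz <- suppressWarnings(standardize(Z))
  if (length(sdz$dropped)) {
    rlang::inform(
      paste(
        "constant trait column(s) reported with zero effect:",
        paste(sdz$dropped, collapse = ", ")
      ),
      .frequency = "once", .frequency_id = "invadescape_const_traits"
    )
  }
  X <- cbind(`(Intercept)` = 1, sdz$train)

  run <- function() {
    gibbs_vague_lm_cpp(
      X, y,
      coef_prec = 0.001, n_iter = control$iter, burnin = control$burnin,
      n_chains = control$chains, sigma_lo = 0.001, sigma_hi = 30
    )
  }
  chains <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  terms <- c(colnames(X), "sigma")
  chains <- lapply(chains, function(m) {
    colnames(m) <- terms
    m
  })
  draws <- do.call(rbind, chains)
  est <- colMeans(draws)
  ci <- apply(draws, 2, quantile, probs = c(0.025, 0.975))
  rhat <- gelman_rubin(chains)

  # constant (dropped) traits are reported as exact zero effects so the
  # output schema always covers all four traits
  all_terms <- c("(Intercept)", traits, "sigma")
  expand <- function(v, fill) {
    out <- setNames(rep(fill, length(all_terms)), all_terms)
    out[names(v)] <- v
    out
  }
  structure(
    list(
      chains = chains, terms = all_terms,
      estimate = expand(est, 0),
      conf.low = expand(ci[1, ], 0), conf.high = expand(ci[2, ], 0),
      rhat = expand(rhat, NA_real_),
      dropped = sdz$dropped, n = nrow(Z), control = control
    ),
    class = "interaction_fit"
  )
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf(
    "<interaction_fit> n = %d combinations, max Rhat %.3f\n",
    x$n, max(x$rhat, na.rm = TRUE)
  ))
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_interaction_model
#' @param x An `interaction_fit`.
#' @param ... Unused.
#' @export
tidy.interaction_fit <- function(x, ...) {
  tibble::tibble(
    term = x$terms,
    estimate = unname(x$estimate),
    conf.low = unname(x$conf.low),
    conf.high = unname(x$conf.high),
    rhat = unname(x$rhat),
    significant = unname(x$conf.low > 0 | x$conf.high < 0)
  )
}

#' @rdname fit_interaction_model
#' @export
glance.interaction_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    max_rhat = max(x$rhat, na.rm = TRUE),
    converged = all(x$rhat < 1.1, na.rm = TRUE)
  )
}

#' Relative importance of landscape metrics
#'
#' Scales a vector of coefficient estimates relative to the strongest
#' predictor: `|beta| / max |beta|`, with the sign reported separately. The
#' strongest predictor maps to exactly 1; an all-zero vector maps to all
#' zeros and is flagged.
#'
#' @param data Data frame with one row per metric.
#' @param estimate Column holding coefficient estimates.
#' @param metric Column holding metric names.
#' @return A tibble with `metric`, `estimate`, `relative_importance`, and
#'   `sign` (`"+"`, `"-"`, or `"0"`); attribute `all_zero` is `TRUE` when the
#'   input had no nonzero entry.
#' @export
#' @examples
#' relative_importance(
#'   tibble::tibble(metric = c("a", "b", "c"), estimate = c(2, -1, 0))
#' )
relative_importance <- function(data, estimate = "estimate",
                                metric = "metric") {
  b <- data[[estimate]]
  mx <- max(abs(b))
  all_zero <- mx == 0
  if (all_zero) {
    warning("all coefficients are zero; relative importances set to 0",
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    metric = data[[metric]],
    estimate = b,
    relative_importance = if (all_zero) rep(0, length(b)) else abs(b) / mx,
    sign = dplyr::case_when(b > 0 ~ "+", b < 0 ~ "-", TRUE ~ "0")
  )
  attr(out, "all_zero") <- all_zero
  out
}

#' Long table of trait-by-metric interaction effects
#'
#' Collects stage-2 fits into one long table: one row per (response metric,
#' trait, landscape metric) with the trait coefficient's posterior mean, 95%
#' credible interval, and significance flag. Rows are ordered by response,
#' then registry position of the landscape metric, then trait. Missing fits
#' are reported, not silently dropped.
#'
#' @param fits A tibble with columns `response`, `metric`, and `fit` (a
#'   list-column of `interaction_fit` objects, `NULL` where a stage-1 fit was
#'   unavailable).
#' @return A tibble with columns `response`, `metric`, `position`, `trait`,
#'   `estimate`, `conf.low`, `conf.high`, `significant`.
#' @export
interaction_table <- function(fits) {
  stopifnot(all(c("response", "metric", "fit") %in% names(fits)))
  missing <- fits[vapply(fits$fit, is.null, logical(1)), ]
  if (nrow(missing) > 0) {
    warning(
      sprintf(
        "%d (response, metric) fits missing: %s",
        nrow(missing),
        paste(utils::head(
          paste(missing$response, missing$metric, sep = "/"), 5
        ), collapse = ", ")
      ),
      call. = FALSE
    )
    fits <- fits[!vapply(fits$fit, is.null, logical(1)), ]
  }
  reg <- metric_registry()[, c("name", "position")]
  out <- purrr::pmap_dfr(fits, function(response, metric, fit, ...) {
    td <- tidy(fit)
    td <- td[!td$term %in% c("(Intercept)", "sigma"), ]
    tibble::tibble(
      response = response, metric = metric, trait = td$term,
      estimate = td$estimate, conf.low = td$conf.low,
      conf.high = td$conf.high, significant = td$significant
    )
  })
  out <- dplyr::left_join(out, reg, by = c(metric = "name"))
  dplyr::arrange(
    out[, c(
      "response", "metric", "position", "trait", "estimate", "conf.low",
      "conf.high", "significant"
    )],
    .data$response, .data$position, .data$trait
  )
}
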