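#' MCMC control settings
#'
#' @param chains Number of chains (default 3).
#' @param iter Total iterations per chain including burn-in.
#' @param burnin Burn-in iterations discarded per chain.
#' @param preset `"reduced"` (3 chains, 2,000 iterations after a 1,000
#'   burn-in; the package default used by tests and desk-scale runs) or
#'   `"paper"` (3 chains, 10,000 iterations after a 5,000 burn-in, the
#'   full-scale setting). Explicit `chains`/`iter`/`burnin` override the
#'   preset.
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = NULL, iter = NULL, burnin = NULL,
                         preset = c("reduced", "paper")) {
  preset <- match.arg(preset)
  base <- if (preset == "paper") {
    list(chains = 3L, iter = 15000L, burnin = 5000L)
  } else {
    list(chains = 3L, iter = 3000L, burnin = 1000L)
  }
  out <- list(
    chains = as.integer(chains %||% base$chains),
    iter = as.integer(iter %||% base$iter),
    burnin = as.integer(burnin %||% base$burnin)
  )
  stopifnot(out$chains >= 1, out$iter > out$burnin, out$burnin >= 0)
  structure(out, class = "mcmc_control")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Center and scale a design matrix by training moments
#'
#' Training columns are centered to mean 0 and scaled to unit standard
#' deviation; validation columns are transformed with the *training* moments.
#' Constant training columns cannot be standardized: they are dropped with a
#' warning and recorded.
#'
#' @param x_train Numeric matrix or data frame of training predictors.
#' @param x_val Optional validation predictors with the same columns.
#' @return A list of class `standardized_design`: `train`, `val`, `center`,
#'   `scale`, `dropped` (names of dropped constant columns).
#' @export
standardize <- function(x_train, x_val = NULL) {
  x_train <- as.matrix(x_train)
  if (!is.null(x_val)) x_val <- as.matrix(x_val)
  ctr <- colMeans(x_train)
  scl <- apply(x_train, 2, sd)
  const <- !is.finite(scl) | scl < 1e-12
  if (all(const)) {
    stop("all predictor columns are constant; nothing to standardize",
      call. = FALSE
    )
  }
  dropped <- colnames(x_train)[const]
  if (length(dropped)) {
    warning(
      "dropping constant predictor column(s): ",
      paste(dropped, collapse = ", "),
      call. = FALSE
    )
  }
  keep <- !const
  z_train <- sweep(
    sweep(x_train[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/"
  )
  z_val <- NULL
  if (!is.null(x_val)) {
    z_val <- sweep(
      sweep(x_val[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/"
    )
  }
  structure(
    list(
      train = z_train, val = z_val,
      center = ctr[keep], scale = scl[keep], dropped = dropped
    ),
    class = "standardized_design"
  )
}

#' Build a train/holdout regression design
#'
#' Pairs one response vector with a predictor matrix, splits the rows into a
#' training and a holdout (validation) part, and standardizes the predictors
#' by the training moments. The full-scale design uses a 900/100 split; the
#' default holds out 10% of rows.
#'
#' @param x Predictor matrix or data frame (rows = landscapes).
#' @param y Numeric response vector, one value per row of `x`.
#' @param holdout_frac Fraction of rows held out for validation.
#' @param holdout_ids Optional explicit row indices to hold out (overrides
#'   `holdout_frac`); lets one split be shared across many designs.
#' @param seed Seed for the random split.
#' @return A list of class `lasso_design` with standardized `x_train`,
#'   `x_val`, responses, the holdout indices, and the dropped-column record.
#' @export
lasso_design <- function(x, y, holdout_frac = 0.1, holdout_ids = NULL,
                         seed = 1) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(nrow(x) == length(y), !anyNA(x), !anyNA(y))
  n <- nrow(x)
  if (is.null(holdout_ids)) {
    n_val <- max(1L, round(holdout_frac * n))
    if (n_val >= n) stop("holdout uses all rows", call. = FALSE)
    holdout_ids <- withr::with_seed(seed, sort(sample.int(n, n_val)))
  }
  train_ids <- setdiff(seq_len(n), holdout_ids)
  sdz <- standardize(x[train_ids, , drop = FALSE],
    x_val = x[holdout_ids, , drop = FALSE]
  )
  structure(
    list(
      x_train = sdz$train, y_train = y[train_ids],
      x_val = sdz$val, y_val = y[holdout_ids],
      train_ids = train_ids, holdout_ids = holdout_ids,
      center = sdz$center, scale = sdz$scale, dropped = sdz$dropped,
      all_terms = colnames(x)
    ),
    class = "lasso_design"
  )
}

#' Fit the Bayesian lasso at one shrinkage rate
#'
#' Linear regression of the response on standardized predictors with
#' independent Laplace(0, rate `tau`) priors on the slopes, a vague normal
#' prior on the intercept (precision 0.01), and a uniform prior on the
#' residual scale over (0.001, 30). Sampled by a Gibbs sampler using the
#' exponential scale-mixture representation of the Laplace prior. Convergence
#' is checked with the Gelman-Rubin statistic; if any parameter exceeds 1.1
#' the fit is retried once with doubled iterations and flagged if it still
#' fails.
#'
#' @param design A [lasso_design()] (or a plain matrix given together with
#'   `y`).
#' @param tau Positive Laplace rate (larger = stronger shrinkage).
#' @param y Response vector when `design` is a plain matrix.
#' @param control An [mcmc_control()].
#' @param seed Optional seed.
#' @return An object of class `bayes_lasso`: posterior draws per chain,
#'   coefficient summary (use [tidy()]), convergence diagnostics, and the
#'   design.
#' @export
fit_lasso <- function(design, tau, y = NULL, control = mcmc_control(),
                      seed = NULL) {
  if (is.matrix(design) || is.data.frame(design)) {
    stopifnot(!is.null(y))
    xm <- as.matrix(design)
    if (is.null(colnames(xm))) {
      colnames(xm) <- paste0("x", seq_len(ncol(xm)))
    }
    design <- list(
      x_train = xm, y_train = y, x_val = NULL, y_val = NULL,
      dropped = character(0), all_terms = colnames(xm)
    )
  }
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0) {
    stop("`tau` must be a positive shrinkage rate", call. = FALSE)
  }
  x <- design$x_train
  yy <- design$y_train
  if (nrow(x) <= 50) {
    rlang::inform(
      sprintf("fitting with only %d training rows", nrow(x)),
      .frequency = "once", .frequency_id = "invadescape_small_n"
    )
  }
  sample_once <- function(ctl) {
    gibbs_blasso_cpp(
      x, yy, tau,
      n_iter = ctl$iter, burnin = ctl$burnin, n_chains = ctl$chains,
      beta0_prec = 0.01, sigma_lo = 0.001, sigma_hi = 30
    )
  }
  run <- function() {
    chains <- sample_once(control)
    rhat <- gelman_rubin(chains)
    retried <- FALSE
    if (any(rhat > 1.1, na.rm = TRUE) && control$chains > 1) {
      retried <- TRUE
      ctl2 <- control
      ctl2$iter <- 2L * control$iter
      ctl2$burnin <- 2L * control$burnin
      chains <- sample_once(ctl2)
      rhat <- gelman_rubin(chains)
    }
    list(chains = chains, rhat = rhat, retried = retried)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  terms <- c("(Intercept)", colnames(x), "sigma")
  chains <- lapply(res$chains, function(m) {
    colnames(m) <- terms
    m
  })
  draws <- do.call(rbind, chains)
  est <- colMeans(draws)
  ci <- apply(draws, 2, quantile, probs = c(0.025, 0.975))
  structure(
    list(
      chains = chains, tau = tau, terms = terms,
      estimate = est, conf.low = ci[1, ], conf.high = ci[2, ],
      rhat = setNames(res$rhat, terms),
      converged = all(res$rhat < 1.1, na.rm = TRUE),
      retried = res$retried,
      design = design, control = control
    ),
    class = "bayes_lasso"
  )
}

#' @export
print.bayes_lasso <- function(x, ...) {
  cat(sprintf(
    "<bayes_lasso> tau = %.4g, %d chains x %d kept draws, max Rhat %.3f\n",
    x$tau, length(x$chains), nrow(x$chains[[1]]), max(x$rhat, na.rm = TRUE)
  ))
  invisible(x)
}

#' @rdname fit_lasso
#' @param x A `bayes_lasso` fit.
#' @param ... Unused.
#' @export
tidy.bayes_lasso <- function(x, ...) {
  tibble::tibble(
    term = x$terms,
    estimate = unname(x$estimate),
    conf.low = unname(x$conf.low),
    conf.high = unname(x$conf.high),
    rhat = unname(x$rhat),
    excludes_zero = unname(x$conf.low > 0 | x$conf.high < 0)
  )
}

#' @rdname fit_lasso
#' @export
glance.bayes_lasso <- function(x, ...) {
  tibble::tibble(
    tau = x$tau,
    n_train = nrow(x$design$x_train),
    p = ncol(x$design$x_train),
    max_rhat = max(x$rhat, na.rm = TRUE),
    converged = x$converged,
    sum_abs_beta = sum(abs(
      x$estimate[!x$terms %in% c("(Intercept)", "sigma")]
    ))
  )
}

#' Out-of-sample log predictive density
#'
#' The model-selection score: the sum over held-out points of the log of the
#' posterior-predictive density, estimated by averaging the normal likelihood
#' over retained posterior draws (pooled across chains).
#'
#' @param fit A `bayes_lasso` fit.
#' @param x_val,y_val Held-out predictors (already on the standardized scale)
#'   and responses; defaults to the design's holdout part.
#' @return A single numeric score (larger is better).
#' @export
oos_log_predictive_density <- function(fit, x_val = NULL, y_val = NULL) {
  stopifnot(inherits(fit, "bayes_lasso"))
  x_val <- x_val %||% fit$design$x_val
  y_val <- y_val %||% fit$design$y_val
  if (is.null(x_val) || is.null(y_val) || length(y_val) == 0) {
    stop("no validation data available", call. = FALSE)
  }
  x_val <- as.matrix(x_val)
  draws <- do.call(rbind, fit$chains)
  if (nrow(draws) < 100) {
    warning("fewer than 100 retained draws; score is noisy", call. = FALSE)
  }
  p <- ncol(x_val)
  beta0 <- draws[, 1]
  beta <- draws[, 1 + seq_len(p), drop = FALSE]
  sigma <- draws[, ncol(draws)]
  preds <- tcrossprod(x_val, beta) # n_val x n_draws
  preds <- sweep(preds, 2, beta0, "+")
  score <- 0
  for (i in seq_len(length(y_val))) {
    ld <- dnorm(y_val[i], preds[i, ], sigma, log = TRUE)
    mx <- max(ld)
    score <- score + mx + log(mean(exp(ld - mx)))
  }
  score
}

#' Default shrinkage-rate grid
#'
#' 24 log-spaced Laplace rates spanning 0.1 to 2000 — from near-zero
#' shrinkage to essentially-null slopes.
#'
#' @param n Number of grid values (default 24).
#' @param lower,upper Grid range.
#' @return A strictly increasing numeric vector.
#' @export
tau_grid_default <- function(n = 24, lower = 0.1, upper = 2000) {
  exp(seq(log(lower), log(upper), length.out = n))
}

#' Select the shrinkage rate by held-out predictive score
#'
#' Fits the Bayesian lasso at each rate in the grid, scores every fit by
#' [oos_log_predictive_density()] on the shared holdout, and selects the rate
#' with the highest score (ties broken toward stronger shrinkage). The score
#' curve is classified as `"interior"` when the maximum is away from both
#' grid ends, else `"lower"`/`"upper"` boundary.
#'
#' @param design A [lasso_design()] with a non-empty holdout part.
#' @param taus Shrinkage grid (default [tau_grid_default()]).
#' @param control An [mcmc_control()].
#' @param seed Optional seed; per-rate fits use `seed + index`.
#' @return An object of class `tau_selection`: `curve` (tibble of `tau`,
#'   `score`, `sum_abs_beta`, `max_rhat`), `tau_star`, `boundary`, and `fit`
#'   (the `bayes_lasso` at `tau_star`).
#' @export
select_tau <- function(design, taus = tau_grid_default(),
                       control = mcmc_control(), seed = NULL) {
  stopifnot(inherits(design, "lasso_design"), length(taus) >= 1)
  if (is.unsorted(taus, strictly = TRUE)) {
    stop("`taus` must be strictly increasing", call. = FALSE)
  }
  fits <- vector("list", length(taus))
  rows <- vector("list", length(taus))
  for (i in seq_along(taus)) {
    fit <- fit_lasso(design, taus[i],
      control = control,
      seed = if (is.null(seed)) NULL else seed + i
    )
    fits[[i]] <- fit
    rows[[i]] <- tibble::tibble(
      tau = taus[i],
      score = oos_log_predictive_density(fit),
      sum_abs_beta = glance(fit)$sum_abs_beta,
      max_rhat = max(fit$rhat, na.rm = TRUE)
    )
  }
  curve <- dplyr::bind_rows(rows)
  best <- max(which(curve$score >= max(curve$score) - 1e-12))
  boundary <- if (length(taus) == 1) {
    "single"
  } else if (best == 1) {
    "lower"
  } else if (best == length(taus)) {
    "upper"
  } else {
    "interior"
  }
  structure(
    list(
      curve = curve, tau_star = taus[best], boundary = boundary,
      fit = fits[[best]]
    ),
    class = "tau_selection"
  )
}

#' @export
print.tau_selection <- function(x, ...) {
  cat(sprintf(
    "<tau_selection> tau* = %.4g (%s maximum) over %d rates\n",
    x$tau_star, x$boundary, nrow(x$curve)
  ))
  invisible(x)
}

#' @rdname select_tau
#' @param x A `tau_selection`.
#' @param ... Unused.
#' @export
tidy.tau_selection <- function(x, ...) x$curve

#' Plot a shrinkage-selection score curve
#'
#' Held-out log predictive density against the Laplace shrinkage rate, with
#' the selected rate marked.
#'
#' @param object A `tau_selection`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tau_selection <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$tau, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(
      xintercept = object$tau_star, linetype = "dashed", colour = "red"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Laplace shrinkage rate (log scale)",
      y = "Held-out log predictive density",
      title = sprintf(
        "Selected rate %.3g (%s maximum)", object$tau_star, object$boundary
      )
    )
}

#' Gelman-Rubin convergence statistic
#'
#' The potential scale reduction factor per parameter: `sqrt(var+ / W)` with
#' `var+ = (n-1)/n W + B/n`, where `W` is the mean within-chain variance and
#' `B/n` the between-chain variance of means. Values near 1 indicate
#' convergence.
#'
#' @param chains A list (one element per chain) of draw matrices with common
#'   columns, or of numeric vectors for a single parameter.
#' @return Named numeric vector of R-hat values (one per column).
#' @export
gelman_rubin <- function(chains) {
  if (length(chains) < 2) {
    stop("at least two chains are required", call. = FALSE)
  }
  if (is.null(dim(chains[[1]]))) {
    chains <- lapply(chains, function(v) matrix(v, ncol = 1))
  }
  n <- nrow(chains[[1]])
  if (n < 10) stop("at least 10 draws per chain are required", call. = FALSE)
  p <- ncol(chains[[1]])
  out <- numeric(p)
  for (j in seq_len(p)) {
    draws <- vapply(chains, function(m) m[, j], numeric(n))
    W <- mean(apply(draws, 2, var))
    B_over_n <- var(colMeans(draws))
    if (W < 1e-300) {
      out[j] <- if (B_over_n < 1e-300) 1 else Inf
    } else {
      out[j] <- sqrt((n - 1) / n + B_over_n / W)
    }
  }
  names(out) <- colnames(chains[[1]])
  out
}
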