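# shared small sparse design used by several blocks
make_sparse_design <- function(n, p, k = 3, sd_noise = 0.3, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("m", seq_len(p))
    beta <- c(rep(1, k), rep(0, p - k))
    y <- as.vector(X %*% beta + rnorm(n, 0, sd_noise))
    list(X = X, y = y, beta = beta)
  })
}

test_that("standardization centers, scales, and round-trips", {
  s <- standardize(matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "a")))
  expect_equal(mean(s$train), 0)
  expect_equal(sd(s$train), 1)

  withr::with_seed(2, {
    X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, letters[1:4]))
  })
  s <- standardize(X)
  back <- sweep(sweep(s$train, 2, s$scale, "*"), 2, s$center, "+")
  expect_equal(back, X, tolerance = 1e-12)

  X2 <- cbind(X, const = 5)
  expect_warning(s2 <- standardize(X2), "constant")
  expect_identical(s2$dropped, "const")
  expect_identical(ncol(s2$train), 4L)

  expect_error(standardize(matrix(1, 5, 2)), "constant")

  # validation transformed by training moments
  s3 <- standardize(X, X + 1)
  expect_equal(
    s3$val - s3$train, 1 / matrix(s3$scale, 10, 4, byrow = TRUE),
    ignore_attr = TRUE
  )
})

test_that("extreme shrinkage collapses all slopes", {
  d <- make_sparse_design(100, 10, seed = 3)
  des <- lasso_design(d$X, d$y, holdout_frac = 0.1, seed = 1)
  fit <- fit_lasso(des, tau = 1e6, control = mcmc_control(iter = 1500, burnin = 500), seed = 4)
  td <- tidy(fit)
  slopes <- td$estimate[!td$term %in% c("(Intercept)", "sigma")]
  expect_true(all(abs(slopes) < 0.01 * sd(d$y)))
})

test_that("sparse signals are recovered with intervals covering the truth", {
  d <- make_sparse_design(300, 20, k = 3, sd_noise = 0.3, seed = 5)
  des <- lasso_design(d$X, d$y, holdout_frac = 0.1, seed = 2)
  fit <- fit_lasso(des, tau = 2, seed = 6)
  td <- tidy(fit)
  td <- td[!td$term %in% c("(Intercept)", "sigma"), ]
  true_nonzero <- paste0("m", 1:3)
  hit <- td$term %in% true_nonzero
  expect_true(all(td$excludes_zero[hit]))
  # note: predictors are standardized, truth is on the raw scale
  scale_adj <- des$scale[td$term[hit]]
  expect_true(all(td$conf.low[hit] <= scale_adj & td$conf.high[hit] >= scale_adj * 0.8))
  expect_lt(mean(td$excludes_zero[!hit]), 0.15)
})

test_that("posterior signs agree with a coordinate-descent MAP oracle", {
  skip_if_not_installed("glmnet")
  d <- make_sparse_design(200, 10, k = 3, sd_noise = 0.5, seed = 7)
  des <- lasso_design(d$X, d$y, holdout_frac = 0.1, seed = 3)
  tau <- 10
  fit <- fit_lasso(des, tau = tau, seed = 8)
  td <- tidy(fit)
  sigma_hat <- td$estimate[td$term == "sigma"]
  n <- nrow(des$x_train)
  # the posterior mode under Laplace(rate tau) matches the lasso penalty
  # lambda = tau * sigma^2 / n on glmnet's objective scale
  gn <- glmnet::glmnet(
    des$x_train, des$y_train,
    lambda = tau * sigma_hat^2 / n, standardize = FALSE
  )
  map <- as.vector(gn$beta)
  bayes <- td$estimate[match(colnames(des$x_train), td$term)]
  big <- abs(bayes) > 0.05
  expect_true(all(sign(bayes[big]) == sign(map[big])))
})

test_that("the Gibbs sampler matches a Metropolis reference on a toy posterior", {
  withr::with_seed(11, {
    X <- matrix(rnorm(100 * 3), 100, 3)
    colnames(X) <- c("a", "b", "c")
    y <- as.vector(X %*% c(1, -0.5, 0) + rnorm(100, 0, 0.4))
  })
  Xs <- scale(X)
  fit <- fit_lasso(Xs, tau = 5, y = y,
    control = mcmc_control(iter = 8000, burnin = 2000), seed = 12
  )
  ref <- withr::with_seed(13, o_mh_lasso(Xs, y, tau = 5, n_iter = 120000,
    burnin = 20000, step = 0.04
  ))
  expect_gt(attr(ref, "accept_rate"), 0.1)
  gibbs_draws <- do.call(rbind, fit$chains)
  for (j in 1:5) { # beta0, three slopes, sigma
    ref_col <- ref[, j]
    gibbs_col <- gibbs_draws[, j]
    tol <- 3 * sqrt(o_mcse(ref_col)^2 + o_mcse(gibbs_col)^2)
    expect_lt(abs(mean(ref_col) - mean(gibbs_col)), max(tol, 0.02))
  }
})

test_that("the predictive score has its closed form on degenerate draws", {
  # single-draw posterior: the Monte-Carlo score is exactly the normal
  # log-density at the posterior prediction
  draws <- matrix(c(0.5, 1, -1, 2), 1, 4,
    dimnames = list(NULL, c("(Intercept)", "x1", "x2", "sigma"))
  )
  fit <- structure(
    list(chains = list(draws), design = list(x_val = NULL, y_val = NULL)),
    class = "bayes_lasso"
  )
  x_val <- matrix(c(1, 0.5), 1, 2)
  pred <- 0.5 + 1 * 1 + (-1) * 0.5
  y_val <- 2.3
  expect_equal(
    suppressWarnings(oos_log_predictive_density(fit, x_val, y_val)),
    dnorm(y_val, pred, 2, log = TRUE),
    tolerance = 1e-12
  )

  # validation point at the prediction with sigma = 1: log(1/sqrt(2*pi))
  draws1 <- matrix(c(0, 1, 1), 1, 3,
    dimnames = list(NULL, c("(Intercept)", "x1", "sigma"))
  )
  fit1 <- structure(
    list(chains = list(draws1), design = list()),
    class = "bayes_lasso"
  )
  expect_equal(
    suppressWarnings(
      oos_log_predictive_density(fit1, matrix(2, 1, 1), 2)
    ),
    log(1 / sqrt(2 * pi)),
    tolerance = 1e-12
  )
  expect_error(
    oos_log_predictive_density(fit1, NULL, NULL),
    "validation"
  )
})

test_that("the score deteriorates for far-shifted validation data", {
  d <- make_sparse_design(120, 5, seed = 15)
  des <- lasso_design(d$X, d$y, holdout_frac = 0.15, seed = 4)
  fit <- fit_lasso(des, tau = 2,
    control = mcmc_control(iter = 1500, burnin = 500), seed = 16
  )
  near <- oos_log_predictive_density(fit)
  far <- oos_log_predictive_density(fit, des$x_val, des$y_val + 50)
  expect_lt(far, near)
})

test_that("shrinkage selection finds interior optima and stays monotone", {
  # noisy sparse design where moderate shrinkage genuinely helps prediction
  d <- make_sparse_design(120, 40, k = 5, sd_noise = 2, seed = 17)
  des <- lasso_design(d$X, d$y, holdout_frac = 0.1, seed = 5)
  sel <- select_tau(des,
    taus = tau_grid_default(8),
    control = mcmc_control(iter = 2000, burnin = 800), seed = 18
  )
  expect_identical(sel$boundary, "interior")
  expect_identical(nrow(sel$curve), 8L)
  # total shrinkage is non-increasing in tau (5% Monte-Carlo slack)
  sab <- sel$curve$sum_abs_beta
  expect_true(all(diff(sab) <= 0.05 * max(sab)))

  one <- select_tau(des, taus = 5,
    control = mcmc_control(iter = 1000, burnin = 400), seed = 19
  )
  expect_identical(one$tau_star, 5)
  expect_identical(one$boundary, "single")
  expect_identical(nrow(one$curve), 1L)
})

test_that("pure-noise responses do not select the weakest shrinkage", {
  picked_smallest <- sapply(1:10, function(i) {
    withr::with_seed(100 + i, {
      X <- matrix(rnorm(120 * 20), 120, 20)
      y <- rnorm(120)
    })
    des <- lasso_design(X, y, holdout_frac = 0.15, seed = i)
    sel <- select_tau(des,
      taus = tau_grid_default(6),
      control = mcmc_control(iter = 1200, burnin = 400), seed = 200 + i
    )
    sel$tau_star == tau_grid_default(6)[1]
  })
  expect_lte(mean(picked_smallest), 0.2)
})

test_that("standardized coefficients ignore raw predictor scaling", {
  d <- make_sparse_design(150, 6, k = 2, seed = 21)
  X2 <- d$X
  X2[, 1] <- X2[, 1] * 1000
  des1 <- lasso_design(d$X, d$y, holdout_frac = 0.1, seed = 6)
  des2 <- lasso_design(X2, d$y, holdout_frac = 0.1, seed = 6)
  f1 <- fit_lasso(des1, tau = 2, seed = 22)
  f2 <- fit_lasso(des2, tau = 2, seed = 22)
  expect_equal(
    tidy(f1)$estimate[2], tidy(f2)$estimate[2],
    tolerance = 0.05
  )
})

test_that("Gelman-Rubin behaves on identical, disjoint, and stationary chains", {
  withr::with_seed(23, {
    v <- rnorm(5000)
  })
  expect_lt(abs(gelman_rubin(list(v, v, v))[1] - 1), 1e-3)

  withr::with_seed(24, {
    a <- rnorm(500, 0, 1)
    b <- rnorm(500, 10, 1)
  })
  expect_gt(gelman_rubin(list(a, b))[1], 1.1)

  expect_error(gelman_rubin(list(a)), "two chains")
  expect_error(gelman_rubin(list(a[1:5], b[1:5])), "10 draws")

  ok <- sapply(1:20, function(i) {
    withr::with_seed(300 + i, {
      chains <- list(rnorm(800), rnorm(800), rnorm(800))
    })
    gelman_rubin(chains)[1] < 1.05
  })
  expect_gte(mean(ok), 0.95)
})

test_that("non-positive shrinkage rates are rejected", {
  d <- make_sparse_design(50, 4, seed = 25)
  des <- lasso_design(d$X, d$y, holdout_frac = 0.1, seed = 7)
  expect_error(fit_lasso(des, tau = 0), "positive")
  expect_error(fit_lasso(des, tau = -1), "positive")
  expect_error(
    select_tau(des, taus = c(5, 2)),
    "increasing"
  )
})
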