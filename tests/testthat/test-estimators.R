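# Point estimators: Hajek IPW, outcome regression, AIPW, and the assembled
# pipelines.

test_that("Hajek IPW matches hand evaluation on the 4-row fixture", {
  Y <- c(3, 1, 2, 0)
  A <- c(1, 1, 0, 0)
  # constant propensity: difference of group means
  expect_equal(hajek_ipw(Y, A, rep(0.5, 4)), 1)
  # uneven propensities, evaluated by hand
  expect_equal(hajek_ipw(Y, A, c(0.8, 0.4, 0.5, 0.2)), 5 / 3 - 16 / 13,
               tolerance = 1e-12)
  # both groups constant at c: zero for any valid propensity
  expect_equal(hajek_ipw(rep(2.2, 4), A, c(0.3, 0.6, 0.5, 0.9)), 0,
               tolerance = 1e-12)
})

test_that("Hajek IPW guards its positivity preconditions", {
  Y <- c(3, 1, 2, 0)
  A <- c(1, 1, 0, 0)
  expect_error(hajek_ipw(Y, A, c(0, 0.4, 0.5, 0.2)), "propensity 0")
  expect_error(hajek_ipw(Y, A, c(0.8, 0.4, 1, 0.2)), "propensity 1")
  # a negative score warns when the weight totals still normalise
  Y6 <- c(3, 1, 2, 0, 1, 2)
  A6 <- c(1, 1, 1, 1, 1, 0)
  expect_warning(hajek_ipw(Y6, A6, c(0.9, 0.9, 0.9, 0.9, -0.5, 0.5)),
                 "negative")
  # ... and errors when they do not
  expect_error(
    suppressWarnings(hajek_ipw(Y, A, c(0.8, -0.2, 0.5, 0.2))),
    "non-positive weight totals"
  )
})

test_that("Hajek IPW is location/scale equivariant and weight-scale invariant", {
  set.seed(33)
  Y <- rnorm(30)
  A <- rep(c(1, 0), 15)
  pi <- runif(30, 0.2, 0.8)
  est <- hajek_ipw(Y, A, pi)
  expect_equal(hajek_ipw(Y + 5, A, pi), est, tolerance = 1e-10)
  expect_equal(hajek_ipw(3 * Y, A, pi), 3 * est, tolerance = 1e-10)
  # constant propensity reduces to the difference of group means
  expect_equal(hajek_ipw(Y, A, rep(0.37, 30)),
               mean(Y[A == 1]) - mean(Y[A == 0]), tolerance = 1e-12)
})

test_that("OR estimator equals the treatment coefficient of a joint fit", {
  d <- toy_data(n = 50L, seed = 909L)
  fit <- fit_or_model(d, model_spec("OR", c("X1", "X2"), "OR1"))
  est <- or_estimate(d, fit)
  expect_equal(est, fit$treat_coef)
  # oracle: row-wise average of mu1 - mu0
  mu1 <- fit$intercept + drop(d$X[, 1:2] %*% fit$slopes) + fit$treat_coef
  mu0 <- fit$intercept + drop(d$X[, 1:2] %*% fit$slopes)
  expect_equal(est, mean(mu1 - mu0), tolerance = 1e-12)
})

test_that("AIPW with zero outcome model reduces to Horvitz-Thompson IPW", {
  d <- toy_data(n = 40L, seed = 111L)
  ps_fit <- fit_ps_model(d, model_spec("PS", "X1", "PS1"))
  zero_or <- fit_or_model(observed_data(rep(0, 40L), d$A, d$X),
                          model_spec("OR", "X1", "OR1"))
  pi <- 1 / (1 + exp(-(ps_fit$intercept + d$X[, 1] * ps_fit$slopes)))
  ht <- mean(d$A * d$Y / pi) - mean((1 - d$A) * d$Y / (1 - pi))
  expect_equal(aipw_estimate(d, ps_fit, zero_or), ht, tolerance = 1e-10)
})

test_that("AIPW is exact when the outcome model is exact", {
  d <- toy_data(n = 40L, seed = 222L)
  d_exact <- observed_data(1 + 2 * d$X[, 1] + 0.7 * d$A, d$A, d$X)
  ps_fit <- fit_ps_model(d_exact, model_spec("PS", character(), "PS0"))
  or_fit <- fit_or_model(d_exact, model_spec("OR", "X1", "OR1"))
  expect_equal(aipw_estimate(d_exact, ps_fit, or_fit), 0.7, tolerance = 1e-8)
})

test_that("AIPW matches term-by-term evaluation on a 6-row fixture", {
  X <- matrix(c(-0.5, 0.3, 1.1, -1.2, 0.8, 0.1), ncol = 1,
              dimnames = list(NULL, "X1"))
  d <- observed_data(Y = c(2.0, 1.5, 3.0, 0.5, 2.5, 1.0),
                     A = c(1, 0, 1, 0, 1, 0), X = X)
  ps_fit <- fit_ps_model(d, model_spec("PS", "X1", "PS1"))
  or_fit <- fit_or_model(d, model_spec("OR", "X1", "OR1"))
  pi <- 1 / (1 + exp(-(ps_fit$intercept + X[, 1] * ps_fit$slopes)))
  mu1 <- or_fit$intercept + X[, 1] * or_fit$slopes + or_fit$treat_coef
  mu0 <- or_fit$intercept + X[, 1] * or_fit$slopes
  acc <- 0
  for (i in 1:6) {
    t1 <- d$A[i] * d$Y[i] / pi[i] - (d$A[i] - pi[i]) * mu1[i] / pi[i]
    t0 <- (1 - d$A[i]) * d$Y[i] / (1 - pi[i]) +
      (d$A[i] - pi[i]) * mu0[i] / (1 - pi[i])
    acc <- acc + (t1 - t0) / 6
  }
  expect_equal(aipw_estimate(d, ps_fit, or_fit), acc, tolerance = 1e-12)
})

test_that("estimate_ate IPW path reduces to Hajek on the parametric propensity", {
  cfg <- dgp_config(n = 400L, alpha0 = 0, seed = 51L)
  d <- gen_dataset(cfg)
  est <- estimate_ate(d, "IPW", "1000")
  fit <- fit_ps_model(d, ps_model_set()[[1]])
  pi <- 1 / (1 + exp(-(fit$intercept + drop(d$X[, 1:7] %*% fit$slopes))))
  expect_equal(est$estimate, hajek_ipw(d$Y, d$A, pi), tolerance = 1e-10)
  expect_identical(est$label, "IPW-1000")
})

test_that("kernel MiPS with one PS and one OR index is the double-index path", {
  cfg <- dgp_config(n = 300L, alpha0 = 0, seed = 52L)
  d <- gen_dataset(cfg)
  est <- estimate_ate(d, "Ker.MiPS", "1010")
  ps <- fit_ps_model(d, ps_model_set()[[1]])
  or <- fit_or_model(d, or_model_set()[[1]])
  S <- build_index_matrix(d, list(ps), list(or))
  pi <- nw_mips(S, d$A)
  expect_equal(est$estimate, hajek_ipw(d$Y, d$A, pi$scores), tolerance = 1e-10)
})

test_that("invalid estimator configurations are rejected", {
  d <- toy_data(n = 30L, seed = 66L)
  expect_error(estimate_ate(d, "ANN.MiPS", "0000"), "all-zero bitmask")
  expect_error(estimate_ate(d, "IPW", "1010"), "exactly one PS")
  expect_error(estimate_ate(d, "OR", "1010"), "exactly one OR")
  expect_error(estimate_ate(d, "AIPW", "1000"), "one PS and one OR")
  expect_error(estimate_ate(d, "ANN.MiPS", "10"), "4 characters")
})

test_that("estimator labels follow the bitmask naming convention", {
  d <- gen_dataset(dgp_config(n = 200L, alpha0 = 0, seed = 53L))
  e <- estimate_ate(d, "ANN.MiPS", "1010", ann = ann_config(epochs = 5))
  expect_identical(e$label, "ANN.MiPS-1010")
  e2 <- estimate_ate(d, "ANN.MiPS", "1111", extra = "2PS2OR",
                     ann = ann_config(epochs = 5))
  expect_identical(e2$label, "ANN.MiPS-1111-2PS2OR")
  # ANN propensities are clipped into (0, 1)
  expect_true(all(e$diagnostics$score_range > 0 &
                    e$diagnostics$score_range < 1))
})
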