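# Candidate model fitting and index-matrix construction.

test_that("logistic PS fit matches the saturated 2x2 closed form", {
  d <- contingency_data()
  fit <- fit_ps_model(d, model_spec("PS", "X1", "PS1"))
  expect_true(fit$converged)
  # log-odds: x=0 -> log(1/3); x=1 -> log(3); slope log 9
  expect_equal(fit$intercept, log(1 / 3), tolerance = 1e-6)
  expect_equal(unname(fit$slopes), log(9), tolerance = 1e-6)
})

test_that("logistic PS fit matches brute-force likelihood maximisation", {
  d <- toy_data(n = 30L, seed = 202L)
  fit <- fit_ps_model(d, model_spec("PS", "X1", "PS1"))
  oracle <- grid_logistic_mle(d$X[, 1], d$A)
  expect_equal(fit$intercept, oracle[1], tolerance = 1e-4)
  expect_equal(unname(fit$slopes), oracle[2], tolerance = 1e-4)
})

test_that("degenerate and rank-deficient PS designs are flagged", {
  d <- toy_data(n = 20L, seed = 303L)
  d_const <- observed_data(d$Y, rep(1L, 20L), d$X)
  fit <- fit_ps_model(d_const, model_spec("PS", "X1", "PS1"))
  expect_false(fit$converged)

  expect_error(
    fit_ps_model(d, model_spec("PS", c("X1", "X1"), "PSdup")),
    "rank deficient"
  )
})

test_that("OLS OR fit recovers exact and degenerate cases", {
  d <- toy_data(n = 25L, seed = 404L)

  # flat response
  d_flat <- observed_data(rep(3.5, 25L), d$A, d$X)
  fit <- fit_or_model(d_flat, model_spec("OR", c("X1", "X2"), "OR1"))
  expect_equal(fit$intercept, 3.5, tolerance = 1e-10)
  expect_equal(unname(fit$slopes), c(0, 0), tolerance = 1e-10)
  expect_equal(fit$treat_coef, 0, tolerance = 1e-10)

  # noiseless linear response, no treatment effect
  d_lin <- observed_data(1 + 2 * d$X[, 1], d$A, d$X)
  fit2 <- fit_or_model(d_lin, model_spec("OR", "X1", "OR1"))
  expect_equal(fit2$intercept, 1, tolerance = 1e-10)
  expect_equal(unname(fit2$slopes), 2, tolerance = 1e-10)

  # residual orthogonality to the design
  fit3 <- fit_or_model(d, model_spec("OR", c("X1", "X2"), "OR1"))
  mu <- fit3$intercept + d$X[, 1:2] %*% fit3$slopes + fit3$treat_coef * d$A
  r <- d$Y - drop(mu)
  expect_lt(max(abs(crossprod(cbind(1, d$X[, 1:2], d$A), r))) / max(abs(d$Y)),
            1e-8)
})

test_that("intercept-plus-treatment OR model returns the group-mean difference", {
  d <- toy_data(n = 40L, seed = 505L)
  fit <- fit_or_model(d, model_spec("OR", character(), "OR0"))
  expect_equal(fit$treat_coef,
               mean(d$Y[d$A == 1]) - mean(d$Y[d$A == 0]),
               tolerance = 1e-10)
})

test_that("group-separate OR fits are exact on a noiseless interaction-free model", {
  d <- toy_data(n = 40L, seed = 606L)
  d_exact <- observed_data(d$X[, 1] + d$A, d$A, d$X)
  fit <- fit_or_model(d_exact, model_spec("OR", "X1", "OR1"), separate = TRUE)
  expect_equal(or_estimate(d_exact, fit), 1, tolerance = 1e-8)
  S <- build_index_matrix(d_exact, list(), list(fit), standardize = FALSE)
  expect_equal(ncol(S$S), 2L) # one index column per group
})

test_that("index matrix standardization, zero columns and invariances", {
  d <- toy_data(n = 50L, seed = 707L)
  ps <- fit_ps_model(d, model_spec("PS", c("X1", "X2"), "PS1"))
  or <- fit_or_model(d, model_spec("OR", c("X1", "X3"), "OR1"))

  S <- build_index_matrix(d, list(ps), list(or))
  expect_equal(ncol(S$S), 2L)
  expect_equal(colMeans(S$S), c(PS1 = 0, OR1 = 0), tolerance = 1e-12)
  expect_equal(apply(S$S, 2, sd), c(PS1 = 1, OR1 = 1), tolerance = 1e-12)

  # rescaling a covariate leaves the standardized index column unchanged
  X2 <- d$X
  X2[, 1] <- X2[, 1] * 10
  d2 <- observed_data(d$Y, d$A, X2)
  ps2 <- fit_ps_model(d2, model_spec("PS", c("X1", "X2"), "PS1"))
  expect_equal(ps2$slopes[["X1"]], ps$slopes[["X1"]] / 10, tolerance = 1e-6)
  S2 <- build_index_matrix(d2, list(ps2), list())
  S1 <- build_index_matrix(d, list(ps), list())
  expect_equal(S2$S, S1$S, tolerance = 1e-6)

  # row permutation permutes the index rows identically
  perm <- rev(seq_len(50L))
  dp <- observed_data(d$Y[perm], d$A[perm], d$X[perm, ])
  psp <- fit_ps_model(dp, model_spec("PS", c("X1", "X2"), "PS1"))
  Sp <- build_index_matrix(dp, list(psp), list())
  expect_equal(Sp$S[perm, , drop = FALSE], S1$S, tolerance = 1e-8,
               ignore_attr = TRUE)

  # an all-zero slope vector yields a flagged zero column
  zfit <- fit_or_model(observed_data(rep(1, 50L), d$A, d$X),
                       model_spec("OR", "X1", "ORz"))
  expect_warning(Sz <- build_index_matrix(d, list(), list(zfit)),
                 "zero variance")
  expect_true(all(Sz$S[, 1] == 0))
})

test_that("non-converged fits are rejected by the index builder", {
  d <- toy_data(n = 20L, seed = 808L)
  bad <- fit_ps_model(observed_data(d$Y, rep(1L, 20L), d$X),
                      model_spec("PS", "X1", "PS1"))
  expect_error(build_index_matrix(d, list(bad), list()), "converge")
})

test_that("benchmark candidate sets match their printed composition", {
  ps <- ps_model_set(extra = TRUE)
  or <- or_model_set(extra = TRUE)
  expect_equal(vapply(ps, function(s) s$label, ""),
               c("PS1", "PS2", "PS3", "PS4"))
  expect_equal(ps[[1]]$terms, paste0("X", 1:7))
  expect_equal(ps[[2]]$terms, paste0("X", 1:7, "^2"))
  expect_equal(or[[1]]$terms, paste0("X", c(1:4, 8:10)))
  expect_equal(or[[4]]$terms, paste0("X", 1:3, "^2"))
  expect_true(all(vapply(or, function(s) s$include_treatment, TRUE)))
})
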