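# Integrated propensity scores: kernel smoother and neural network.

test_that("kernel scores reduce to mean(A) in the flat-kernel limit", {
  set.seed(1)
  S <- matrix(rnorm(40), 20, 2)
  A <- rbinom(20, 1, 0.5)
  pi <- nw_mips(S, A, bandwidths = c(1e6, 1e6))
  expect_equal(pi$scores, rep(mean(A), 20), tolerance = 1e-9)

  # indistinguishable regressors: every score is mean(A) at any bandwidth
  S_const <- matrix(1, 20, 2)
  pi2 <- nw_mips(S_const, A, bandwidths = c(0.3, 0.3))
  expect_equal(pi2$scores, rep(mean(A), 20), tolerance = 1e-12)
})

test_that("kernel scores equal a brute-force double-loop evaluation", {
  S <- matrix(c(0.1, -0.4, 1.2, 0.7, -1.0,
                0.5, 0.0, -0.3, 0.9, 0.2), 5, 2)
  A <- c(1, 0, 1, 1, 0)
  h <- c(0.6, 0.8)
  oracle <- numeric(5)
  for (i in 1:5) {
    num <- den <- 0
    for (j in 1:5) {
      w <- prod(dnorm((S[j, ] - S[i, ]) / h))
      num <- num + w * A[j]
      den <- den + w
    }
    oracle[i] <- num / den
  }
  pi <- nw_mips(S, A, bandwidths = h)
  expect_equal(pi$scores, oracle, tolerance = 1e-12)

  # leave-in convexity: scores stay inside [0, 1] on random inputs
  set.seed(42)
  for (rep in 1:5) {
    Sr <- matrix(rnorm(60), 30, 2)
    Ar <- rbinom(30, 1, 0.4)
    pr <- nw_mips(Sr, Ar)
    expect_true(all(pr$scores >= 0 & pr$scores <= 1))
    expect_identical(pr$out_of_range, 0L)
  }
})

test_that("kernel scores are equivariant under row permutation", {
  set.seed(5)
  S <- matrix(rnorm(50), 25, 2)
  A <- rbinom(25, 1, 0.5)
  perm <- sample(25)
  p1 <- nw_mips(S, A, bandwidths = c(0.5, 0.5))
  p2 <- nw_mips(S[perm, ], A[perm], bandwidths = c(0.5, 0.5))
  expect_equal(p2$scores, p1$scores[perm], tolerance = 1e-12)
})

test_that("leave-one-out mode exposes the degenerate-score pathology", {
  # one isolated treated point among clustered controls: its leave-one-out
  # score is driven entirely by controls, so weighting by it must fail
  S <- matrix(c(0, 0.01, -0.01, 0.02, 5), ncol = 1)
  A <- c(0L, 0L, 0L, 0L, 1L)
  pi <- nw_mips(S, A, bandwidths = 0.5, leave_one_out = TRUE)
  expect_equal(pi$scores[5], 0, tolerance = 1e-12)
  expect_error(hajek_ipw(rnorm(5), A, pi), "propensity 0")

  # underflowing denominator is reported with the offending row
  expect_error(nw_mips(S, A, bandwidths = 1e-4, leave_one_out = TRUE),
               "row")

  # out-of-range diagnostics count scores outside [0, 1]
  pv <- propensity_vector(c(-0.1, 0.5, 1.2), method = "kernel")
  expect_identical(pv$out_of_range, 2L)
})

test_that("Scott bandwidth rule follows its closed form", {
  set.seed(9)
  S <- scale(matrix(rnorm(200), 100, 2))
  h <- scott_bandwidth(S)
  sds <- apply(S, 2, sd) # exactly 1 after scaling
  expect_equal(h, sds * 100^(-1 / 6), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(scott_bandwidth(S, undersmooth = 0.5), h / 2, tolerance = 1e-12)
  expect_error(scott_bandwidth(S[1, , drop = FALSE]), "at least 2")
  expect_error(scott_bandwidth(matrix(1, 10, 2)), "zero-variance")
})

test_that("network training beats the constant predictor on a separable index", {
  set.seed(11)
  S <- matrix(rnorm(200), 200, 1)
  A <- as.integer(S[, 1] > 0)
  m <- train_ann(S, A, ann_config(seed = 3, trace = TRUE))
  # best constant predictor has MSE p(1-p) = 0.25 at p = 1/2
  expect_lt(tail(m$loss_trace, 1), 0.25)
  # loss trace decreases after the momentum transient
  post <- m$loss_trace[-(1:10)]
  expect_true(all(diff(post) <= 1e-9))
})

test_that("degenerate all-treated target drives predictions towards one", {
  set.seed(12)
  S <- scale(matrix(rnorm(100), 100, 1))
  m <- train_ann(S, rep(1L, 100), ann_config(seed = 4))
  expect_true(all(predict(m, S)$scores > 0.9))
})

test_that("training is bit-reproducible under a fixed seed", {
  set.seed(13)
  S <- matrix(rnorm(120), 60, 2)
  A <- rbinom(60, 1, 0.5)
  m1 <- train_ann(S, A, ann_config(epochs = 200, seed = 21))
  m2 <- train_ann(S, A, ann_config(epochs = 200, seed = 21))
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$fitted, m2$fitted)
  m3 <- train_ann(S, A, ann_config(epochs = 200, seed = 22))
  expect_false(identical(m1$weights, m3$weights))
})

test_that("prediction is the forward pass of the trained network", {
  set.seed(14)
  S <- matrix(rnorm(80), 40, 2)
  A <- rbinom(40, 1, 0.5)
  m <- train_ann(S, A, ann_config(epochs = 100, seed = 5))
  p <- predict(m, S)
  expect_s3_class(p, "propensity_vector")
  expect_identical(p$method, "ann")
  expect_equal(p$scores, m$fitted, tolerance = 1e-12)
  expect_true(all(p$scores > 0 & p$scores < 1))
  expect_error(predict(m, S[, 1, drop = FALSE]), "input columns")

  # zero-weight network: constant output sigmoid(output bias)
  w0 <- list(W1 = matrix(0, 2, 4), b1 = rep(0, 4), W2 = matrix(0, 4, 4),
             b2 = rep(0, 4), W3 = rep(0, 4), b3 = 0.7)
  m0 <- structure(list(weights = w0, d = 2L, cfg = ann_config()),
                  class = "ann_mips")
  expect_equal(predict(m0, S)$scores, rep(1 / (1 + exp(-0.7)), 40),
               tolerance = 1e-12)
})

test_that("sigmoid output requires a binary target and enough rows", {
  S <- matrix(rnorm(40), 20, 2)
  expect_error(train_ann(S, rnorm(20), ann_config()), "0/1")
  expect_error(train_ann(S[1:5, ], rbinom(5, 1, 0.5), ann_config()),
               "at least 10")
})
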