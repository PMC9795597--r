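# Small fixtures built in code, shared across test files.

with_seed_helper <- function(seed, expr) {
  set.seed(seed)
  expr
}

DEFAULT_OUTCOME_COEFS_helper <- function() dgp_config(n = 1L)$outcome_coefs

# deterministic toy dataset with one informative covariate
toy_data <- function(n = 30L, seed = 101L, p = 3L) {
  withr_seed <- function(expr) {
    set.seed(seed)
    expr
  }
  withr_seed({
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("X", 1:p)))
    pr <- 1 / (1 + exp(-(0.3 + 0.8 * X[, 1])))
    A <- rbinom(n, 1L, pr)
    if (length(unique(A)) < 2L) A[1:2] <- c(0L, 1L)
    Y <- 1 + 0.5 * X[, 1] - 0.3 * X[, 2] + 0.7 * A + rnorm(n, sd = 0.5)
    observed_data(Y, A, X)
  })
}

# the 2x2 contingency fixture: x=1 -> 3 treated / 1 control,
# x=0 -> 1 treated / 3 controls
contingency_data <- function() {
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  A <- c(1, 1, 1, 0, 1, 0, 0, 0)
  observed_data(Y = seq_along(A), A = A,
                X = matrix(x, ncol = 1, dimnames = list(NULL, "X1")))
}

# brute-force logistic MLE by nested grid refinement (independent of glm)
grid_logistic_mle <- function(x, a, center = c(0, 0), width = 4, steps = 5L) {
  best <- center
  for (s in seq_len(steps)) {
    grid <- seq(-width, width, length.out = 41L)
    vals <- expand.grid(b0 = best[1] + grid, b1 = best[2] + grid)
    ll <- vapply(seq_len(nrow(vals)), function(i) {
      eta <- vals$b0[i] + vals$b1[i] * x
      sum(a * eta - log1p(exp(eta)))
    }, numeric(1))
    best <- unlist(vals[which.max(ll), ], use.names = FALSE)
    width <- width / 10
  }
  best
}
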