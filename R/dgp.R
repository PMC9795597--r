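# Synthetic data-generating process: 10 standard-normal covariates, logistic
# treatment assignment on X1-X7, linear outcome on treatment and
# X1-X4, X8-X10 with standard-normal noise.  The treatment coefficient is the
# true average treatment effect (-0.4 by default).

DEFAULT_TREAT_COEFS <- c(0.16, -0.05, 0.12, -0.10, -0.16, -0.10, 0.15)

DEFAULT_OUTCOME_COEFS <- list(
  intercept = -3.85,
  treatment = -0.4,
  covariates = c(-0.8, -0.36, -0.73, -0.2, 0, 0, 0, 0.71, -0.19, 0.26)
)

# Correlation-matrix constructors ---------------------------------------

#' Correlation structures for the simulated covariates
#'
#' `corr_identity()` gives independent covariates, `corr_exchangeable()` a
#' constant pairwise correlation, and `corr_ar1()` a first-order
#' autoregressive decay `rho^|i-j|`.
#'
#' @param p matrix dimension.
#' @param rho pairwise correlation; must keep the matrix positive definite.
#' @return a `p x p` correlation matrix.
#' @export
corr_identity <- function(p = 10L) diag(p)

#' @rdname corr_identity
#' @export
corr_exchangeable <- function(p = 10L, rho) {
  stopifnot(rho > -1 / (p - 1), rho < 1)
  m <- matrix(rho, p, p)
  diag(m) <- 1
  m
}

#' @rdname corr_identity
#' @export
corr_ar1 <- function(p = 10L, rho) {
  stopifnot(abs(rho) < 1)
  rho^abs(outer(seq_len(p), seq_len(p), "-"))
}

check_corr <- function(corr) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr)) {
    stop("`corr` must be a square matrix", call. = FALSE)
  }
  if (max(abs(corr - t(corr))) > 1e-10) {
    stop("`corr` must be symmetric", call. = FALSE)
  }
  if (max(abs(diag(corr) - 1)) > 1e-10) {
    stop("`corr` must have unit diagonal", call. = FALSE)
  }
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12) {
    stop("`corr` must be positive definite", call. = FALSE)
  }
  invisible(corr)
}

# Configuration ----------------------------------------------------------

#' Configuration of the synthetic data-generating process
#'
#' Defaults reproduce the benchmark generating process: ten standard-normal
#' covariates, treatment assigned by a logistic model with coefficients
#' `(0.16, -0.05, 0.12, -0.10, -0.16, -0.10, 0.15)` on `X1..X7`, and a linear
#' outcome `Y = -3.85 - 0.4 A - 0.8 X1 - 0.36 X2 - 0.73 X3 - 0.2 X4
#' + 0.71 X8 - 0.19 X9 + 0.26 X10 + eps` with standard-normal noise.  The
#' treatment-model intercept `alpha0 = 0` gives roughly 50% treated and
#' `alpha0 = -1.1` roughly 25%.
#'
#' @param n sample size.
#' @param alpha0 treatment-model intercept.
#' @param corr covariate correlation matrix (positive definite, unit
#'   diagonal); see [corr_identity()].
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param treat_coefs logistic coefficients for the leading covariates.
#' @param outcome_coefs list with elements `intercept`, `treatment` and
#'   `covariates` (numeric vector, one entry per covariate column).
#' @param noise_sd standard deviation of the outcome noise.
#' @return an object of class `dgp_config`.
#' @export
dgp_config <- function(n, alpha0 = 0, corr = corr_identity(10L), seed = NULL,
                       treat_coefs = DEFAULT_TREAT_COEFS,
                       outcome_coefs = DEFAULT_OUTCOME_COEFS,
                       noise_sd = 1) {
  stopifnot(length(n) == 1L, n >= 0, n == floor(n))
  check_corr(corr)
  p <- ncol(corr)
  # default coefficient vectors adapt to a non-default covariate dimension
  if (missing(treat_coefs) && p < length(treat_coefs)) {
    treat_coefs <- treat_coefs[seq_len(p)]
  }
  if (missing(outcome_coefs) && p != length(outcome_coefs$covariates)) {
    cv <- rep(0, p)
    k <- min(p, length(outcome_coefs$covariates))
    cv[seq_len(k)] <- outcome_coefs$covariates[seq_len(k)]
    outcome_coefs$covariates <- cv
  }
  stopifnot(is.numeric(treat_coefs), length(treat_coefs) >= 1L)
  if (!all(c("intercept", "treatment", "covariates") %in% names(outcome_coefs))) {
    stop("`outcome_coefs` needs intercept, treatment and covariates", call. = FALSE)
  }
  if (length(outcome_coefs$covariates) != ncol(corr)) {
    stop("outcome covariate coefficients must match the number of covariates",
         call. = FALSE)
  }
  if (length(treat_coefs) > ncol(corr)) {
    stop("more treatment coefficients than covariates", call. = FALSE)
  }
  stopifnot(noise_sd > 0)
  structure(
    list(n = as.integer(n), alpha0 = alpha0, corr = corr, seed = seed,
         treat_coefs = treat_coefs, outcome_coefs = outcome_coefs,
         noise_sd = noise_sd),
    class = "dgp_config"
  )
}

# Generators -------------------------------------------------------------

#' Generate multivariate-normal covariates
#'
#' Rows are i.i.d. mean-zero normal with unit marginal variances and the
#' correlation matrix of the configuration, obtained by a Cholesky transform
#' of independent standard normals.
#'
#' @param cfg a [dgp_config()].
#' @param seed optional seed overriding `cfg$seed`.
#' @return an `n x p` matrix with columns `X1..Xp`.
#' @export
gen_covariates <- function(cfg, seed = cfg$seed) {
  p <- ncol(cfg$corr)
  X <- with_seed(seed, {
    Z <- matrix(rnorm(cfg$n * p), nrow = cfg$n, ncol = p)
    Z %*% chol(cfg$corr)
  })
  colnames(X) <- paste0("X", seq_len(p))
  X
}

#' Treatment-assignment probabilities of the generating model
#'
#' @param X covariate matrix with at least as many columns as coefficients.
#' @param alpha0 intercept of the logistic treatment model.
#' @param treat_coefs logistic slopes applied to the leading columns of `X`.
#' @return vector of probabilities `P(A = 1 | X)`.
#' @export
treatment_prob <- function(X, alpha0, treat_coefs = DEFAULT_TREAT_COEFS) {
  if (ncol(X) < length(treat_coefs)) {
    stop(sprintf("need at least %d covariate columns, got %d",
                 length(treat_coefs), ncol(X)), call. = FALSE)
  }
  expit(alpha0 + drop(X[, seq_along(treat_coefs), drop = FALSE] %*% treat_coefs))
}

#' Generate treatment assignments
#'
#' Draws `A_i ~ Bernoulli(expit(alpha0 + c' X_i))` independently across
#' subjects.
#'
#' @inheritParams treatment_prob
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return integer 0/1 vector.
#' @export
gen_treatment <- function(X, alpha0, treat_coefs = DEFAULT_TREAT_COEFS,
                          seed = NULL) {
  pr <- treatment_prob(X, alpha0, treat_coefs)
  with_seed(seed, rbinom(nrow(X), 1L, pr))
}

#' Generate outcomes and their potential-outcome pair
#'
#' Both potential outcomes share one noise draw per subject, so
#' `Y1 - Y0` equals the treatment coefficient exactly for every subject; the
#' observed outcome satisfies the consistency identity
#' `Y = A * Y1 + (1 - A) * Y0`.
#'
#' @param X covariate matrix.
#' @param A binary treatment vector of matching length.
#' @param outcome_coefs outcome-model coefficients, see [dgp_config()].
#' @param noise_sd noise standard deviation.
#' @param seed optional seed.
#' @return list with `Y`, `Y1`, `Y0`.
#' @export
gen_outcome <- function(X, A, outcome_coefs = DEFAULT_OUTCOME_COEFS,
                        noise_sd = 1, seed = NULL) {
  if (nrow(X) != length(A)) {
    stop("`X` and `A` lengths differ", call. = FALSE)
  }
  if (ncol(X) < length(outcome_coefs$covariates)) {
    stop("too few covariate columns for the outcome model", call. = FALSE)
  }
  if (!all(A %in% c(0, 1))) stop("`A` must be 0/1", call. = FALSE)
  base <- outcome_coefs$intercept +
    drop(X[, seq_along(outcome_coefs$covariates), drop = FALSE] %*%
           outcome_coefs$covariates)
  eps <- with_seed(seed, rnorm(nrow(X), sd = noise_sd))
  Y0 <- base + eps
  Y1 <- Y0 + outcome_coefs$treatment
  list(Y = A * Y1 + (1 - A) * Y0, Y1 = Y1, Y0 = Y0)
}

#' True average treatment effect of a generating configuration
#'
#' With no treatment-covariate interaction in the outcome model the ATE is
#' the treatment coefficient itself.
#'
#' @param cfg a [dgp_config()].
#' @return the true ATE (`-0.4` for the default configuration).
#' @export
true_ate <- function(cfg) cfg$outcome_coefs$treatment

#' Generate a complete observational dataset
#'
#' Draws covariates, treatment and outcome in one seeded pass and returns an
#' [observed_data()] object that also retains the potential outcomes for
#' evaluation.
#'
#' @param cfg a [dgp_config()].
#' @param seed optional seed overriding `cfg$seed`.
#' @return an `observed_data` object with attributes `Y1`, `Y0`.
#' @export
gen_dataset <- function(cfg, seed = cfg$seed) {
  with_seed(seed, {
    X <- gen_covariates(cfg, seed = NULL)
    A <- gen_treatment(X, cfg$alpha0, cfg$treat_coefs, seed = NULL)
    out <- gen_outcome(X, A, cfg$outcome_coefs, cfg$noise_sd, seed = NULL)
    observed_data(out$Y, A, X, Y1 = out$Y1, Y0 = out$Y0)
  })
}

# Observed-data container ------------------------------------------------

#' Observational dataset container
#'
#' Bundles a continuous outcome, a binary treatment indicator and a covariate
#' matrix after validation: equal lengths, `A` strictly 0/1, and no missing
#' values.
#'
#' @param Y numeric outcome vector.
#' @param A binary treatment vector.
#' @param X covariate matrix (columns named, `X1..Xp` by default).
#' @param Y1,Y0 optional potential-outcome vectors kept as attributes.
#' @return an object of class `observed_data` with elements `Y`, `A`, `X`.
#' @export
observed_data <- function(Y, A, X, Y1 = NULL, Y0 = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  n <- length(Y)
  if (length(A) != n || nrow(X) != n) {
    stop("`Y`, `A` and `X` must have equal length", call. = FALSE)
  }
  if (anyNA(Y) || anyNA(A) || anyNA(X)) {
    stop("missing values are not allowed", call. = FALSE)
  }
  if (!all(A %in% c(0, 1))) {
    bad <- which(!(A %in% c(0, 1)))
    stop(sprintf("`A` must be 0/1; offending rows: %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  obj <- structure(list(Y = as.numeric(Y), A = as.integer(A), X = X),
                   class = "observed_data")
  if (!is.null(Y1)) attr(obj, "Y1") <- as.numeric(Y1)
  if (!is.null(Y0)) attr(obj, "Y0") <- as.numeric(Y0)
  obj
}

#' @export
print.observed_data <- function(x, ...) {
  cat(sprintf("<observed_data> n = %d, p = %d, treated = %d (%.1f%%)\n",
              length(x$Y), ncol(x$X), sum(x$A), 100 * mean(x$A)))
  invisible(x)
}

#' @export
dim.observed_data <- function(x) c(length(x$Y), ncol(x$X))
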