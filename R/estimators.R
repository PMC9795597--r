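# Point estimators of the average treatment effect: Hajek-normalised IPW
# with any propensity vector, outcome regression, AIPW, and the multi-index
# pipelines (kernel or neural network) assembled by estimate_ate().

# fitted parametric propensities of a PS candidate fit
ps_fitted <- function(fit, X) {
  stopifnot(fit$spec$role == "PS")
  expit(fit$intercept + drop(term_matrix(fit$spec, X) %*% fit$slopes))
}

#' Hajek-normalised inverse-probability-weighting estimator
#'
#' `sum(A w1 Y)/sum(A w1) - sum((1-A) w0 Y)/sum((1-A) w0)` with
#' `w1 = 1/pi`, `w0 = 1/(1-pi)`.  The self-normalised form is invariant to
#' rescaling the weights within each group and reduces to the difference of
#' group means under a constant propensity.  Kernel-based scores outside
#' `[0, 1]` produce negative weights; the computation proceeds with a
#' warning since diagnosing that failure mode is part of the method's story.
#'
#' @param Y outcome vector.
#' @param A binary treatment vector.
#' @param pi propensity scores ([propensity_vector()] or numeric).
#' @return the point estimate (numeric scalar).
#' @export
hajek_ipw <- function(Y, A, pi) {
  if (inherits(pi, "propensity_vector")) pi <- pi$scores
  n <- length(Y)
  stopifnot(length(A) == n, length(pi) == n, all(A %in% c(0, 1)))
  if (any(A == 1 & pi == 0)) {
    stop("propensity 0 for a treated unit", call. = FALSE)
  }
  if (any(A == 0 & pi == 1)) {
    stop("propensity 1 for a control unit", call. = FALSE)
  }
  w1 <- 1 / pi
  w0 <- 1 / (1 - pi)
  if (any((A == 1 & w1 < 0) | (A == 0 & w0 < 0))) {
    warning("negative inverse-probability weights: propensity scores outside [0, 1]",
            call. = FALSE)
  }
  s1 <- sum(A * w1)
  s0 <- sum((1 - A) * w0)
  if (s1 <= 0 || s0 <= 0) {
    stop("non-positive weight totals; cannot normalise", call. = FALSE)
  }
  sum(A * w1 * Y) / s1 - sum((1 - A) * w0 * Y) / s0
}

#' Outcome-regression estimator
#'
#' Averages the fitted treated-minus-control predictions over all subjects.
#' For a joint linear fit without interactions this is exactly the fitted
#' coefficient of the treatment indicator; for group-separate fits the
#' row-wise mean of `mu1(X) - mu0(X)` is returned.
#'
#' @param data an [observed_data()].
#' @param or_fit a converged OR `fitted_index`.
#' @return the point estimate.
#' @export
or_estimate <- function(data, or_fit) {
  stopifnot(inherits(or_fit, "fitted_index"), or_fit$spec$role == "OR")
  if (!isTRUE(or_fit$converged)) stop("OR fit did not converge", call. = FALSE)
  if (is.null(or_fit$separate) && !is.null(or_fit$treat_coef)) {
    return(or_fit$treat_coef)
  }
  mean(or_predict(or_fit, data$X, 1L) - or_predict(or_fit, data$X, 0L))
}

#' Augmented inverse-probability-weighting (AIPW) estimator
#'
#' Textbook doubly robust combination of one parametric PS fit and one OR
#' fit, with unnormalised weights:
#' `mean(A Y / pi - (A - pi) mu1 / pi) - mean((1-A) Y / (1-pi) + (A - pi) mu0 / (1-pi))`.
#'
#' @param data an [observed_data()].
#' @param ps_fit a converged PS `fitted_index`.
#' @param or_fit a converged OR `fitted_index`.
#' @return the point estimate.
#' @export
aipw_estimate <- function(data, ps_fit, or_fit) {
  stopifnot(inherits(ps_fit, "fitted_index"), ps_fit$spec$role == "PS",
            inherits(or_fit, "fitted_index"), or_fit$spec$role == "OR")
  if (!isTRUE(ps_fit$converged) || !isTRUE(or_fit$converged)) {
    stop("candidate fits must have converged", call. = FALSE)
  }
  pi <- ps_fitted(ps_fit, data$X)
  if (any(pi <= 0 | pi >= 1)) {
    stop("fitted propensities outside (0, 1)", call. = FALSE)
  }
  mu1 <- or_predict(or_fit, data$X, 1L)
  mu0 <- or_predict(or_fit, data$X, 0L)
  A <- data$A
  Y <- data$Y
  mean(A * Y / pi - (A - pi) * mu1 / pi) -
    mean((1 - A) * Y / (1 - pi) + (A - pi) * mu0 / (1 - pi))
}

# Bitmask handling -------------------------------------------------------

parse_bitmask <- function(bitmask, n_ps = 2L, n_or = 2L) {
  if (!grepl(sprintf("^[01]{%d}$", n_ps + n_or), bitmask)) {
    stop(sprintf("bitmask must be %d characters of 0/1", n_ps + n_or),
         call. = FALSE)
  }
  bits <- as.integer(strsplit(bitmask, "")[[1L]]) == 1L
  list(ps = bits[seq_len(n_ps)], or = bits[n_ps + seq_len(n_or)])
}

estimator_label <- function(method, bitmask, extra) {
  suffix <- switch(extra, none = "", `2PS` = "-2PS", `2OR` = "-2OR",
                   `2PS2OR` = "-2PS2OR")
  paste0(method, "-", bitmask, suffix)
}

#' Estimate the ATE with a configured estimator
#'
#' Orchestrates the full pipeline for a named method:
#' \describe{
#'   \item{`"IPW"`}{parametric logistic propensity from the single selected
#'     PS candidate, then Hajek IPW.}
#'   \item{`"OR"`}{single selected OR candidate, outcome-regression
#'     estimator.}
#'   \item{`"AIPW"`}{one selected PS and one selected OR candidate.}
#'   \item{`"Ker.MiPS"` / `"ANN.MiPS"`}{fit all selected candidates, build
#'     the (standardized) multi-index, regress treatment on it by kernel
#'     smoothing or neural network, then Hajek IPW with the integrated
#'     score.  With one PS and one OR index the kernel path is the
#'     double-index estimator.}
#'   \item{`"IPW.ANN"` / `"OR.ANN"`}{the same network architecture applied
#'     directly to the (standardized) raw covariates: a sigmoid-output
#'     network for the propensity, a linear-output network for the outcome
#'     regressed on `(X, A)`.}
#' }
#' The four-digit `bitmask` selects PS1, PS2, OR1, OR2 (left to right);
#' `extra` appends the deliberately incorrect three-covariate candidates to
#' the selection for the robustness scenarios.
#'
#' Neural-network propensities are clipped to `[1e-6, 1 - 1e-6]` before
#' weighting; kernel propensities are not clipped unless `clip = TRUE`, so
#' that out-of-range kernel scores remain observable.
#'
#' @param data an [observed_data()].
#' @param method estimator name, see above.
#' @param bitmask four characters of 0/1 selecting PS1, PS2, OR1, OR2.
#' @param extra `"none"`, `"2PS"`, `"2OR"` or `"2PS2OR"`.
#' @param ps_specs,or_specs candidate [model_spec()] lists; defaults are the
#'   benchmark sets of [ps_model_set()] / [or_model_set()].
#' @param ann an [ann_config()] for the ANN-based methods.
#' @param bandwidths,undersmooth kernel settings, see [nw_mips()].
#' @param clip clip kernel scores into `(0, 1)`?
#' @param standardize standardize the index columns before scoring?
#' @return an object of class `ate_estimate` with elements `estimate`,
#'   `label`, `method` and `diagnostics`.
#' @export
estimate_ate <- function(data, method = c("ANN.MiPS", "Ker.MiPS", "IPW", "OR",
                                          "AIPW", "IPW.ANN", "OR.ANN"),
                         bitmask = "1111",
                         extra = c("none", "2PS", "2OR", "2PS2OR"),
                         ps_specs = NULL, or_specs = NULL,
                         ann = ann_config(),
                         bandwidths = NULL, undersmooth = 1, clip = FALSE,
                         standardize = TRUE) {
  method <- match.arg(method)
  extra <- match.arg(extra)
  ps_specs <- ps_specs %||% ps_model_set(extra %in% c("2PS", "2PS2OR"))
  or_specs <- or_specs %||% or_model_set(extra %in% c("2OR", "2PS2OR"))

  diagnostics <- list()
  result <- function(est, pi = NULL) {
    if (!is.null(pi)) {
      diagnostics$score_range <- range(pi$scores)
      diagnostics$out_of_range <- pi$out_of_range
    }
    structure(list(estimate = est,
                   label = estimator_label(method, bitmask, extra),
                   method = method, bitmask = bitmask, extra = extra,
                   se = NULL, ci = NULL, diagnostics = diagnostics),
              class = "ate_estimate")
  }

  if (method %in% c("IPW.ANN", "OR.ANN")) {
    Xs <- scale(data$X)
    if (method == "IPW.ANN") {
      cfg <- ann
      cfg$output <- "sigmoid"
      model <- train_ann(Xs, data$A, cfg)
      pi <- predict(model, Xs)
      pi$scores <- pmin(pmax(pi$scores, 1e-6), 1 - 1e-6)
      pi$clipped <- TRUE
      return(result(hajek_ipw(data$Y, data$A, pi), pi))
    }
    # OR.ANN: network regression of the (scaled) outcome on (X, A)
    cfg <- ann
    cfg$output <- "linear"
    mu_y <- mean(data$Y)
    sd_y <- sd(data$Y)
    D <- cbind(Xs, A = data$A)
    model <- train_ann(D, (data$Y - mu_y) / sd_y, cfg)
    pred <- function(a) {
      mu_y + sd_y * predict(model, cbind(Xs, A = rep(a, nrow(Xs))))
    }
    return(result(mean(pred(1) - pred(0))))
  }

  sel <- parse_bitmask(bitmask)
  use_ps <- which(sel$ps)
  use_or <- which(sel$or)
  if (extra %in% c("2PS", "2PS2OR")) use_ps <- c(use_ps, 3L, 4L)
  if (extra %in% c("2OR", "2PS2OR")) use_or <- c(use_or, 3L, 4L)

  if (method == "IPW") {
    if (length(use_ps) != 1L || length(use_or) != 0L) {
      stop("IPW needs a bitmask selecting exactly one PS model", call. = FALSE)
    }
    fit <- fit_ps_model(data, ps_specs[[use_ps]])
    if (!fit$converged) stop("PS model did not converge", call. = FALSE)
    pi <- propensity_vector(ps_fitted(fit, data$X), method = "parametric")
    return(result(hajek_ipw(data$Y, data$A, pi), pi))
  }
  if (method == "OR") {
    if (length(use_or) != 1L || length(use_ps) != 0L) {
      stop("OR needs a bitmask selecting exactly one OR model", call. = FALSE)
    }
    fit <- fit_or_model(data, or_specs[[use_or]])
    return(result(or_estimate(data, fit)))
  }
  if (method == "AIPW") {
    if (length(use_ps) != 1L || length(use_or) != 1L) {
      stop("AIPW needs exactly one PS and one OR model", call. = FALSE)
    }
    ps_fit <- fit_ps_model(data, ps_specs[[use_ps]])
    or_fit <- fit_or_model(data, or_specs[[use_or]])
    if (!ps_fit$converged) stop("PS model did not converge", call. = FALSE)
    return(result(aipw_estimate(data, ps_fit, or_fit)))
  }

  # multi-index methods
  if (length(use_ps) + length(use_or) == 0L) {
    stop("all-zero bitmask: no candidate model selected", call. = FALSE)
  }
  ps_fits <- lapply(ps_specs[use_ps], fit_ps_model, data = data)
  or_fits <- lapply(or_specs[use_or], fit_or_model, data = data)
  diagnostics$converged <- vapply(c(ps_fits, or_fits),
                                  function(f) isTRUE(f$converged), logical(1L))
  S <- suppressWarnings(
    build_index_matrix(data, ps_fits, or_fits, standardize = standardize)
  )
  if (method == "Ker.MiPS") {
    pi <- nw_mips(S, data$A, bandwidths = bandwidths, undersmooth = undersmooth)
    if (clip) {
      pi$scores <- pmin(pmax(pi$scores, 1e-6), 1 - 1e-6)
      pi$clipped <- TRUE
    }
  } else {
    model <- train_ann(S, data$A, ann)
    pi <- predict(model, S)
    pi$scores <- pmin(pmax(pi$scores, 1e-6), 1 - 1e-6)
    pi$clipped <- TRUE
  }
  result(hajek_ipw(data$Y, data$A, pi), pi)
}

#' @export
print.ate_estimate <- function(x, ...) {
  cat(sprintf("<ate_estimate> %s: %.4f", x$label, x$estimate))
  if (!is.null(x$se)) cat(sprintf("  (SE %.4f)", x$se))
  if (!is.null(x$ci)) cat(sprintf("  95%% CI [%.4f, %.4f]", x$ci[1L], x$ci[2L]))
  cat("\n")
  invisible(x)
}
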