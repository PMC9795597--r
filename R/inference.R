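# Bootstrap standard errors and Wald confidence intervals.

#' Bootstrap standard error of an estimator
#'
#' Draws `B` resamples of size `n` with replacement and re-runs the full
#' estimation pipeline on each (candidate models are refitted and any neural
#' network retrained with a resample-specific derived seed).  Resamples in
#' which the treatment is single-class, or on which the estimator fails, are
#' redrawn and counted so that exactly `B` estimates enter the standard
#' deviation (denominator `B - 1`).
#'
#' @param data an [observed_data()].
#' @param statistic function `(data, seed) -> numeric` computing the point
#'   estimate; `seed` feeds any internal randomness (e.g. network
#'   initialisation).
#' @param B number of bootstrap resamples.
#' @param seed master seed; resample draws and statistic seeds are pure
#'   functions of it.
#' @param max_redraws cap on total redraws before aborting.
#' @return the bootstrap SE (numeric scalar) with attributes `estimates`
#'   (the `B` resample estimates) and `n_redraws`.
#' @export
bootstrap_se <- function(data, statistic, B = 100L, seed = 1L,
                         max_redraws = 10L * B) {
  stopifnot(B >= 2L)
  n <- length(data$Y)
  ests <- numeric(B)
  redraws <- 0L
  b <- 1L
  draw <- 0L
  while (b <= B) {
    draw <- draw + 1L
    idx <- with_seed(derive_seed(seed, draw, stream = 1L),
                     sample.int(n, n, replace = TRUE))
    Ab <- data$A[idx]
    if (length(unique(Ab)) < 2L) {
      redraws <- redraws + 1L
      if (redraws > max_redraws) {
        stop("maximum bootstrap redraws exceeded", call. = FALSE)
      }
      next
    }
    db <- observed_data(data$Y[idx], Ab, data$X[idx, , drop = FALSE])
    val <- tryCatch(
      suppressWarnings(statistic(db, derive_seed(seed, draw, stream = 2L))),
      error = function(e) NA_real_
    )
    if (!is.finite(val)) {
      redraws <- redraws + 1L
      if (redraws > max_redraws) {
        stop("maximum bootstrap redraws exceeded", call. = FALSE)
      }
      next
    }
    ests[b] <- val
    b <- b + 1L
  }
  structure(sd(ests), estimates = ests, n_redraws = redraws)
}

#' Wald confidence interval
#'
#' `estimate +/- z * se`.  For the default 95% level the conventional
#' two-decimal critical value `z = 1.96` is used; other levels use the exact
#' normal quantile.
#'
#' @param estimate point estimate.
#' @param se non-negative standard error.
#' @param level confidence level.
#' @param z optional critical value overriding the default.
#' @return numeric vector `c(lo, hi)`.
#' @export
wald_ci <- function(estimate, se, level = 0.95, z = NULL) {
  if (se < 0) stop("`se` must be non-negative", call. = FALSE)
  if (is.null(z)) {
    z <- if (identical(level, 0.95)) 1.96 else qnorm(1 - (1 - level) / 2)
  }
  c(estimate - z * se, estimate + z * se)
}

#' Point estimate with bootstrap SE and Wald interval
#'
#' Convenience wrapper: runs [estimate_ate()], then [bootstrap_se()] on the
#' identical pipeline, and attaches `se` and `ci` to the estimate.
#'
#' @inheritParams estimate_ate
#' @param B bootstrap resamples.
#' @param seed master seed driving the resamples, the main fit's network
#'   initialisation and each resample's retraining.
#' @param level confidence level for the Wald interval.
#' @return an `ate_estimate` with `se` and `ci` filled in.
#' @export
estimate_with_ci <- function(data, method = "ANN.MiPS", bitmask = "1111",
                             extra = "none", B = 100L, seed = 1L,
                             level = 0.95, ann = ann_config(), ...) {
  ann$seed <- derive_seed(seed, 0L, stream = 2L)
  est <- estimate_ate(data, method = method, bitmask = bitmask, extra = extra,
                      ann = ann, ...)
  stat <- function(d, s) {
    a <- ann
    a$seed <- s
    estimate_ate(d, method = method, bitmask = bitmask, extra = extra,
                 ann = a, ...)$estimate
  }
  se <- bootstrap_se(data, stat, B = B, seed = seed)
  est$se <- as.numeric(se)
  est$n_redraws <- attr(se, "n_redraws")
  est$ci <- wald_ci(est$estimate, est$se, level = level)
  est
}
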