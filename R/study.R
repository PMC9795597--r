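# Monte Carlo evaluation harness: repeated draws from the generating
# process, a panel of configured estimators, and the five summary metrics
# (percentage bias, RMSE, Monte Carlo SE, bootstrap SE, CI coverage).

#' Monte Carlo metrics for one estimator
#'
#' Given the `R` replication estimates (and optionally their per-replication
#' bootstrap SEs) computes
#' `BIAS% = 100 (mean - truth) / truth`,
#' `RMSE = sqrt(mean((est - truth)^2))`,
#' `MC-SE = sd(est)` (denominator `R - 1`),
#' `BS-SE = mean(se)` and
#' `CI-Cov = 100 * mean(|est - truth| <= 1.96 se)`.
#'
#' @param estimates numeric vector of replication estimates.
#' @param ses optional vector of bootstrap SEs (same length).
#' @param truth true ATE; must be nonzero for the relative bias.
#' @return one-row data frame with columns `bias_pct`, `rmse`, `mc_se`,
#'   `bs_se`, `ci_cov`.
#' @export
compute_metrics <- function(estimates, ses = NULL, truth) {
  R <- length(estimates)
  stopifnot(R >= 1L)
  if (truth == 0) {
    stop("relative bias undefined for truth = 0", call. = FALSE)
  }
  if (!is.null(ses)) {
    stopifnot(length(ses) == R, all(ses >= 0))
  }
  data.frame(
    bias_pct = 100 * (mean(estimates) - truth) / truth,
    rmse = sqrt(mean((estimates - truth)^2)),
    mc_se = if (R > 1L) sd(estimates) else 0,
    bs_se = if (is.null(ses)) NA_real_ else mean(ses),
    ci_cov = if (is.null(ses)) NA_real_ else
      100 * mean(abs(estimates - truth) <= 1.96 * ses)
  )
}

#' Declare one estimator for a Monte Carlo study
#'
#' @param method estimator name, see [estimate_ate()]; alternatively a
#'   function `(data, seed) -> numeric` for a user-supplied estimator.
#' @param bitmask candidate-model selection (four characters of 0/1).
#' @param extra extra incorrect-model scenario, see [estimate_ate()].
#' @param label optional display label; defaults to `method-bitmask[-extra]`.
#' @return a list understood by [run_study()].
#' @export
study_estimator <- function(method, bitmask = "1111", extra = "none",
                            label = NULL) {
  if (is.function(method)) {
    if (is.null(label)) stop("a callable estimator needs a label", call. = FALSE)
    return(list(method = method, bitmask = bitmask, extra = extra,
                label = label))
  }
  list(method = method, bitmask = bitmask, extra = extra,
       label = label %||% estimator_label(method, bitmask, extra))
}

#' Configure a Monte Carlo study
#'
#' @param dgp a [dgp_config()] describing the generating process.
#' @param replications number of Monte Carlo replications.
#' @param estimators list of [study_estimator()] entries.
#' @param bootstrap_B bootstrap resamples per replication, or `NULL` to skip
#'   bootstrap SEs (then `bs_se` and `ci_cov` are `NA`).
#' @param seed master seed; every replication, resample and network
#'   initialisation derives its own seed from it.
#' @param ann base [ann_config()] for ANN-based estimators (its seed is
#'   overridden per replication).
#' @param workers parallel workers (forked); results are invariant to the
#'   worker count because all seeds are derived per replication.
#' @return an object of class `study_config`.
#' @export
study_config <- function(dgp, replications = 1000L, estimators,
                         bootstrap_B = NULL, seed = 1L,
                         ann = ann_config(), workers = 1L) {
  stopifnot(inherits(dgp, "dgp_config"), replications >= 1L,
            length(estimators) >= 1L)
  if (!is.null(bootstrap_B)) stopifnot(bootstrap_B >= 2L)
  structure(list(dgp = dgp, replications = as.integer(replications),
                 estimators = estimators, bootstrap_B = bootstrap_B,
                 seed = seed, ann = ann, workers = as.integer(workers)),
            class = "study_config")
}

run_one_replication <- function(cfg, r) {
  rep_seed <- derive_seed(cfg$seed, r, stream = 0L)
  data <- gen_dataset(cfg$dgp, seed = rep_seed)
  out <- lapply(seq_along(cfg$estimators), function(e) {
    est_cfg <- cfg$estimators[[e]]
    ann <- cfg$ann
    ann$seed <- derive_seed(rep_seed, e, stream = 3L)
    point <- tryCatch(
      suppressWarnings(
        if (is.function(est_cfg$method)) {
          est_cfg$method(data, ann$seed)
        } else {
          estimate_ate(data, method = est_cfg$method, bitmask = est_cfg$bitmask,
                       extra = est_cfg$extra, ann = ann)$estimate
        }
      ),
      error = function(err) NA_real_
    )
    se <- NA_real_
    if (!is.null(cfg$bootstrap_B) && is.finite(point) &&
        !is.function(est_cfg$method)) {
      stat <- function(d, s) {
        a <- cfg$ann
        a$seed <- s
        estimate_ate(d, method = est_cfg$method, bitmask = est_cfg$bitmask,
                     extra = est_cfg$extra, ann = a)$estimate
      }
      se <- tryCatch(
        as.numeric(bootstrap_se(data, stat, B = cfg$bootstrap_B,
                                seed = derive_seed(rep_seed, e, stream = 4L))),
        error = function(err) NA_real_
      )
    }
    c(point = point, se = se)
  })
  do.call(rbind, out)
}

#' Run a Monte Carlo study
#'
#' For each replication a fresh dataset is generated with a derived seed,
#' every configured estimator is computed (with a bootstrap SE when
#' configured), and the results are aggregated with [compute_metrics()]
#' against the generating process's true ATE.  Replications on which an
#' estimator fails are excluded from that estimator's metrics and counted in
#' `n_failed`.
#'
#' @param cfg a [study_config()].
#' @return a data frame (class `sim_result`) with one row per estimator:
#'   `estimator`, `bias_pct`, `rmse`, `mc_se`, `bs_se`, `ci_cov`, `n_failed`.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  reps <- seq_len(cfg$replications)
  if (cfg$workers > 1L &&
      requireNamespace("parallel", quietly = TRUE) &&
      .Platform$OS.type == "unix") {
    raw <- parallel::mclapply(reps, function(r) run_one_replication(cfg, r),
                              mc.cores = cfg$workers)
  } else {
    raw <- lapply(reps, function(r) run_one_replication(cfg, r))
  }
  truth <- true_ate(cfg$dgp)
  rows <- lapply(seq_along(cfg$estimators), function(e) {
    points <- vapply(raw, function(m) m[e, "point"], numeric(1L))
    ses <- vapply(raw, function(m) m[e, "se"], numeric(1L))
    ok <- is.finite(points)
    if (!is.null(cfg$bootstrap_B)) ok <- ok & is.finite(ses)
    met <- compute_metrics(points[ok],
                           ses = if (is.null(cfg$bootstrap_B)) NULL else ses[ok],
                           truth = truth)
    cbind(data.frame(estimator = cfg$estimators[[e]]$label), met,
          data.frame(n_failed = sum(!ok)))
  })
  res <- do.call(rbind, rows)
  attr(res, "truth") <- truth
  attr(res, "replications") <- cfg$replications
  class(res) <- c("sim_result", "data.frame")
  res
}

#' @export
print.sim_result <- function(x, digits = 3L, ...) {
  cat(sprintf("Monte Carlo study: %d replications, true ATE %.4g\n\n",
              attr(x, "replications"), attr(x, "truth")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}
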