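# Candidate parametric models for the propensity score (logistic) and the
# outcome regression (linear).  Only the fitted slope vector of each model is
# carried forward: it defines one column of the multi-index.

#' Specify a candidate model
#'
#' A candidate model is an ordered list of covariate transforms (term
#' strings such as `"X1"` or `"X3^2"`), a role (`"PS"` for the logistic
#' treatment model, `"OR"` for the linear outcome model) and a label.  OR
#' models include the treatment indicator as a regressor unless
#' `include_treatment = FALSE`.
#'
#' @param role `"PS"` or `"OR"`.
#' @param terms character vector of transform strings, e.g. `c("X1", "X2^2")`;
#'   may be empty for an intercept-only (or intercept-plus-treatment) model.
#' @param label unique label, e.g. `"PS1"`.
#' @param include_treatment should the OR design include `A`? Ignored for PS.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(role = c("PS", "OR"), terms = character(), label,
                       include_treatment = (role == "OR")) {
  role <- match.arg(role)
  stopifnot(is.character(terms), nzchar(label))
  if (role == "PS" && isTRUE(include_treatment)) {
    stop("a PS model cannot include the treatment", call. = FALSE)
  }
  structure(list(role = role, terms = terms, label = label,
                 include_treatment = isTRUE(include_treatment)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s [%s]: %s%s\n", x$label, x$role,
              paste(x$terms, collapse = " + "),
              if (x$include_treatment) " + A" else ""))
  invisible(x)
}

# evaluate one term string ("X3", "X3^2", "log(X3)") against the covariates
eval_term <- function(term, covs) {
  e <- tryCatch(parse(text = term)[[1L]], error = function(err) {
    stop(sprintf("cannot parse term '%s'", term), call. = FALSE)
  })
  env <- as.data.frame(covs)
  v <- eval(e, envir = env)
  if (length(v) != nrow(covs)) {
    stop(sprintf("term '%s' does not evaluate to one value per row", term),
         call. = FALSE)
  }
  as.numeric(v)
}

# n x length(terms) matrix of transformed covariates (no intercept, no A)
term_matrix <- function(spec, X) {
  X <- as.matrix(X)
  if (length(spec$terms) == 0L) {
    return(matrix(numeric(0), nrow = nrow(X), ncol = 0L))
  }
  M <- vapply(spec$terms, eval_term, numeric(nrow(X)), covs = X)
  matrix(M, nrow = nrow(X), dimnames = list(NULL, spec$terms))
}

check_full_rank <- function(D, what) {
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[qrD$pivot[(qrD$rank + 1L):ncol(D)]]
    stop(sprintf("%s design is rank deficient; collinear terms: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(NULL)
}

new_fitted_index <- function(spec, intercept, slopes, treat_coef = NULL,
                             converged = TRUE, n_iter = NA_integer_,
                             fit = NULL, separate = NULL) {
  structure(list(spec = spec, intercept = intercept, slopes = slopes,
                 treat_coef = treat_coef, converged = converged,
                 n_iter = n_iter, fit = fit, separate = separate),
            class = "fitted_index")
}

#' @export
print.fitted_index <- function(x, ...) {
  cat(sprintf("<fitted_index> %s [%s] converged=%s\n", x$spec$label,
              x$spec$role, x$converged))
  print(c(`(Intercept)` = x$intercept, x$slopes,
          if (!is.null(x$treat_coef)) c(A = x$treat_coef)))
  invisible(x)
}

#' Fit a candidate propensity-score model
#'
#' Maximum-likelihood logistic regression of the treatment on the spec's
#' transformed covariates (iteratively reweighted least squares).  A fit is
#' flagged `converged = FALSE` when the response is single-class, when IRLS
#' fails to converge, when the coefficients diverge (separation) or when the
#' score equations are not solved to tolerance.
#'
#' @param data an [observed_data()].
#' @param spec a PS [model_spec()].
#' @param maxit maximum IRLS iterations.
#' @return a `fitted_index` with the intercept and index slopes.
#' @export
fit_ps_model <- function(data, spec, maxit = 100L) {
  stopifnot(inherits(spec, "model_spec"), spec$role == "PS")
  M <- term_matrix(spec, data$X)
  check_full_rank(cbind(`(Intercept)` = 1, M), sprintf("PS model %s", spec$label))
  if (length(unique(data$A)) < 2L) {
    return(new_fitted_index(spec, NA_real_, stats::setNames(
      rep(NA_real_, ncol(M)), colnames(M)), converged = FALSE, n_iter = 0L))
  }
  D <- cbind(`(Intercept)` = 1, M)
  fit <- suppressWarnings(
    stats::glm.fit(D, data$A, family = binomial(),
                   control = stats::glm.control(epsilon = 1e-12, maxit = maxit))
  )
  cf <- fit$coefficients
  p <- fit$fitted.values
  # score (gradient of the log-likelihood) at the reported optimum
  grad <- drop(crossprod(D, data$A - p))
  separated <- any(abs(cf) > 1e3) || any(p < 1e-12) || any(p > 1 - 1e-12)
  converged <- isTRUE(fit$converged) && !separated &&
    max(abs(grad)) <= 1e-6 * max(1, nrow(D))
  new_fitted_index(spec, unname(cf[1L]),
                   stats::setNames(unname(cf[-1L]), colnames(M)),
                   converged = converged, n_iter = fit$iter, fit = fit)
}

#' Fit a candidate outcome-regression model
#'
#' Ordinary least squares of the outcome on the spec's transformed covariates
#' plus (by default) the treatment indicator.  With `separate = TRUE` the
#' model (without `A`) is fitted separately within the treated and control
#' groups, accommodating treatment-covariate interactions; such a fit
#' contributes two index columns.
#'
#' @param data an [observed_data()].
#' @param spec an OR [model_spec()].
#' @param separate fit treated and control groups separately?
#' @return a `fitted_index`; for joint fits `treat_coef` holds the
#'   coefficient of `A`.
#' @export
fit_or_model <- function(data, spec, separate = FALSE) {
  stopifnot(inherits(spec, "model_spec"), spec$role == "OR")
  M <- term_matrix(spec, data$X)
  if (separate) {
    fits <- lapply(c(1L, 0L), function(a) {
      idx <- data$A == a
      if (sum(idx) <= ncol(M) + 1L) {
        stop(sprintf("group A=%d too small for OR model %s", a, spec$label),
             call. = FALSE)
      }
      Dg <- cbind(`(Intercept)` = 1, M[idx, , drop = FALSE])
      check_full_rank(Dg, sprintf("OR model %s (A=%d)", spec$label, a))
      stats::lm.fit(Dg, data$Y[idx])
    })
    cf1 <- fits[[1L]]$coefficients
    cf0 <- fits[[2L]]$coefficients
    return(new_fitted_index(
      spec, unname(cf0[1L]), stats::setNames(unname(cf0[-1L]), colnames(M)),
      treat_coef = NULL, converged = TRUE, n_iter = 1L,
      separate = list(
        treated = list(intercept = unname(cf1[1L]),
                       slopes = stats::setNames(unname(cf1[-1L]), colnames(M))),
        control = list(intercept = unname(cf0[1L]),
                       slopes = stats::setNames(unname(cf0[-1L]), colnames(M))))
    ))
  }
  D <- cbind(`(Intercept)` = 1, M)
  if (spec$include_treatment) D <- cbind(D, A = data$A)
  if (nrow(D) <= ncol(D)) {
    stop("not enough rows to fit the OR model", call. = FALSE)
  }
  check_full_rank(D, sprintf("OR model %s", spec$label))
  fit <- stats::lm.fit(D, data$Y)
  cf <- fit$coefficients
  new_fitted_index(
    spec, unname(cf["(Intercept)"]),
    stats::setNames(unname(cf[colnames(M)]), colnames(M)),
    treat_coef = if (spec$include_treatment) unname(cf["A"]) else NULL,
    converged = TRUE, n_iter = 1L, fit = fit
  )
}

# linear predictor of an OR fit at treatment level a
or_predict <- function(fit, X, a) {
  M <- term_matrix(fit$spec, X)
  if (!is.null(fit$separate)) {
    part <- if (a == 1) fit$separate$treated else fit$separate$control
    part$intercept + drop(M %*% part$slopes)
  } else {
    tc <- if (!is.null(fit$treat_coef)) fit$treat_coef else 0
    fit$intercept + drop(M %*% fit$slopes) + a * tc
  }
}

# Index matrix -----------------------------------------------------------

#' Build the multi-index regressor matrix
#'
#' Each converged candidate fit contributes the linear index
#' `slopes' T(X)` (intercept and treatment coefficient excluded); a
#' group-separate OR fit contributes one column per group.  With
#' `standardize = TRUE` (the default) every column is centred and scaled to
#' unit sample standard deviation and the transform parameters are stored for
#' reuse on new rows.  A zero-variance column is replaced by zeros with a
#' warning.
#'
#' @param data an [observed_data()].
#' @param ps_fits,or_fits lists of `fitted_index` objects (either may be
#'   empty, not both).
#' @param standardize centre/scale the index columns?
#' @return an object of class `index_matrix` with elements `S`, `center`,
#'   `scale`.
#' @export
build_index_matrix <- function(data, ps_fits = list(), or_fits = list(),
                               standardize = TRUE) {
  if (inherits(ps_fits, "fitted_index")) ps_fits <- list(ps_fits)
  if (inherits(or_fits, "fitted_index")) or_fits <- list(or_fits)
  fits <- c(ps_fits, or_fits)
  if (length(fits) == 0L) stop("need at least one candidate fit", call. = FALSE)
  for (f in fits) {
    if (!isTRUE(f$converged)) {
      stop(sprintf("candidate model %s did not converge", f$spec$label),
           call. = FALSE)
    }
  }
  cols <- list()
  for (f in fits) {
    M <- term_matrix(f$spec, data$X)
    if (!is.null(f$separate)) {
      cols[[paste0(f$spec$label, ".t")]] <- drop(M %*% f$separate$treated$slopes)
      cols[[paste0(f$spec$label, ".c")]] <- drop(M %*% f$separate$control$slopes)
    } else {
      cols[[f$spec$label]] <- drop(M %*% f$slopes)
    }
  }
  S <- do.call(cbind, cols)
  colnames(S) <- names(cols)
  ctr <- rep(0, ncol(S))
  scl <- rep(1, ncol(S))
  zero_var <- logical(ncol(S))
  for (j in seq_len(ncol(S))) {
    sj <- sd(S[, j])
    if (!is.finite(sj) || sj < 1e-12) {
      zero_var[j] <- TRUE
      S[, j] <- 0
      warning(sprintf("index column '%s' has zero variance; replaced by zeros",
                      colnames(S)[j]), call. = FALSE)
    } else if (standardize) {
      ctr[j] <- mean(S[, j])
      scl[j] <- sj
      S[, j] <- (S[, j] - ctr[j]) / scl[j]
    }
  }
  structure(list(S = S, center = ctr, scale = scl,
                 standardized = standardize, zero_var = zero_var),
            class = "index_matrix")
}

#' @export
print.index_matrix <- function(x, ...) {
  cat(sprintf("<index_matrix> n = %d, d = %d (%s)\n", nrow(x$S), ncol(x$S),
              if (x$standardized) "standardized" else "raw"))
  invisible(x)
}

# Preset candidate model sets --------------------------------------------

#' Benchmark candidate model sets
#'
#' `ps_model_set()` returns the two benchmark propensity-score candidates:
#' `PS1` linear in `X1..X7` (correct under the default generating process)
#' and `PS2` in squared terms (incorrect).  `or_model_set()` returns the two
#' outcome-regression candidates on `X1..X4, X8..X10` plus treatment, linear
#' (`OR1`, correct) and squared (`OR2`, incorrect).  With
#' `extra = TRUE` two additional deliberately incorrect models on three
#' covariates (linear and squared) are appended, as used in the
#' extra-incorrect-model robustness scenarios.
#'
#' @param extra append the two extra incorrect candidates?
#' @return list of [model_spec()] objects.
#' @export
ps_model_set <- function(extra = FALSE) {
  out <- list(
    model_spec("PS", paste0("X", 1:7), "PS1"),
    model_spec("PS", paste0("X", 1:7, "^2"), "PS2")
  )
  if (extra) {
    out <- c(out, list(
      model_spec("PS", paste0("X", 1:3), "PS3"),
      model_spec("PS", paste0("X", 1:3, "^2"), "PS4")
    ))
  }
  out
}

#' @rdname ps_model_set
#' @export
or_model_set <- function(extra = FALSE) {
  or_vars <- paste0("X", c(1:4, 8:10))
  out <- list(
    model_spec("OR", or_vars, "OR1"),
    model_spec("OR", paste0(or_vars, "^2"), "OR2")
  )
  if (extra) {
    out <- c(out, list(
      model_spec("OR", paste0("X", 1:3), "OR3"),
      model_spec("OR", paste0("X", 1:3, "^2"), "OR4")
    ))
  }
  out
}
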