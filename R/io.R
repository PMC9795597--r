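# Dataset and configuration I/O.  Datasets travel as headered CSV with
# columns Y, A, X1..Xp (optionally Y1, Y0); configurations as YAML
# documents validated against a fixed schema.

#' Read an observational dataset from CSV
#'
#' @param path CSV file with a header.
#' @param y,a names of the outcome and treatment columns.
#' @param x names of the covariate columns; default: every other numeric
#'   column except retained potential-outcome columns.
#' @return an [observed_data()].
#' @export
read_dataset <- function(path, y = "Y", a = "A", x = NULL) {
  df <- read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty dataset", call. = FALSE)
  for (col in c(y, a)) {
    if (!col %in% names(df)) {
      stop(sprintf("column '%s' not found", col), call. = FALSE)
    }
  }
  if (is.null(x)) x <- setdiff(names(df), c(y, a, "Y1", "Y0"))
  missing_rows <- which(!stats::complete.cases(df[c(y, a, x)]))
  if (length(missing_rows) > 0L) {
    stop(sprintf("missing values in row(s): %s",
                 paste(utils::head(missing_rows, 10L), collapse = ", ")),
         call. = FALSE)
  }
  Av <- df[[a]]
  bad <- which(!(Av %in% c(0, 1)))
  if (length(bad) > 0L) {
    stop(sprintf("treatment column '%s' must be 0/1; offending row(s): %s",
                 a, paste(utils::head(bad, 10L), collapse = ", ")),
         call. = FALSE)
  }
  if (!is.numeric(df[[y]])) {
    stop(sprintf("outcome column '%s' must be numeric", y), call. = FALSE)
  }
  X <- as.matrix(df[x])
  if (!is.numeric(X)) stop("covariate columns must be numeric", call. = FALSE)
  observed_data(df[[y]], Av, X,
                Y1 = if ("Y1" %in% names(df)) df[["Y1"]],
                Y0 = if ("Y0" %in% names(df)) df[["Y0"]])
}

#' Write an observational dataset to CSV
#'
#' @param data an [observed_data()].
#' @param path output path.
#' @param keep_potential include the potential-outcome columns when the
#'   generator retained them?
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, keep_potential = FALSE) {
  df <- data.frame(Y = data$Y, A = data$A, data$X, check.names = FALSE)
  if (keep_potential && !is.null(attr(data, "Y1"))) {
    df$Y1 <- attr(data, "Y1")
    df$Y0 <- attr(data, "Y0")
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Configuration schema ----------------------------------------------------

config_defaults <- function() {
  list(
    dgp = list(n = 1000L, alpha0 = 0, corr = "identity", rho = NULL,
               seed = NULL, noise_sd = 1),
    scoring = list(
      method = "ann",
      kernel = list(bandwidth_rule = "scott", undersmooth = 1),
      ann = list(epochs = 1000L, learning_rate = 0.001, momentum = 0.5,
                 init_scale = 0.3, seed = 1L, batch = "online")
    ),
    bootstrap = list(B = 100L, seed = 1L),
    study = list(replications = 1000L, workers = 1L, seed = 1L,
                 estimators = list())
  )
}

check_known_keys <- function(doc, template, path = "") {
  bad <- setdiff(names(doc), names(template))
  if (length(bad) > 0L) {
    stop(sprintf("unknown configuration key(s)%s: %s",
                 if (nzchar(path)) paste0(" under '", path, "'") else "",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  for (k in names(doc)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]])) &&
        k != "estimators" && is.list(doc[[k]])) {
      check_known_keys(doc[[k]], template[[k]],
                       if (nzchar(path)) paste(path, k, sep = ".") else k)
    }
  }
  invisible(NULL)
}

merge_config <- function(defaults, doc) {
  for (k in names(doc)) {
    if (is.list(defaults[[k]]) && is.list(doc[[k]]) && k != "estimators") {
      defaults[[k]] <- merge_config(defaults[[k]], doc[[k]])
    } else {
      defaults[[k]] <- doc[[k]]
    }
  }
  defaults
}

#' Validate a configuration document
#'
#' Accepts a YAML file path or a nested list, rejects unknown keys, checks
#' value ranges and fills in defaults (1000 network epochs, 100 bootstrap
#' resamples, identity covariate correlation, ...).
#'
#' @param document path to a YAML file, or a nested list.
#' @return the completed configuration (class `run_config`).
#' @export
validate_config <- function(document) {
  if (is.character(document)) {
    # keep YAML 1.1 boolean-like scalars ("n", "y", "no", ...) as literal
    # strings so that the key `n:` is not read as the boolean FALSE; the
    # schema has no boolean-valued entries
    keep <- function(x) x
    document <- yaml::read_yaml(document,
                                handlers = list("bool#yes" = keep,
                                                "bool#no" = keep))
  }
  stopifnot(is.list(document))
  defaults <- config_defaults()
  check_known_keys(document, defaults)
  cfg <- merge_config(defaults, document)

  errs <- character()
  add <- function(msg) errs <<- c(errs, msg)
  if (cfg$dgp$n < 1) add("dgp.n must be >= 1")
  if (!cfg$dgp$corr %in% c("identity", "exchangeable", "ar1")) {
    add("dgp.corr must be identity, exchangeable or ar1")
  }
  if (cfg$dgp$corr != "identity" && is.null(cfg$dgp$rho)) {
    add("dgp.rho required for non-identity correlation")
  }
  if (cfg$dgp$noise_sd <= 0) add("dgp.noise_sd must be positive")
  sa <- cfg$scoring$ann
  if (sa$learning_rate <= 0 || sa$learning_rate >= 1) {
    add("scoring.ann.learning_rate must be in (0, 1)")
  }
  if (sa$momentum < 0 || sa$momentum >= 1) {
    add("scoring.ann.momentum must be in [0, 1)")
  }
  if (sa$epochs < 1) add("scoring.ann.epochs must be >= 1")
  if (!cfg$scoring$method %in% c("ann", "kernel")) {
    add("scoring.method must be ann or kernel")
  }
  if (cfg$scoring$kernel$undersmooth <= 0) {
    add("scoring.kernel.undersmooth must be positive")
  }
  if (cfg$bootstrap$B != 0 && cfg$bootstrap$B < 2) {
    add("bootstrap.B must be 0 (disabled) or >= 2")
  }
  if (cfg$study$replications < 1) add("study.replications must be >= 1")
  for (e in cfg$study$estimators) {
    if (is.null(e$method)) {
      add("every study estimator needs a method")
      next
    }
    bm <- e$bitmask %||% "1111"
    if (!grepl("^[01]{4}$", bm)) {
      add(sprintf("invalid bitmask '%s'", bm))
    } else if (grepl("MiPS", e$method) && bm == "0000" &&
               (e$extra %||% "none") == "none") {
      add(sprintf("estimator %s-0000 selects no candidate model", e$method))
    }
  }
  if (length(errs) > 0L) {
    stop(paste0("invalid configuration:\n  - ",
                paste(errs, collapse = "\n  - ")), call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

#' Build a [dgp_config()] from a validated configuration
#'
#' @param cfg a `run_config` from [validate_config()].
#' @return a [dgp_config()].
#' @export
config_to_dgp <- function(cfg) {
  corr <- switch(cfg$dgp$corr,
                 identity = corr_identity(10L),
                 exchangeable = corr_exchangeable(10L, cfg$dgp$rho),
                 ar1 = corr_ar1(10L, cfg$dgp$rho))
  dgp_config(n = cfg$dgp$n, alpha0 = cfg$dgp$alpha0, corr = corr,
             seed = cfg$dgp$seed, noise_sd = cfg$dgp$noise_sd)
}

#' Build an [ann_config()] from a validated configuration
#'
#' @param cfg a `run_config` from [validate_config()].
#' @return an [ann_config()].
#' @export
config_to_ann <- function(cfg) {
  a <- cfg$scoring$ann
  ann_config(epochs = a$epochs, learning_rate = a$learning_rate,
             momentum = a$momentum, init_scale = a$init_scale,
             seed = a$seed, batch = a$batch)
}
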