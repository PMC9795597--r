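# Integrated propensity scores: nonparametric regression of the treatment on
# the multi-index, by a multivariate Nadaraya-Watson kernel smoother or by a
# small feed-forward neural network.

as_index <- function(S) {
  if (inherits(S, "index_matrix")) S$S else as.matrix(S)
}

#' Propensity-score vector with range diagnostics
#'
#' @param scores numeric vector of estimated treatment probabilities.
#' @param method `"kernel"`, `"ann"` or `"parametric"`.
#' @param clipped were scores clipped into `(0, 1)`?
#' @return an object of class `propensity_vector`; `out_of_range` counts
#'   scores outside `[0, 1]`.
#' @export
propensity_vector <- function(scores, method = c("kernel", "ann", "parametric"),
                              clipped = FALSE) {
  method <- match.arg(method)
  structure(list(scores = as.numeric(scores), method = method,
                 out_of_range = sum(scores < 0 | scores > 1),
                 clipped = clipped),
            class = "propensity_vector")
}

#' @export
print.propensity_vector <- function(x, ...) {
  cat(sprintf("<propensity_vector> method=%s n=%d range=[%.4g, %.4g] out_of_range=%d\n",
              x$method, length(x$scores), min(x$scores), max(x$scores),
              x$out_of_range))
  invisible(x)
}

#' Scott-type bandwidths for the kernel smoother
#'
#' Per-dimension rule `h_j = undersmooth * sd_j * n^(-1/(d+4))`, the
#' multivariate normal-reference scaling for a `d`-dimensional regressor.
#'
#' @param S index matrix (or [build_index_matrix()] result).
#' @param undersmooth positive multiplier applied to every bandwidth.
#' @return numeric bandwidth vector of length `d`.
#' @export
scott_bandwidth <- function(S, undersmooth = 1) {
  S <- as_index(S)
  n <- nrow(S)
  d <- ncol(S)
  if (n < 2L) stop("need at least 2 rows to choose a bandwidth", call. = FALSE)
  stopifnot(undersmooth > 0)
  sds <- apply(S, 2L, sd)
  if (any(sds <= 0)) {
    stop(sprintf("zero-variance index column(s): %s",
                 paste(which(sds <= 0), collapse = ", ")), call. = FALSE)
  }
  undersmooth * sds * n^(-1 / (d + 4))
}

#' Kernel-based multi-index propensity score
#'
#' Nadaraya-Watson regression of the treatment indicator on the index
#' columns with a product Gaussian kernel and diagonal bandwidth matrix:
#' `score_i = sum_j K_H(S_j - S_i) A_j / sum_j K_H(S_j - S_i)`, summing over
#' all `j` including `j = i` (leave-in).  With `d = 2` (one PS and one OR
#' index) this is exactly the double-index propensity score.  The optional
#' leave-one-out mode drops the self term; its scores can degenerate when a
#' point is isolated, which the range diagnostics record.
#'
#' @param S index matrix or [build_index_matrix()] result.
#' @param A binary treatment vector.
#' @param bandwidths positive bandwidth per column; default is
#'   [scott_bandwidth()].
#' @param undersmooth multiplier passed to the bandwidth rule.
#' @param leave_one_out drop the self term from the kernel sums?
#' @return a [propensity_vector()] with `method = "kernel"`.
#' @export
nw_mips <- function(S, A, bandwidths = NULL, undersmooth = 1,
                    leave_one_out = FALSE) {
  S <- as_index(S)
  n <- nrow(S)
  if (n < 2L) stop("need at least 2 rows", call. = FALSE)
  stopifnot(length(A) == n, all(A %in% c(0, 1)))
  if (is.null(bandwidths)) bandwidths <- scott_bandwidth(S, undersmooth)
  if (length(bandwidths) == 1L) bandwidths <- rep(bandwidths, ncol(S))
  stopifnot(length(bandwidths) == ncol(S), all(bandwidths > 0),
            all(is.finite(S)))
  M <- matrix(0, n, n)
  for (k in seq_len(ncol(S))) {
    u <- S[, k] / bandwidths[k]
    M <- M + (outer(u, u, "-"))^2
  }
  W <- exp(-0.5 * M)
  if (leave_one_out) diag(W) <- 0
  denom <- rowSums(W)
  if (any(denom <= 0)) {
    stop(sprintf("kernel denominator underflowed to 0 at row(s) %s; increase the bandwidth",
                 paste(utils::head(which(denom <= 0), 5L), collapse = ", ")),
         call. = FALSE)
  }
  propensity_vector(drop(W %*% A) / denom, method = "kernel")
}

# ANN configuration and training -----------------------------------------

#' Neural-network configuration for the integrated propensity score
#'
#' The default architecture follows the estimator's reference setup: two
#' hidden layers of four neurons with hyperbolic-tangent activations, a
#' sigmoid output (so estimated probabilities always lie strictly inside
#' `(0, 1)`), squared-error loss minimised by backpropagation with learning
#' rate 0.001 and momentum 0.5, weights initialised uniformly on
#' `(-init_scale, init_scale)`.  In the default `"online"` batch mode the
#' weights are updated once per pattern, sweeping the sample in fixed order
#' each epoch; `"full"` accumulates the mean gradient and updates once per
#' epoch.
#'
#' @param epochs number of sweeps through the data.
#' @param learning_rate gradient-descent step size, in (0, 1).
#' @param momentum momentum coefficient, in (0, 1).
#' @param hidden hidden-layer sizes (length 2).
#' @param init_scale half-width of the uniform weight initialisation.
#' @param seed integer seed for the initialisation.
#' @param batch `"online"` (per-pattern updates) or `"full"` (one update per
#'   epoch).
#' @param output `"sigmoid"` for probability targets, `"linear"` for
#'   regression targets.
#' @param trace record the full-sample training loss after every epoch?
#' @return an object of class `ann_config`.
#' @export
ann_config <- function(epochs = 1000L, learning_rate = 0.001, momentum = 0.5,
                       hidden = c(4L, 4L), init_scale = 0.3, seed = 1L,
                       batch = c("online", "full"),
                       output = c("sigmoid", "linear"), trace = FALSE) {
  batch <- match.arg(batch)
  output <- match.arg(output)
  stopifnot(epochs >= 1, learning_rate > 0, learning_rate < 1,
            momentum >= 0, momentum < 1, length(hidden) == 2L,
            all(hidden >= 1), init_scale > 0)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 momentum = momentum, hidden = as.integer(hidden),
                 init_scale = init_scale, seed = seed, batch = batch,
                 output = output, trace = trace),
            class = "ann_config")
}

init_weights <- function(d, hidden, init_scale, seed) {
  with_seed(seed, {
    h1 <- hidden[1L]; h2 <- hidden[2L]
    u <- function(k) runif(k, -init_scale, init_scale)
    list(W1 = matrix(u(d * h1), d, h1), b1 = u(h1),
         W2 = matrix(u(h1 * h2), h1, h2), b2 = u(h2),
         W3 = u(h2), b3 = u(1L))
  })
}

#' Train the neural network on the multi-index
#'
#' Regresses the binary treatment (or, with a linear output, a continuous
#' target) on the index columns.  Training is fully deterministic given the
#' configuration seed.
#'
#' @param S index matrix or [build_index_matrix()] result.
#' @param A target vector (binary for the sigmoid output).
#' @param cfg an [ann_config()].
#' @return an object of class `ann_mips` holding the trained weights, the
#'   fitted values and (if requested) the per-epoch loss trace.
#' @export
train_ann <- function(S, A, cfg = ann_config()) {
  idx <- if (inherits(S, "index_matrix")) S else NULL
  S <- as_index(S)
  n <- nrow(S)
  if (n < 10L) stop("need at least 10 rows to train the network", call. = FALSE)
  stopifnot(length(A) == n, all(is.finite(S)), all(is.finite(A)))
  if (cfg$output == "sigmoid" && !all(A %in% c(0, 1))) {
    stop("sigmoid output requires a 0/1 target", call. = FALSE)
  }
  w0 <- init_weights(ncol(S), cfg$hidden, cfg$init_scale, cfg$seed)
  res <- ann_train_cpp(S, as.numeric(A), w0,
                       lr = cfg$learning_rate, momentum = cfg$momentum,
                       epochs = cfg$epochs, online = (cfg$batch == "online"),
                       sigmoid_out = (cfg$output == "sigmoid"),
                       trace = cfg$trace)
  structure(list(weights = res$weights, fitted = res$fitted,
                 loss_trace = if (cfg$trace) res$loss_trace else NULL,
                 d = ncol(S), cfg = cfg,
                 center = if (!is.null(idx)) idx$center,
                 scale = if (!is.null(idx)) idx$scale),
            class = "ann_mips")
}

#' @export
print.ann_mips <- function(x, ...) {
  cat(sprintf("<ann_mips> %d -> %d -> %d -> 1 (%s output), %d epochs (%s)\n",
              x$d, x$cfg$hidden[1L], x$cfg$hidden[2L], x$cfg$output,
              x$cfg$epochs, x$cfg$batch))
  invisible(x)
}

#' Predict integrated propensity scores from a trained network
#'
#' @param object a trained `ann_mips` model.
#' @param newdata index matrix with the model's input dimension, on the same
#'   (standardized) scale as the training indices.
#' @param ... unused.
#' @return a [propensity_vector()] (`method = "ann"`) for sigmoid networks,
#'   otherwise a plain numeric vector.
#' @export
predict.ann_mips <- function(object, newdata, ...) {
  S <- as_index(newdata)
  if (ncol(S) != object$d) {
    stop(sprintf("network expects %d input columns, got %d", object$d, ncol(S)),
         call. = FALSE)
  }
  out <- ann_forward_cpp(S, object$weights,
                         sigmoid_out = (object$cfg$output == "sigmoid"))
  if (object$cfg$output == "sigmoid") {
    propensity_vector(out, method = "ann")
  } else {
    as.numeric(out)
  }
}
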