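#' Gradient-weighted class activation maps
#'
#' Maps the target-class score back to the last convolutional layer of the
#' event arm: channel weights are the spatial means of the score's
#' gradient with respect to that layer's activations, the weighted channel
#' sum is rectified, linearly interpolated to the input length, and
#' max-normalised to 1 (all-zero maps are left at zero).  The
#' gradient-weighted form is used because the dense layers after the
#' convolution preclude the classic global-average-pooling formulation.
#'
#' @param model An `afnet` with an event arm (an untrained model is
#'   allowed; the output is flagged).
#' @param windows Windows tibble or n x L matrix.
#' @param target_class `"AF"` (default) or `"SINUS"`.
#' @return Tibble with one row per window: `target_class`, `trained`, and
#'   list-column `cam` (length-L values in `[0, 1]`).
#' @export
class_activation_map <- function(model, windows, target_class = "AF") {
  stopifnot(inherits(model, "afnet"))
  if (is.null(model$event_arm)) {
    rlang::abort("variant has no event arm; no rhythm class score to map")
  }
  target_class <- match.arg(target_class, rhythm_levels())
  X <- if (is.data.frame(windows)) windows_matrix(windows$samples)
  else if (is.matrix(windows)) windows else matrix(windows, nrow = 1)
  n <- nrow(X)
  L <- model$input_length
  tfw <- nn_forward(model$trunk, as_engine_batch(X), n, L, FALSE)
  efw <- nn_forward(model$event_arm, tfw$out, n, tfw$L, FALSE)
  # index of the last conv layer in the event arm and the layers above it
  conv_idx <- max(which(vapply(model$event_arm, function(l) l$kind, "") == "conv"))
  above <- (conv_idx + 1):length(model$event_arm)
  dout <- matrix(0, n, 2)
  dout[, match(target_class, rhythm_levels())] <- 1
  bw <- nn_backward(model$event_arm[above], efw$caches[above], dout, n)
  A <- efw$caches[[conv_idx]]$out       # (n*Lc) x C activations
  dA <- bw$dx                           # same shape
  Lc <- tfw$L                           # event-arm convs preserve length
  cams <- lapply(seq_len(n), function(i) {
    rows <- i + n * (seq_len(Lc) - 1)
    alpha <- colMeans(dA[rows, , drop = FALSE])
    m <- pmax(A[rows, , drop = FALSE] %*% alpha, 0)
    m <- stats::approx(seq_len(Lc), m, n = L)$y
    if (max(m) > 0) m <- m / max(m)
    as.numeric(m)
  })
  out <- tibble::tibble(target_class = target_class, trained = model$trained,
                        cam = cams)
  if (is.data.frame(windows) && "window_id" %in% names(windows)) {
    out <- dplyr::bind_cols(windows["window_id"], out)
  }
  out
}

#' Project embeddings to two dimensions
#'
#' Seeded nonlinear 2-D projection of the embedding layer: classical
#' multidimensional scaling refined by Kruskal's non-metric MDS on the
#' Euclidean distance matrix.  Coincident embeddings receive a tiny seeded
#' jitter so the distance matrix is valid.  A pure function of the
#' embeddings, seed and settings.
#'
#' @param embeddings n x d matrix (n >= 10), e.g. from [embed_windows()].
#' @param seed Integer seed.
#' @param maxit Iterations for the non-metric refinement.
#' @return Tibble with `dim1`, `dim2`, one row per embedding.
#' @export
embedding_projection <- function(embeddings, seed = 1L, maxit = 30) {
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) < 10) {
    abort_field("embeddings", sprintf(
      "need at least 10 points for a stable projection, got %d; supply more windows",
      nrow(embeddings)))
  }
  set.seed(as.integer(seed))
  d <- stats::dist(embeddings)
  eps <- max(d) * 1e-6 + 1e-12
  if (any(d < eps)) {
    d[d < eps] <- eps * (1 + stats::runif(sum(d < eps)))
  }
  init <- stats::cmdscale(d, k = 2)
  if (ncol(init) < 2 || any(!is.finite(init))) {
    init <- matrix(stats::rnorm(2 * nrow(embeddings), 0, 1e-4), ncol = 2)
  }
  xy <- MASS::isoMDS(d, y = init, k = 2, maxit = maxit, trace = FALSE)$points
  tibble::tibble(dim1 = xy[, 1], dim2 = xy[, 2])
}
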