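#' Configure the convolutional denoising autoencoder
#'
#' The encoder is three convolution + max-pool stages (filters
#' `enc_filters`, kernel width `kernel`, ReLU), compressing a length-`L`
#' window to a latent sequence of `L / 8` steps; the decoder mirrors it
#' with three upsample + convolution stages, ending in a linear
#' single-channel reconstruction.  Training minimises mean-squared error
#' between the reconstruction and the clean target with Adam; the learning
#' rate drops by `lr_decrement` (to a floor of `lr_floor`) whenever the
#' validation loss has not improved for `lr_patience` epochs.  The printed
#' defaults are 200 epochs with a 0.001 decrement every 25 stale epochs;
#' desk-scale runs use far fewer epochs.
#'
#' @param input_length Window length `L` in samples (default 800); must be
#'   divisible by 8.
#' @param enc_filters Encoder filter counts, length 3 (default 32, 16, 8).
#' @param kernel Convolution kernel width, odd (default 5).
#' @param lr Initial Adam learning rate (default 0.001).
#' @param epochs Training epochs (default 200).
#' @param lr_decrement Additive learning-rate reduction (default 0.001).
#' @param lr_patience Epochs without validation improvement before a
#'   reduction (default 25).
#' @param lr_floor Smallest admissible learning rate (default 1e-5).
#' @param batch Minibatch size (default 128).
#' @param val_frac Fraction of records held out for validation (default 0.1).
#' @param seed Integer seed controlling initialisation and training.
#' @return A `cdae_config` list with derived field `latent_length`.
#' @export
cdae_config <- function(input_length = 800L, enc_filters = c(32L, 16L, 8L),
                        kernel = 5L, lr = 0.001, epochs = 200L,
                        lr_decrement = 0.001, lr_patience = 25L,
                        lr_floor = 1e-5, batch = 128L, val_frac = 0.1,
                        seed = 1L) {
  check_number(input_length, "input_length", 8, Inf)
  if (input_length %% 8 != 0) {
    abort_field("input_length", "must be divisible by 8 (three pooling stages)")
  }
  if (length(enc_filters) != 3 || any(enc_filters < 1)) {
    abort_field("enc_filters", "must be three positive filter counts")
  }
  if (kernel %% 2 != 1) abort_field("kernel", "must be odd")
  check_number(epochs, "epochs", 1, Inf)
  latent <- input_length / 8
  stopifnot(latent < input_length)
  structure(list(input_length = as.integer(input_length),
                 enc_filters = as.integer(enc_filters),
                 kernel = as.integer(kernel), lr = lr,
                 epochs = as.integer(epochs), lr_decrement = lr_decrement,
                 lr_patience = as.integer(lr_patience), lr_floor = lr_floor,
                 batch = as.integer(batch), val_frac = val_frac,
                 latent_length = as.integer(latent), seed = as.integer(seed)),
            class = "cdae_config")
}

#' Build a convolutional denoising autoencoder
#'
#' Parameters are He-initialised deterministically from `config$seed`; two
#' builds with the same configuration are identical.
#'
#' @param config A [cdae_config()].
#' @return A `cdae` model object.
#' @export
build_cdae <- function(config = cdae_config()) {
  stopifnot(inherits(config, "cdae_config"))
  f <- config$enc_filters
  k <- config$kernel
  layers <- list(
    nn_conv(1L, f[1], k, "relu"), nn_pool(),
    nn_conv(f[1], f[2], k, "relu"), nn_pool(),
    nn_conv(f[2], f[3], k, "relu"), nn_pool(),
    nn_upsample(), nn_conv(f[3], f[2], k, "relu"),
    nn_upsample(), nn_conv(f[2], f[1], k, "relu"),
    nn_upsample(), nn_conv(f[1], 1L, k, "linear")
  )
  set.seed(derive_seed(config$seed, "cdae_init"))
  structure(list(layers = nn_init(layers), config = config,
                 encoder_idx = c(1L, 3L, 5L), n_encoder_layers = 6L,
                 trained = FALSE, history = NULL), class = "cdae")
}

#' @export
print.cdae <- function(x, ...) {
  cat("<cdae> ", x$config$input_length, "-sample windows, filters ",
      paste(x$config$enc_filters, collapse = "/"), ", latent length ",
      x$config$latent_length, if (x$trained) ", trained" else ", untrained",
      "\n", sep = "")
  invisible(x)
}

#' Corrupt a batch of clean windows
#'
#' Assigns one Gaussian noise factor to each window (round-robin over
#' `factors` or sampled uniformly) and adds noise scaled by that factor
#' times the window's own standard deviation, preserving the clean/noisy
#' pairing.  Uses the global RNG.
#'
#' @param clean An n x L matrix of clean windows (or a windows tibble with
#'   a `clean` list-column).
#' @param factors Non-empty set of noise factors (default [noise_factors()]).
#' @param assignment `"round_robin"` (default) or `"random"`.
#' @return List with `corrupted` (n x L matrix) and `noise_factor`
#'   (length-n vector).
#' @export
corrupt_batch <- function(clean, factors = noise_factors(),
                          assignment = c("round_robin", "random")) {
  assignment <- match.arg(assignment)
  if (!length(factors)) abort_field("factors", "must be non-empty")
  if (any(factors < 0)) abort_field("factors", "must be >= 0")
  if (is.data.frame(clean)) clean <- windows_matrix(clean$clean)
  n <- nrow(clean)
  nf <- if (assignment == "round_robin") {
    rep_len(factors, n)
  } else {
    sample(factors, n, replace = TRUE)
  }
  sds <- apply(clean, 1, stats::sd)
  noise <- matrix(stats::rnorm(length(clean)), n) * (nf * sds)
  list(corrupted = clean + noise, noise_factor = nf)
}

#' Build corrupted/clean training pairs for the autoencoder
#'
#' Replaces the `samples` column of a windows tibble with Gaussian-corrupted
#' copies of the `clean` windows via [corrupt_batch()], recording the factor
#' drawn for each window.  This is the canonical way to assemble denoising
#' training data from clean simulated windows.
#'
#' @param windows Windows tibble with a `clean` list-column.
#' @param factors Noise-factor set (default [noise_factors()]).
#' @param assignment Factor assignment rule (see [corrupt_batch()]).
#' @param seed Integer seed.
#' @return `windows` with corrupted `samples` and updated `noise_factor`.
#' @export
cdae_pairs <- function(windows, factors = noise_factors(),
                       assignment = "round_robin", seed = 1L) {
  stopifnot("clean" %in% names(windows))
  set.seed(derive_seed(seed, "cdae_pairs"))
  cb <- corrupt_batch(windows, factors, assignment)
  windows$samples <- lapply(seq_len(nrow(cb$corrupted)),
                            function(i) cb$corrupted[i, ])
  windows$noise_factor <- cb$noise_factor
  windows$qa <- qa_from_noise(cb$noise_factor)
  windows
}

# Forward a matrix of windows (n x L) through a cdae layer stack.
cdae_forward <- function(model, X, training = FALSE, n_layers = NULL) {
  L <- ncol(X)
  if (L != model$config$input_length) {
    abort_field("windows", sprintf("expected length %d, got %d",
                                   model$config$input_length, L))
  }
  layers <- model$layers
  if (!is.null(n_layers)) layers <- layers[seq_len(n_layers)]
  nn_forward(layers, as_engine_batch(X), nrow(X), L, training)
}

#' Train the denoising autoencoder
#'
#' Inputs are corrupted windows; targets are the matching clean windows.
#' A record-level validation split monitors mean-squared error and drives
#' the learning-rate schedule.  Training is bit-reproducible from the
#' configuration seed on a fixed thread count.
#'
#' @param model A `cdae` from [build_cdae()].
#' @param windows Windows tibble with list-columns `samples` (corrupted
#'   input) and `clean` (target), e.g. from [preprocess_records()].
#' @param epochs Override the configured epoch count (used for desk-scale
#'   runs).
#' @param verbose Print per-epoch losses.
#' @return The trained `cdae`, with a `history` tibble (`epoch`,
#'   `train_mse`, `val_mse`, `lr`).
#' @export
train_cdae <- function(model, windows, epochs = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "cdae"))
  if (!nrow(windows)) abort_field("windows", "must be non-empty")
  if (!all(c("samples", "clean") %in% names(windows))) {
    abort_field("windows", "need `samples` (corrupted) and `clean` list-columns")
  }
  cfg <- model$config
  if (is.null(epochs)) epochs <- cfg$epochs
  X <- windows_matrix(windows$samples)
  Y <- windows_matrix(windows$clean)
  set.seed(derive_seed(cfg$seed, "cdae_train"))
  # validation split by record id so no record straddles the split
  rec <- if ("record_id" %in% names(windows)) windows$record_id else
    seq_len(nrow(windows))
  ur <- unique(rec)
  val_rec <- sample(ur, max(1, round(cfg$val_frac * length(ur))))
  val <- rec %in% val_rec
  tr_idx <- which(!val)
  va_idx <- which(val)
  layers <- model$layers
  state <- adam_init(layers)
  lr <- cfg$lr
  t <- 0
  best_val <- Inf
  stale <- 0
  hist <- vector("list", epochs)
  val_mse <- function(lys) {
    fw <- nn_forward(lys, as_engine_batch(X[va_idx, , drop = FALSE]),
                     length(va_idx), ncol(X), "infer")
    mean((fw$out - as_engine_batch(Y[va_idx, , drop = FALSE]))^2)
  }
  for (ep in seq_len(epochs)) {
    ord <- sample(tr_idx)
    bs <- split(ord, ceiling(seq_along(ord) / cfg$batch))
    tl <- 0
    for (b in bs) {
      n <- length(b)
      fw <- nn_forward(layers, as_engine_batch(X[b, , drop = FALSE]), n,
                       ncol(X), "train")
      layers <- fw$layers
      lo <- mse_loss_grad(fw$out, as_engine_batch(Y[b, , drop = FALSE]))
      if (!is.finite(lo$loss)) {
        rlang::abort(sprintf("non-finite training loss at epoch %d", ep))
      }
      bw <- nn_backward(layers, fw$caches, lo$dz, n, need_input_grad = FALSE)
      t <- t + 1
      up <- adam_step(layers, bw$grads, state, lr, t)
      layers <- up$layers
      state <- up$state
      tl <- tl + lo$loss * n
    }
    vm <- val_mse(layers)
    hist[[ep]] <- tibble::tibble(epoch = ep, train_mse = tl / length(tr_idx),
                                 val_mse = vm, lr = lr)
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f  lr %.5f",
                      ep, tl / length(tr_idx), vm, lr))
    }
    if (vm < best_val - 1e-9) {
      best_val <- vm
      stale <- 0
    } else {
      stale <- stale + 1
      if (stale >= cfg$lr_patience) {
        lr <- max(lr - cfg$lr_decrement, cfg$lr_floor)
        stale <- 0
      }
    }
  }
  model$layers <- layers
  model$trained <- TRUE
  model$history <- dplyr::bind_rows(hist)
  model
}

#' Reconstruct windows through the autoencoder
#'
#' @param model A `cdae`.
#' @param windows An n x L matrix, a numeric window, or a windows tibble
#'   with a `samples` list-column.
#' @return n x L matrix of reconstructions.
#' @export
reconstruct <- function(model, windows) {
  stopifnot(inherits(model, "cdae"))
  X <- if (is.data.frame(windows)) windows_matrix(windows$samples)
  else if (is.matrix(windows)) windows else matrix(windows, nrow = 1)
  out <- cdae_forward(model, X, training = FALSE)$out
  matrix(out, nrow(X), ncol(X))
}

#' Extract the trained encoder weights
#'
#' Returns the three encoder convolution layers' parameters (weight and
#' bias tensors with shape metadata) for transfer into the classifier
#' trunk.  The object round-trips through `saveRDS()`/`readRDS()`
#' bit-exactly.
#'
#' @param model A `cdae`.
#' @return An `encoder_weights` object (list of 3 `W`/`b` pairs).
#' @export
extract_encoder <- function(model) {
  stopifnot(inherits(model, "cdae"))
  ws <- lapply(model$encoder_idx, function(i) {
    ly <- model$layers[[i]]
    list(W = ly$W, b = ly$b, in_ch = ly$in_ch, out_ch = ly$out_ch,
         kernel = ly$kernel)
  })
  structure(list(weights = ws, input_length = model$config$input_length,
                 latent_length = model$config$latent_length,
                 trained = model$trained), class = "encoder_weights")
}

#' @export
print.encoder_weights <- function(x, ...) {
  cat("<encoder_weights> 3 conv layers:",
      paste(vapply(x$weights, function(w)
        sprintf("%dx%d->%d", w$kernel, w$in_ch, w$out_ch), ""),
        collapse = ", "),
      if (x$trained) "(trained)" else "(untrained)", "\n")
  invisible(x)
}

#' Encode windows to the latent representation
#'
#' Runs only the encoder half (three conv + pool stages).
#'
#' @inheritParams reconstruct
#' @return Matrix of latent activations, one row per window
#'   (`latent_length * enc_filters[3]` values).
#' @export
encode <- function(model, windows) {
  stopifnot(inherits(model, "cdae"))
  X <- if (is.data.frame(windows)) windows_matrix(windows$samples)
  else if (is.matrix(windows)) windows else matrix(windows, nrow = 1)
  fw <- cdae_forward(model, X, training = FALSE,
                     n_layers = model$n_encoder_layers)
  matrix(fw$out, nrow(X))
}
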