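#' Model variants
#'
#' The four ablation variants of the classifier: multitask (rhythm +
#' quality heads) or single task (rhythm only), each with or without
#' encoder pretraining.  `"ST_QA"` is an additional quality-only variant
#' used internally for label propagation.
#'
#' @return Character vector of variant names.
#' @export
model_variants <- function() {
  c("MT_PRETRAINED", "MT_RANDOM", "ST_PRETRAINED", "ST_RANDOM")
}

variant_has_qa <- function(v) v %in% c("MT_PRETRAINED", "MT_RANDOM", "ST_QA")
variant_has_af <- function(v) v != "ST_QA"
variant_pretrained <- function(v) grepl("PRETRAINED", v)

#' Build the multitask rhythm/quality classifier
#'
#' A shared trunk of six hidden convolutional layers feeds one or two task
#' arms.  Trunk layers 1-3 replicate the autoencoder encoder (conv +
#' max-pool, ReLU) so pretrained encoder weights can be copied in
#' one-to-one; layers 4-6 are convolutions with leaky-ReLU, batch
#' normalisation and dropout.  The quality arm adds one convolution (ReLU,
#' batch norm, dropout) and two dense layers ending in a 3-way softmax; the
#' event arm adds three such convolutions and two dense layers ending in a
#' 2-way softmax, whose penultimate dense layer is the embedding layer.
#' All weights are He-initialised from per-segment derived seeds, so trunk
#' and arm initialisations are identical across variants sharing a seed.
#'
#' @param variant One of [model_variants()] (or `"ST_QA"`).
#' @param input_length Window length `L` (default 800).
#' @param seed Integer seed.
#' @param encoder Optional [extract_encoder()] result; when supplied to a
#'   pretrained variant the weights are transferred immediately.
#' @param dropout Dropout rate for trunk layers 4-6 and the arms
#'   (default 0.25).
#' @param enc_filters Encoder filter counts (must match the autoencoder
#'   whose weights will be transferred; default 32, 16, 8).
#' @return An `afnet` model object.
#' @export
build_afnet <- function(variant = "MT_PRETRAINED", input_length = 800L,
                        seed = 1L, encoder = NULL, dropout = 0.25,
                        enc_filters = c(32L, 16L, 8L)) {
  if (!variant %in% c(model_variants(), "ST_QA")) {
    abort_field("variant", paste("must be one of:",
                                 paste(c(model_variants(), "ST_QA"), collapse = ", ")))
  }
  if (input_length %% 8 != 0) abort_field("input_length", "must be divisible by 8")
  f <- as.integer(enc_filters)
  trunk <- list(
    nn_conv(1L, f[1], 5L, "relu"), nn_pool(),
    nn_conv(f[1], f[2], 5L, "relu"), nn_pool(),
    nn_conv(f[2], f[3], 5L, "relu"), nn_pool(),
    nn_conv(f[3], 32L, 3L, "leaky"), nn_bn(32L), nn_dropout(dropout),
    nn_conv(32L, 32L, 3L, "leaky"), nn_bn(32L), nn_dropout(dropout),
    nn_conv(32L, 32L, 3L, "leaky"), nn_bn(32L), nn_dropout(dropout)
  )
  Lr <- as.integer(input_length / 8) # trunk output length after 3 pools
  qa_arm <- if (variant_has_qa(variant)) list(
    nn_conv(32L, 16L, 3L, "relu"), nn_bn(16L), nn_dropout(dropout),
    nn_flatten(), nn_dense(Lr * 16L, 64L, "relu"),
    nn_dense(64L, 3L, "linear")
  )
  event_arm <- if (variant_has_af(variant)) list(
    nn_conv(32L, 16L, 3L, "relu"), nn_bn(16L), nn_dropout(dropout),
    nn_conv(16L, 16L, 3L, "relu"), nn_bn(16L), nn_dropout(dropout),
    nn_conv(16L, 8L, 3L, "relu"), nn_bn(8L), nn_dropout(dropout),
    nn_flatten(), nn_dense(Lr * 8L, 64L, "relu"),
    nn_dense(64L, 2L, "linear")
  )
  set.seed(derive_seed(seed, "afnet_init_trunk"))
  trunk <- nn_init(trunk)
  if (!is.null(qa_arm)) {
    set.seed(derive_seed(seed, "afnet_init_qa"))
    qa_arm <- nn_init(qa_arm)
  }
  if (!is.null(event_arm)) {
    set.seed(derive_seed(seed, "afnet_init_event"))
    event_arm <- nn_init(event_arm)
  }
  model <- structure(list(variant = variant,
                          input_length = as.integer(input_length),
                          trunk = trunk, qa_arm = qa_arm,
                          event_arm = event_arm, encoder_pos = c(1L, 3L, 5L),
                          seed = as.integer(seed), transferred = FALSE,
                          trained = FALSE, history = NULL),
                     class = "afnet")
  if (!is.null(encoder)) model <- transfer_encoder_weights(model, encoder)
  model
}

n_params <- function(model) {
  cnt <- function(lys) sum(vapply(lys, function(ly) {
    sum(vapply(nn_param_names(ly), function(nm) length(ly[[nm]]), 0))
  }, 0))
  cnt(model$trunk) + cnt(model$qa_arm %||% list()) +
    cnt(model$event_arm %||% list())
}

#' @export
print.afnet <- function(x, ...) {
  cat("<afnet> variant ", x$variant, ", input length ", x$input_length,
      ", ", format(n_params(x), big.mark = ","), " parameters",
      if (x$transferred) ", encoder transferred" else "",
      if (x$trained) ", trained" else ", untrained", "\n", sep = "")
  invisible(x)
}

#' Copy pretrained encoder weights into the trunk
#'
#' Sets trunk layers 1-3 (the encoder-shaped convolutions) to the
#' autoencoder encoder's parameters.  The layers stay trainable: training
#' continues backpropagation through them (full fine-tuning).  Only
#' pretrained variants may receive weights; random-initialisation variants
#' never call this.  Idempotent.
#'
#' @param model An `afnet` with a pretrained variant.
#' @param enc An `encoder_weights` object.
#' @return The model with transferred weights.
#' @export
transfer_encoder_weights <- function(model, enc) {
  stopifnot(inherits(model, "afnet"), inherits(enc, "encoder_weights"))
  if (!variant_pretrained(model$variant)) {
    rlang::abort(sprintf(
      "variant %s uses random initialisation; encoder transfer is not part of its pipeline",
      model$variant))
  }
  for (j in seq_along(model$encoder_pos)) {
    i <- model$encoder_pos[j]
    ly <- model$trunk[[i]]
    w <- enc$weights[[j]]
    if (!identical(dim(ly$W), dim(w$W))) {
      rlang::abort(sprintf(
        "encoder layer %d shape mismatch: trunk expects %s, encoder provides %s",
        j, paste(dim(ly$W), collapse = "x"), paste(dim(w$W), collapse = "x")))
    }
    ly$W <- w$W
    ly$b <- w$b
    model$trunk[[i]] <- ly
  }
  model$transferred <- TRUE
  model
}

# Forward through trunk and requested arms.  X is an n x L matrix.
afnet_forward <- function(model, X, mode = "infer", qa = TRUE, af = TRUE) {
  n <- nrow(X)
  L <- ncol(X)
  if (L != model$input_length) {
    abort_field("windows", sprintf("expected length %d, got %d",
                                   model$input_length, L))
  }
  tfw <- nn_forward(model$trunk, as_engine_batch(X), n, L, mode)
  out <- list(trunk = tfw, n = n)
  if (qa && !is.null(model$qa_arm)) {
    out$qa <- nn_forward(model$qa_arm, tfw$out, n, tfw$L, mode)
  }
  if (af && !is.null(model$event_arm)) {
    out$af <- nn_forward(model$event_arm, tfw$out, n, tfw$L, mode)
  }
  out
}

# Re-estimate batch-norm inference statistics with dropout off, then fold
# them in.  Statistics gathered during training are collected under dropout
# noise and systematically overestimate the variance seen at inference.
afnet_calibrate <- function(model, X, batch = 256L) {
  chunks <- split(seq_len(nrow(X)), ceiling(seq_len(nrow(X)) / batch))
  for (ix in chunks) {
    fw <- afnet_forward(model, X[ix, , drop = FALSE], mode = "calibrate")
    model$trunk <- fw$trunk$layers
    if (!is.null(fw$qa)) model$qa_arm <- fw$qa$layers
    if (!is.null(fw$af)) model$event_arm <- fw$af$layers
  }
  model$trunk <- nn_bn_finalize(model$trunk)
  if (!is.null(model$qa_arm)) model$qa_arm <- nn_bn_finalize(model$qa_arm)
  if (!is.null(model$event_arm)) model$event_arm <- nn_bn_finalize(model$event_arm)
  model
}

inv_freq_weights <- function(y, k) {
  tab <- tabulate(y, k)
  w <- length(y) / (sum(tab > 0) * pmax(tab, 1))
  sw <- w[y]
  sw / mean(sw)
}

#' Train the classifier
#'
#' Joint loss `w_af * CE(rhythm) + w_qa * CE(quality)` with
#' inverse-frequency class weights per task; single-task variants use only
#' their own term.  A subject-level validation split monitors weighted
#' macro-averaged F1 on the rhythm task (quality task for `"ST_QA"`), and
#' the best-scoring epoch's parameters are restored at the end.  Pretrained
#' variants must have received encoder weights before training (pretraining
#' precedes fine-tuning).
#'
#' @param model An `afnet`.
#' @param windows Windows tibble with a `samples` list-column, a `rhythm`
#'   factor column (unless `"ST_QA"`), and a `qa` factor column (multitask
#'   and `"ST_QA"` variants).
#' @param epochs,batch,lr Training schedule (Adam optimiser).
#' @param w_qa,w_af Non-negative task loss weights; multitask variants
#'   require `w_qa > 0`.
#' @param val_frac Fraction of subjects held out for model selection
#'   (ignored when `val` is supplied).
#' @param val Optional explicit validation windows tibble; when given, all
#'   of `windows` is used for training.
#' @param seed Integer seed for shuffling and dropout.
#' @param verbose Print per-epoch progress.
#' @return The trained `afnet` with a `history` tibble.
#' @export
train_afnet <- function(model, windows, epochs = 10, batch = 128L, lr = 1e-3,
                        w_qa = 1, w_af = 1, val_frac = 0.15, val = NULL,
                        seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "afnet"))
  if (w_qa < 0 || w_af < 0) abort_field("w_qa/w_af", "must be >= 0")
  is_mt <- model$variant %in% c("MT_PRETRAINED", "MT_RANDOM")
  if (is_mt && w_qa <= 0) {
    rlang::warn("w_qa = 0 degenerates a multitask graph to single-task training")
  }
  if (variant_pretrained(model$variant) && !model$transferred) {
    rlang::abort("pretrained variant has no encoder weights yet; run the autoencoder and transfer_encoder_weights() first")
  }
  use_af <- variant_has_af(model$variant) && w_af > 0
  use_qa <- variant_has_qa(model$variant) && w_qa > 0
  if (!use_af && !use_qa) abort_field("w_qa/w_af", "at least one task weight must be positive")
  X <- windows_matrix(windows$samples)
  y_af <- y_qa <- NULL
  if (use_af) {
    if (!"rhythm" %in% names(windows) || anyNA(windows$rhythm)) {
      abort_field("rhythm", "labels required for the event-detection task")
    }
    y_af <- as.integer(rhythm_factor(as.character(windows$rhythm)))
    if (length(unique(y_af)) < 2) {
      abort_field("rhythm", "training data contains a single rhythm class")
    }
  }
  if (use_qa) {
    if (!"qa" %in% names(windows) || anyNA(windows$qa)) {
      abort_field("qa", "labels required for the quality task")
    }
    y_qa <- as.integer(qa_factor(as.character(windows$qa)))
  }
  set.seed(derive_seed(seed, "afnet_train"))
  if (is.null(val)) {
    subj <- if ("subject_id" %in% names(windows)) windows$subject_id else
      as.character(seq_len(nrow(windows)))
    us <- unique(subj)
    val_s <- sample(us, max(1, round(val_frac * length(us))))
    va_idx <- which(subj %in% val_s)
    tr_idx <- setdiff(seq_len(nrow(windows)), va_idx)
    Xva <- X[va_idx, , drop = FALSE]
    val_truth <- if (use_af) rhythm_factor(rhythm_levels()[y_af[va_idx]]) else
      qa_factor(qa_levels()[y_qa[va_idx]])
  } else {
    tr_idx <- seq_len(nrow(windows))
    Xva <- windows_matrix(val$samples)
    val_truth <- if (use_af) rhythm_factor(as.character(val$rhythm)) else
      qa_factor(as.character(val$qa))
  }
  if (use_af && length(unique(y_af[tr_idx])) < 2) {
    abort_field("rhythm", "training split contains a single rhythm class")
  }
  sw_af <- if (use_af) inv_freq_weights(y_af[tr_idx], 2) else NULL
  sw_qa <- if (use_qa) inv_freq_weights(y_qa[tr_idx], 3) else NULL
  segs <- c("trunk", if (!is.null(model$qa_arm)) "qa_arm",
            if (!is.null(model$event_arm)) "event_arm")
  state <- lapply(segs, function(s) adam_init(model[[s]]))
  names(state) <- segs
  t <- 0
  best_f1 <- -Inf
  best <- NULL
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample(tr_idx)
    bs <- split(ord, ceiling(seq_along(ord) / batch))
    ep_loss <- ep_af <- ep_qa <- 0
    for (b in bs) {
      n <- length(b)
      pos <- match(b, tr_idx)
      fw <- afnet_forward(model, X[b, , drop = FALSE], mode = "train",
                          qa = use_qa, af = use_af)
      model$trunk <- fw$trunk$layers
      dtrunk <- 0
      loss <- loss_af <- loss_qa <- 0
      grads <- list()
      if (use_af) {
        model$event_arm <- fw$af$layers
        ce <- ce_loss_grad(fw$af$out, y_af[b], sw_af[pos], w_af)
        loss_af <- ce$loss
        bw <- nn_backward(model$event_arm, fw$af$caches, ce$dlogits, n)
        grads$event_arm <- bw$grads
        dtrunk <- dtrunk + bw$dx
      }
      if (use_qa) {
        model$qa_arm <- fw$qa$layers
        ce <- ce_loss_grad(fw$qa$out, y_qa[b], sw_qa[pos], w_qa)
        loss_qa <- ce$loss
        bw <- nn_backward(model$qa_arm, fw$qa$caches, ce$dlogits, n)
        grads$qa_arm <- bw$grads
        dtrunk <- dtrunk + bw$dx
      }
      loss <- loss_af + loss_qa
      if (!is.finite(loss)) {
        rlang::abort(sprintf("non-finite training loss at epoch %d", ep))
      }
      grads$trunk <- nn_backward(model$trunk, fw$trunk$caches, dtrunk, n,
                                 need_input_grad = FALSE)$grads
      t <- t + 1
      for (s in names(grads)) {
        up <- adam_step(model[[s]], grads[[s]], state[[s]], lr, t)
        model[[s]] <- up$layers
        state[[s]] <- up$state
      }
      ep_loss <- ep_loss + loss * n
      ep_af <- ep_af + loss_af * n
      ep_qa <- ep_qa + loss_qa * n
    }
    # validation under batch statistics: stable mid-training, no leakage
    # into the running estimates
    vfw <- afnet_forward(model, Xva, mode = "batch_eval",
                         qa = !use_af, af = use_af)
    est <- if (use_af) {
      rhythm_factor(rhythm_levels()[max.col(softmax_probs(vfw$af$out))])
    } else {
      qa_factor(qa_levels()[max.col(softmax_probs(vfw$qa$out))])
    }
    vf1 <- weighted_macro(metrics_from_counts(
      confusion(val_truth, est, levels(val_truth)), quiet = TRUE))$f1
    hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = ep_loss / length(tr_idx),
                                 train_loss_af = ep_af / length(tr_idx),
                                 train_loss_qa = ep_qa / length(tr_idx),
                                 val_f1 = vf1)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f (af %.4f qa %.4f)  val F1 %.4f",
                      ep, ep_loss / length(tr_idx), ep_af / length(tr_idx),
                      ep_qa / length(tr_idx), vf1))
    }
    if (vf1 > best_f1) {
      best_f1 <- vf1
      best <- lapply(segs, function(s) nn_get_params(model[[s]]))
      names(best) <- segs
    }
  }
  for (s in segs) model[[s]] <- nn_set_params(model[[s]], best[[s]])
  model <- afnet_calibrate(model, X[tr_idx, , drop = FALSE])
  model$trained <- TRUE
  model$best_val_f1 <- best_f1
  model$history <- dplyr::bind_rows(hist)
  model
}

#' Predict rhythm and quality for windows
#'
#' Deterministic inference (dropout off, batch normalisation using running
#' statistics); outputs are invariant to batch composition.
#'
#' @param object A trained (or initialised) `afnet`.
#' @param windows Windows tibble with a `samples` list-column, or an
#'   n x L matrix.
#' @param batch Inference batch size.
#' @param ... Unused.
#' @return Tibble with one row per window: softmax probabilities per task
#'   (`af_prob_*`, `qa_prob_*`) and class predictions (`af_pred`,
#'   `qa_pred`); quality columns only for variants with a quality arm.
#' @export
predict.afnet <- function(object, windows, batch = 512L, ...) {
  X <- if (is.data.frame(windows)) windows_matrix(windows$samples)
  else if (is.matrix(windows)) windows else matrix(windows, nrow = 1)
  n <- nrow(X)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / batch))
  res <- purrr::map_dfr(chunks, function(ix) {
    fw <- afnet_forward(object, X[ix, , drop = FALSE], mode = "infer")
    out <- tibble::tibble(.rows = length(ix))
    if (!is.null(fw$af)) {
      p <- softmax_probs(fw$af$out)
      out$af_prob_SINUS <- p[, 1]
      out$af_prob_AF <- p[, 2]
      out$af_pred <- rhythm_factor(rhythm_levels()[max.col(p)])
    }
    if (!is.null(fw$qa)) {
      p <- softmax_probs(fw$qa$out)
      out$qa_prob_EXCELLENT <- p[, 1]
      out$qa_prob_ACCEPTABLE <- p[, 2]
      out$qa_prob_POOR <- p[, 3]
      out$qa_pred <- qa_factor(qa_levels()[max.col(p)])
    }
    out
  })
  if (is.data.frame(windows) && "window_id" %in% names(windows)) {
    res <- dplyr::bind_cols(windows["window_id"], res)
  }
  res
}

#' Extract embedding vectors
#'
#' Activations of the last dense layer before the rhythm prediction (the
#' 64-unit embedding layer of the event arm), used for 2-D projection of
#' the learned representation.
#'
#' @param model An `afnet` with an event arm.
#' @param windows Windows tibble or n x L matrix.
#' @return n x 64 matrix of embeddings.
#' @export
embed_windows <- function(model, windows) {
  stopifnot(inherits(model, "afnet"))
  if (is.null(model$event_arm)) {
    rlang::abort("variant has no event arm, hence no rhythm embedding layer")
  }
  X <- if (is.data.frame(windows)) windows_matrix(windows$samples)
  else if (is.matrix(windows)) windows else matrix(windows, nrow = 1)
  tfw <- nn_forward(model$trunk, as_engine_batch(X), nrow(X),
                    model$input_length, FALSE)
  sub <- model$event_arm[seq_len(length(model$event_arm) - 1L)]
  nn_forward(sub, tfw$out, nrow(X), tfw$L, FALSE)$out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
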