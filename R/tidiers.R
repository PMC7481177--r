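#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the autoencoder training history
#'
#' @param x A trained `cdae`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `train_mse`, `val_mse`, `lr`.
#' @export
tidy.cdae <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer(0), train_mse = double(0),
                                val_mse = double(0), lr = double(0))
}

#' One-row summary of an autoencoder fit
#'
#' @param x A `cdae`.
#' @param ... Unused.
#' @return Tibble: `input_length`, `latent_length`, `trained`, `epochs`,
#'   final training and validation MSE.
#' @export
glance.cdae <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    input_length = x$config$input_length,
    latent_length = x$config$latent_length,
    trained = x$trained,
    epochs = if (is.null(h)) 0L else max(h$epoch),
    train_mse = if (is.null(h)) NA_real_ else h$train_mse[nrow(h)],
    val_mse = if (is.null(h)) NA_real_ else h$val_mse[nrow(h)]
  )
}

#' Tidy the classifier training history
#'
#' @param x A trained `afnet`.
#' @param ... Unused.
#' @return Tibble with per-epoch losses and validation F1.
#' @export
tidy.afnet <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer(0), train_loss = double(0),
                                train_loss_af = double(0),
                                train_loss_qa = double(0), val_f1 = double(0))
}

#' One-row summary of a classifier fit
#'
#' @param x An `afnet`.
#' @param ... Unused.
#' @return Tibble: `variant`, parameter count, transfer/training status,
#'   best validation F1.
#' @export
glance.afnet <- function(x, ...) {
  tibble::tibble(variant = x$variant, n_params = n_params(x),
                 transferred = x$transferred, trained = x$trained,
                 best_val_f1 = x$best_val_f1 %||% NA_real_)
}

#' Per-class rows of a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return The per-class metrics tibble.
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' Aggregate row of a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return The one-row weighted macro-averaged tibble.
#' @export
glance.metrics_report <- function(x, ...) x$aggregate
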