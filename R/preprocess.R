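#' Windowing specification
#'
#' Fixed parameters of the model-input geometry: `t`-second windows taken
#' from signals resampled to `fs_in` Hz and decimated by
#' `downsample_factor`, giving windows of
#' `L = t * fs_in / downsample_factor` samples (800 at the defaults).
#'
#' @param t Window length in seconds (default 25).
#' @param fs_in Reference sampling rate in Hz (default 128); inputs at other
#'   rates are resampled to `fs_in` first so `L` is invariant.
#' @param downsample_factor Integer decimation factor (default 4).
#' @param stride Window stride in seconds; defaults to `t` (non-overlapping,
#'   as used for evaluation).  Smaller strides give overlapping windows for
#'   training-time augmentation (5 s is the conventional choice here).
#' @return A `window_spec` list with derived fields `L` and `fs_eff`.
#' @export
window_spec <- function(t = 25, fs_in = 128, downsample_factor = 4L,
                        stride = t) {
  check_number(t, "t")
  if (t <= 0) abort_field("t", "must be > 0")
  check_number(fs_in, "fs_in", 1, Inf)
  check_number(downsample_factor, "downsample_factor", 1, Inf)
  if (downsample_factor != round(downsample_factor)) {
    abort_field("downsample_factor", "must be an integer")
  }
  L <- fs_in * t / downsample_factor
  if (abs(L - round(L)) > 1e-9) {
    abort_field("t", "fs_in * t / downsample_factor must be an integer")
  }
  check_number(stride, "stride")
  if (stride <= 0 || stride > t) abort_field("stride", "must be in (0, t]")
  structure(list(t = t, fs_in = fs_in,
                 downsample_factor = as.integer(downsample_factor),
                 stride = stride, L = as.integer(round(L)),
                 fs_eff = fs_in / downsample_factor), class = "window_spec")
}

#' Zero-phase Butterworth bandpass filter
#'
#' Second-order Butterworth applied forward-backward (`signal::filtfilt`),
#' so the output is band-limited with zero phase distortion and DC is
#' rejected.  Default corners 0.5-8 Hz cover the pulse fundamental and its
#' first harmonics for heart rates of 30-220 bpm.
#'
#' @param x Numeric trace.
#' @param fs Sampling rate in Hz.
#' @param low,high Corner frequencies in Hz, `0 < low < high < fs/2`.
#' @return Filtered trace, same length.
#' @export
bandpass <- function(x, fs, low = 0.5, high = 8) {
  check_number(low, "low")
  check_number(high, "high")
  if (low <= 0 || high <= low || high >= fs / 2) {
    abort_field("low/high", sprintf(
      "need 0 < low < high < fs/2 = %g Hz (got %g, %g)", fs / 2, low, high))
  }
  bf <- signal::butter(2, c(low, high) / (fs / 2), type = "pass")
  # remove the mean first: the filter's DC gain is zero in steady state but
  # forward-backward filtering of a large offset leaves edge transients
  as.numeric(signal::filtfilt(bf, x - mean(x)))
}

#' Decimate a signal with anti-aliasing
#'
#' Low-pass filters (8th-order Chebyshev, zero phase) and keeps every
#' `factor`-th sample; output length is `floor(length(x) / factor)`.
#'
#' @param x Numeric trace.
#' @param factor Integer decimation factor (>= 1); 1 is the identity.
#' @return Decimated trace.
#' @export
downsample <- function(x, factor) {
  check_number(factor, "factor", 1, Inf)
  if (factor != round(factor)) abort_field("factor", "must be an integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(as.numeric(x))
  y <- as.numeric(signal::decimate(x, factor, ftype = "iir"))
  y[seq_len(floor(length(x) / factor))]
}

#' Min-max standardise a window to [0, 1]
#'
#' `(x - min) / (max - min)`; a constant (degenerate) window maps to all
#' zeros.  Idempotent.
#'
#' @param x Numeric window.
#' @return Standardised window.
#' @export
standardize <- function(x) {
  if (!length(x)) abort_field("x", "must be non-empty")
  r <- range(x)
  if (r[1] == r[2]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Cut a trace into fixed-length standardised windows
#'
#' Windows of `spec$L` samples start at multiples of the stride (on the
#' decimated time base); a trailing partial window is discarded, and each
#' window is min-max standardised.  A signal shorter than one window yields
#' an empty result with a warning.
#'
#' @param x Numeric trace already at the effective rate `spec$fs_eff`.
#' @param spec A [window_spec()].
#' @return Tibble with `window_index` and list-column `samples`.
#' @export
window_signal <- function(x, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  L <- spec$L
  step <- round(spec$stride * spec$fs_eff)
  if (length(x) < L) {
    rlang::warn(sprintf("signal of %d samples is shorter than one %d-sample window",
                        length(x), L))
    return(tibble::tibble(window_index = integer(0), samples = list()))
  }
  starts <- seq(1L, length(x) - L + 1L, by = step)
  tibble::tibble(
    window_index = seq_along(starts),
    samples = lapply(starts, function(s) standardize(x[s:(s + L - 1)]))
  )
}

# Resample to the reference rate when needed (rational-ratio polyphase).
resample_to <- function(x, fs_from, fs_to) {
  if (fs_from == fs_to) return(as.numeric(x))
  k <- MASS::fractions(fs_to / fs_from)
  pq <- as.integer(strsplit(attr(k, "fracs"), "/")[[1]])
  if (length(pq) == 1L) pq <- c(pq, 1L)
  as.numeric(signal::resample(x, pq[1], pq[2]))
}

#' Preprocess a raw PPG trace into model-ready windows
#'
#' Fixed pipeline: resample to `spec$fs_in` if needed, bandpass filter,
#' decimate by `spec$downsample_factor`, cut into windows, and min-max
#' standardise each window.  Filtering precedes per-window standardisation
#' so slow drift never distorts the [0, 1] mapping.
#'
#' @param x Numeric trace.
#' @param fs Sampling rate of `x` in Hz.
#' @param spec A [window_spec()].
#' @param low,high Bandpass corners in Hz.
#' @param subject_id Subject identifier carried onto every window.
#' @return Tibble with `subject_id`, `window_index`, `fs_eff`, list-column
#'   `samples` (length `spec$L`, in `[0, 1]`).
#' @export
preprocess_signal <- function(x, fs, spec = window_spec(), low = 0.5,
                              high = 8, subject_id = "S1") {
  x <- resample_to(x, fs, spec$fs_in)
  x <- bandpass(x, spec$fs_in, low, high)
  x <- downsample(x, spec$downsample_factor)
  w <- window_signal(x, spec)
  tibble::tibble(subject_id = subject_id, window_index = w$window_index,
                 fs_eff = spec$fs_eff, samples = w$samples)
}

#' Preprocess simulated records into labelled window pairs
#'
#' Runs [preprocess_signal()] on the corrupted trace of every record and,
#' in lockstep, on its clean trace, so each emitted window keeps its clean
#' counterpart for denoising-autoencoder training.  Labels (`rhythm`,
#' `qa_true`, `noise_factor`) and subject identity are carried through;
#' windows never cross record (hence subject) boundaries.
#'
#' @param records Tibble from [simulate_ppg_dataset()] (columns
#'   `subject_id`, `rhythm`, `noise_factor`, `qa_true`, `fs`, list-columns
#'   `clean` and `corrupted`).
#' @param spec A [window_spec()].
#' @param low,high Bandpass corners in Hz.
#' @return Tibble of windows: `window_id`, `record_id`, `subject_id`,
#'   `window_index`, `rhythm`, `qa`, `noise_factor`, list-columns `samples`
#'   (corrupted, standardised) and `clean`.
#' @export
preprocess_records <- function(records, spec = window_spec(), low = 0.5,
                               high = 8) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  rid <- if ("id" %in% names(records)) records$id else seq_len(nrow(records))
  out <- purrr::map(seq_len(nrow(records)), function(i) {
    run <- function(x) {
      x <- resample_to(x, records$fs[i], spec$fs_in)
      x <- downsample(bandpass(x, spec$fs_in, low, high),
                      spec$downsample_factor)
      x
    }
    wc <- window_signal(run(records$corrupted[[i]]), spec)
    wk <- window_signal(run(records$clean[[i]]), spec)
    tibble::tibble(
      record_id = rid[i],
      subject_id = records$subject_id[i],
      window_index = wc$window_index,
      rhythm = records$rhythm[i],
      qa = records$qa_true[i],
      noise_factor = records$noise_factor[i],
      samples = wc$samples,
      clean = wk$samples[seq_along(wc$samples)]
    )
  })
  out <- dplyr::bind_rows(out)
  out$window_id <- seq_len(nrow(out))
  dplyr::relocate(out, "window_id")
}

# Stack a list-column of equal-length windows into an n x L matrix.
windows_matrix <- function(samples) {
  L <- length(samples[[1]])
  matrix(unlist(samples, use.names = FALSE), nrow = length(samples),
         ncol = L, byrow = TRUE)
}
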