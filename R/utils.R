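# Shared helpers: validation, peak detection, seed derivation.

abort_field <- function(field, msg) {
  rlang::abort(paste0("invalid `", field, "`: ", msg), class = "ppgnet_validation")
}

check_number <- function(x, field, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort_field(field, "must be a single finite number")
  }
  if (x < lower || x > upper) {
    abort_field(field, sprintf("must be in [%s, %s], got %s", lower, upper, x))
  }
  invisible(x)
}

#' Detect systolic peaks in a PPG trace
#'
#' Simple local-maximum detection with a minimum-height and refractory
#' (minimum peak distance) constraint, tuned so the dicrotic hump of a pulse
#' (relative amplitude ~0.35) is not counted as a beat.  The input is
#' min-max standardised internally, so thresholds are on a [0, 1] scale.
#'
#' @param x Numeric trace.
#' @param fs Sampling rate in Hz.
#' @param min_height Minimum standardised peak height (default 0.45).
#' @param min_distance_s Minimum distance between peaks in seconds; default
#'   0.27 s, just under the shortest plausible beat interval (220 bpm).
#' @return Integer vector of peak sample indices (possibly empty).
#' @export
detect_peaks <- function(x, fs, min_height = 0.45, min_distance_s = 0.27) {
  rng <- range(x)
  if (diff(rng) == 0) return(integer(0))
  xs <- (x - rng[1]) / diff(rng)
  pk <- pracma::findpeaks(xs, minpeakheight = min_height,
                          minpeakdistance = max(1L, round(min_distance_s * fs)))
  if (is.null(pk)) return(integer(0))
  sort(as.integer(pk[, 2]))
}

#' Root mean square of successive differences of peak-to-peak intervals
#'
#' The classic RMSSD irregularity statistic, computed from detected peak
#' times.  Returns `NA` when fewer than three peaks are found.
#'
#' @param x Numeric trace.
#' @param fs Sampling rate in Hz.
#' @param ... Passed to [detect_peaks()].
#' @return RMSSD in seconds, or `NA_real_`.
#' @export
rmssd <- function(x, fs, ...) {
  pk <- detect_peaks(x, fs, ...)
  if (length(pk) < 3) return(NA_real_)
  ibi <- diff(pk) / fs
  sqrt(mean(diff(ibi)^2))
}

#' Derive a module-specific seed from a global seed
#'
#' One global seed fans out to per-stage seeds by hashing the stage name with
#' the seed, so pipeline stages are independently reproducible.
#'
#' @param seed Integer global seed.
#' @param what Character stage label.
#' @return A single integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, what) {
  h <- rlang::hash(paste0(what, "::", as.integer(seed)))
  as.integer(strtoi(substr(h, 1, 7), base = 16L) %% .Machine$integer.max)
}

qa_levels <- function() c("EXCELLENT", "ACCEPTABLE", "POOR")
rhythm_levels <- function() c("SINUS", "AF")

qa_factor <- function(x) factor(x, levels = qa_levels())
rhythm_factor <- function(x) factor(x, levels = rhythm_levels())
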