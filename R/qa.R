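#' Oracle quality label from the generating noise factor
#'
#' For simulated records the quality class is a pure function of the
#' Gaussian noise factor used to corrupt the signal: factors `<= 0.25` are
#' `EXCELLENT`, factors in `(0.25, 2)` are `ACCEPTABLE`, and factors
#' `>= 2` are `POOR`.
#'
#' @param x A records/windows tibble with a `noise_factor` column, or a
#'   numeric vector of noise factors.
#' @return Factor of quality classes (levels EXCELLENT, ACCEPTABLE, POOR).
#' @export
qa_oracle <- function(x) {
  nf <- if (is.data.frame(x)) {
    if (!"noise_factor" %in% names(x)) {
      abort_field("noise_factor", "column required for the quality oracle")
    }
    x$noise_factor
  } else x
  if (any(!is.finite(nf)) || any(nf < 0)) {
    abort_field("noise_factor", "must be finite and >= 0")
  }
  qa_from_noise(nf)
}

#' Morphological signal-quality features
#'
#' Minimal, testable surrogates for published PPG quality criteria:
#' waveform skewness (pulsatile PPG is strongly right-skewed), systolic
#' peak count, coefficient of variation of peak heights and of inter-peak
#' intervals, periodicity (maximum autocorrelation over physiological beat
#' lags, 0.27-2 s), and the fraction of samples pinned to the rails of the
#' standardised range (clipping).
#'
#' @param x A standardised window (numeric) or a windows tibble with a
#'   `samples` list-column.
#' @param fs Effective sampling rate of the window in Hz (default 32).
#' @return One-row-per-window tibble: `skewness`, `peak_count`,
#'   `peak_prominence_cv`, `peak_interval_cv`, `periodicity`,
#'   `clipping_fraction`.
#' @export
sqi_features <- function(x, fs = 32) {
  wins <- if (is.data.frame(x)) x$samples else if (is.list(x)) x else list(x)
  purrr::map_dfr(wins, function(w) {
    w <- standardize(w)
    pk <- detect_peaks(w, fs)
    h <- w[pk]
    cv <- function(v) if (length(v) >= 3 && mean(v) > 0) stats::sd(v) / mean(v) else Inf
    per <- if (stats::sd(w) == 0) 0 else {
      a <- stats::acf(w, lag.max = round(2 * fs), plot = FALSE,
                      demean = TRUE)$acf[-1]
      max(a[round(0.27 * fs):length(a)])
    }
    tibble::tibble(
      skewness = if (stats::sd(w) == 0) 0 else e1071::skewness(w),
      peak_count = length(pk),
      peak_prominence_cv = cv(h),
      peak_interval_cv = cv(diff(pk)),
      periodicity = per,
      clipping_fraction = mean(w >= 0.999 | w <= 0.001)
    )
  })
}

#' Rule-based signal-quality classification
#'
#' Deterministic three-class quality scorer over [sqi_features()]:
#' * `POOR` when pulse structure is undetectable — peak count outside the
#'   plausible 30-220 bpm range for a 25-s window (12-92), no beat-lag
#'   autocorrelation (periodicity < 0.15), or heavy clipping (fraction
#'   > 0.1);
#' * `EXCELLENT` when the waveform is clearly pulsatile — strongly
#'   right-skewed (skewness > 0.5), plausible peak count, consistent peak
#'   heights (prominence CV < 0.5), visible beat-lag autocorrelation
#'   (periodicity >= 0.2) and negligible clipping (< 0.01);
#' * `ACCEPTABLE` otherwise.
#'
#' Increasing additive noise degrades every feature used here on average,
#' so the mean ordinal score is non-increasing in the noise factor.
#'
#' @inheritParams sqi_features
#' @return Factor of quality classes, one per window.
#' @export
rule_based_sqi <- function(x, fs = 32) {
  f <- sqi_features(x, fs)
  poor <- f$peak_count < 12 | f$peak_count > 92 |
    f$periodicity < 0.15 | f$clipping_fraction > 0.1
  excellent <- !poor & f$skewness > 0.5 & f$peak_prominence_cv < 0.5 &
    f$periodicity >= 0.2 & f$clipping_fraction < 0.01
  qa_factor(ifelse(poor, "POOR", ifelse(excellent, "EXCELLENT", "ACCEPTABLE")))
}

#' Propagate quality labels from a scored subset
#'
#' Mirrors the label-propagation protocol in which a modest expert-scored
#' window set (conventionally 1000 windows) trains a quality classifier
#' that labels the remaining corpus.  The classifier is the network's
#' quality arm run as a standalone single-task model (variant `"ST_QA"`),
#' so one architecture family serves both tasks.
#'
#' @param scored Windows tibble with a `qa` factor column covering all
#'   three classes.
#' @param unscored Windows tibble to label.
#' @param epochs Training epochs (default 12).
#' @param seed Integer seed.
#' @param ... Passed to [train_afnet()].
#' @return `unscored` with `qa_pred` (factor) and `qa_confidence`
#'   (winning softmax probability) columns added.
#' @export
propagate_labels <- function(scored, unscored, epochs = 12, seed = 1L, ...) {
  if (!"qa" %in% names(scored)) abort_field("qa", "scored windows need a qa column")
  present <- qa_levels() %in% as.character(unique(scored$qa))
  if (!all(present)) {
    abort_field("qa", paste0("scored subset is missing class(es): ",
                             paste(qa_levels()[!present], collapse = ", ")))
  }
  model <- build_afnet("ST_QA", input_length = length(scored$samples[[1]]),
                       seed = derive_seed(seed, "qa_propagation"))
  fit <- train_afnet(model, scored, epochs = epochs,
                     seed = derive_seed(seed, "qa_propagation_train"), ...)
  pred <- predict(fit, unscored)
  unscored$qa_pred <- pred$qa_pred
  unscored$qa_confidence <- pmax(pred$qa_prob_EXCELLENT,
                                 pred$qa_prob_ACCEPTABLE, pred$qa_prob_POOR)
  unscored
}
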