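#' Canonical Gaussian noise factors
#'
#' The noise-factor grid used to corrupt simulated PPG: each factor scales
#' the per-signal standard deviation of additive Gaussian noise, spanning
#' near-clean (0.001) to noise-dominated (5) regimes.
#'
#' @return Numeric vector of the seven canonical factors.
#' @export
noise_factors <- function() c(0.001, 0.25, 0.5, 0.75, 1, 2, 5)

#' Specify a beat train
#'
#' Describes the beat-to-beat timing process of a simulated rhythm.  Sinus
#' rhythm has low beat-interval variability; atrial fibrillation (AF) is
#' emulated by strong, serially independent interval irregularity
#' ("frequency modulation" of the pulse train).
#'
#' @param rhythm `"SINUS"` or `"AF"`.
#' @param mean_hr Mean heart rate, beats/minute, in `[30, 220]`.
#' @param duration Record duration in seconds.
#' @param rr_variability Coefficient of variation of beat-to-beat intervals
#'   (dimensionless).  Must be `<= 0.1` for sinus and `>= 0.15` for AF.
#' @return A `beat_train_spec` list.
#' @export
beat_train_spec <- function(rhythm = c("SINUS", "AF"), mean_hr = 70,
                            duration = 25, rr_variability = NULL) {
  rhythm <- match.arg(rhythm)
  if (is.null(rr_variability)) {
    rr_variability <- if (rhythm == "SINUS") 0.05 else 0.24
  }
  check_number(mean_hr, "mean_hr", 30, 220)
  check_number(duration, "duration")
  if (duration <= 0) abort_field("duration", "must be > 0")
  check_number(rr_variability, "rr_variability", 0, Inf)
  if (rhythm == "SINUS" && rr_variability > 0.1) {
    abort_field("rr_variability", "must be <= 0.1 for SINUS rhythm")
  }
  if (rhythm == "AF" && rr_variability < 0.15) {
    abort_field("rr_variability", "must be >= 0.15 for AF rhythm")
  }
  structure(list(rhythm = rhythm, mean_hr = mean_hr, duration = duration,
                 rr_variability = rr_variability), class = "beat_train_spec")
}

#' Specify slow modulations of the pulse train
#'
#' Baseline wander (additive respiratory-band drift) and amplitude
#' modulation (multiplicative envelope), the two slow processes overlaid on
#' the clean pulse train.
#'
#' @param bw_freq Baseline-wander frequency in Hz, in `(0, 1]`.
#' @param bw_amp Baseline-wander amplitude as a fraction of pulse amplitude
#'   (`>= 0`).
#' @param am_freq Amplitude-modulation frequency in Hz, in `(0, 1]`.
#' @param am_depth Amplitude-modulation depth, in `[0, 1)`.
#' @return A `modulation_spec` list.
#' @export
modulation_spec <- function(bw_freq = 0.25, bw_amp = 0.3,
                            am_freq = 0.2, am_depth = 0.2) {
  check_number(bw_freq, "bw_freq")
  if (bw_freq <= 0 || bw_freq > 1) abort_field("bw_freq", "must be in (0, 1] Hz")
  check_number(am_freq, "am_freq")
  if (am_freq <= 0 || am_freq > 1) abort_field("am_freq", "must be in (0, 1] Hz")
  check_number(bw_amp, "bw_amp", 0, Inf)
  check_number(am_depth, "am_depth", 0, 1)
  if (am_depth >= 1) abort_field("am_depth", "must be < 1")
  structure(list(bw_freq = bw_freq, bw_amp = bw_amp, am_freq = am_freq,
                 am_depth = am_depth), class = "modulation_spec")
}

#' Draw a series of inter-beat intervals
#'
#' Intervals are log-normal with mean `60 / mean_hr` seconds and coefficient
#' of variation `rr_variability`, serially independent, clipped to the
#' physiological range `[60/220, 60/30]` s.  For sinus rhythm this is mild
#' multiplicative jitter; for AF the same law with a much larger coefficient
#' of variation produces the chaotic, irregularly irregular beat timing that
#' characterises the arrhythmia.  Draws come from the global RNG, so wrap in
#' `set.seed()` for reproducibility.
#'
#' @param spec A [beat_train_spec()].
#' @return Numeric vector of intervals (seconds) whose sum reaches at least
#'   `spec$duration`.
#' @export
make_rr_series <- function(spec) {
  stopifnot(inherits(spec, "beat_train_spec"))
  base <- 60 / spec$mean_hr
  sigma <- sqrt(log(1 + spec$rr_variability^2))
  draw <- function(n) {
    iv <- if (sigma == 0) rep(base, n) else
      base * exp(sigma * stats::rnorm(n) - sigma^2 / 2)
    pmin(pmax(iv, 60 / 220), 60 / 30)
  }
  iv <- draw(ceiling(spec$duration / base * 1.5) + 5)
  while (sum(iv) < spec$duration) iv <- c(iv, draw(10))
  iv[seq_len(which(cumsum(iv) >= spec$duration)[1])]
}

#' Synthesise a clean PPG trace from inter-beat intervals
#'
#' Each beat is a fixed two-lobe template — a systolic Gaussian peak plus a
#' dicrotic hump at ~45% of the beat interval with relative amplitude 0.35 —
#' scaled to the interval length.  The pulse train is then multiplied by the
#' amplitude-modulation envelope and summed with the baseline-wander
#' sinusoid; both modulation phases are drawn from the global RNG.
#'
#' @param rr Numeric vector of inter-beat intervals (seconds).
#' @param mod A [modulation_spec()].
#' @param fs Sampling rate in Hz.
#' @param duration Optional target duration in seconds; the trace is
#'   truncated or zero-padded to `round(duration * fs)` samples.  Defaults
#'   to `sum(rr)`.
#' @return Numeric trace of length `round(duration * fs)`.
#' @export
synthesize_clean_ppg <- function(rr, mod = modulation_spec(), fs = 128,
                                 duration = NULL) {
  stopifnot(inherits(mod, "modulation_spec"))
  if (!length(rr)) abort_field("rr", "must be non-empty")
  check_number(fs, "fs")
  if (fs <= 0) abort_field("fs", "must be > 0")
  if (is.null(duration)) duration <- sum(rr)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  onsets <- cumsum(c(0, rr))[seq_along(rr)]
  pulse <- numeric(n)
  for (i in seq_along(rr)) {
    ti <- rr[i]
    i0 <- max(1L, floor((onsets[i] - 0.2 * ti) * fs) + 1L)
    i1 <- min(n, ceiling((onsets[i] + 1.2 * ti) * fs) + 1L)
    if (i0 > n) break
    tt <- t[i0:i1] - onsets[i]
    pulse[i0:i1] <- pulse[i0:i1] +
      exp(-0.5 * ((tt - 0.22 * ti) / (0.09 * ti))^2) +
      0.35 * exp(-0.5 * ((tt - 0.45 * ti) / (0.13 * ti))^2)
  }
  phi <- stats::runif(2, 0, 2 * pi)
  pulse * (1 + mod$am_depth * sin(2 * pi * mod$am_freq * t + phi[1])) +
    mod$bw_amp * sin(2 * pi * mod$bw_freq * t + phi[2])
}

#' Corrupt a signal with scaled Gaussian noise
#'
#' Adds i.i.d. Gaussian noise with standard deviation
#' `noise_factor * sd(clean)` — the stochastic corruption process used to
#' build denoising-autoencoder training pairs.  Uses the global RNG.
#'
#' @param clean Numeric trace.
#' @param noise_factor Non-negative noise factor (see [noise_factors()]).
#' @return Corrupted trace, same length as `clean`.
#' @export
corrupt_signal <- function(clean, noise_factor) {
  if (!length(clean)) abort_field("clean", "must be non-empty")
  check_number(noise_factor, "noise_factor", 0, Inf)
  clean + stats::rnorm(length(clean), 0, noise_factor * stats::sd(clean))
}

# noise factor -> true quality class (EXCELLENT <= 0.25 < ACCEPTABLE < 2 <= POOR)
qa_from_noise <- function(noise_factor) {
  qa_factor(ifelse(noise_factor <= 0.25, "EXCELLENT",
                   ifelse(noise_factor < 2, "ACCEPTABLE", "POOR")))
}

#' Simulate a single PPG record
#'
#' Fully seed-deterministic: the same `seed` and configuration reproduce the
#' record bit-exactly.
#'
#' @param spec A [beat_train_spec()].
#' @param mod A [modulation_spec()].
#' @param noise_factor Gaussian noise factor.
#' @param fs Sampling rate in Hz (default 128, matching common wrist-worn
#'   devices).
#' @param seed Integer seed for this record.
#' @return A one-row tibble with list-columns `clean` and `corrupted`,
#'   plus `rhythm`, `noise_factor`, `qa_true`, `fs`, `seed`.
#' @export
simulate_ppg <- function(spec, mod = modulation_spec(), noise_factor = 0.001,
                         fs = 128, seed = 1L) {
  set.seed(as.integer(seed))
  rr <- make_rr_series(spec)
  clean <- synthesize_clean_ppg(rr, mod, fs, duration = spec$duration)
  corrupted <- corrupt_signal(clean, noise_factor)
  tibble::tibble(
    rhythm = rhythm_factor(spec$rhythm),
    noise_factor = noise_factor,
    qa_true = qa_from_noise(noise_factor),
    fs = fs,
    seed = as.integer(seed),
    mean_hr = spec$mean_hr,
    rr_variability = spec$rr_variability,
    clean = list(clean),
    corrupted = list(corrupted)
  )
}

#' Plan a stratified simulation manifest
#'
#' Allocates `n_records` evenly over the rhythm-by-noise-factor grid (or by
#' `weights`, largest-remainder rounding), assigns synthetic subjects
#' (rhythm-pure blocks of `records_per_subject` consecutive records), and
#' derives one deterministic seed per record from the global seed.  Cheap
#' even at millions of records; signal synthesis happens later, chunk-wise.
#'
#' @param n_records Number of records (> 0).
#' @param rhythms Rhythm strata (default both).
#' @param noise_factors Noise-factor strata (default the canonical seven).
#' @param weights Optional non-negative stratum weights, length
#'   `length(rhythms) * length(noise_factors)` (rhythm-major order).
#' @param records_per_subject Records per synthetic subject (default 5).
#' @param seed Integer global seed.
#' @return Tibble with columns `id`, `subject_id`, `rhythm`, `noise_factor`,
#'   `qa_true`, `seed`.
#' @export
simulate_manifest <- function(n_records, rhythms = rhythm_levels(),
                              noise_factors = ppgnet::noise_factors(),
                              weights = NULL, records_per_subject = 5,
                              seed = 1L) {
  check_number(n_records, "n_records", 1, Inf)
  strata <- expand.grid(noise_factor = noise_factors, rhythm = rhythms,
                        stringsAsFactors = FALSE)[, c("rhythm", "noise_factor")]
  ns <- nrow(strata)
  if (is.null(weights)) {
    if (n_records %% ns != 0) {
      abort_field("n_records", sprintf(
        "cannot stratify %d records evenly over %d rhythm x noise strata",
        n_records, ns))
    }
    counts <- rep(n_records / ns, ns)
  } else {
    if (length(weights) != ns || any(weights < 0) || sum(weights) == 0) {
      abort_field("weights", "must be non-negative, one per stratum, not all zero")
    }
    exact <- n_records * weights / sum(weights)
    counts <- floor(exact)
    rem <- order(exact - counts, decreasing = TRUE)
    counts[rem[seq_len(n_records - sum(counts))]] <-
      counts[rem[seq_len(n_records - sum(counts))]] + 1
  }
  man <- strata[rep(seq_len(ns), counts), , drop = FALSE]
  # group by rhythm so subjects are rhythm-pure
  man <- man[order(match(man$rhythm, rhythms)), , drop = FALSE]
  base <- derive_seed(seed, "simulator")
  id <- seq_len(nrow(man))
  within_rhythm <- stats::ave(id, man$rhythm, FUN = seq_along)
  tibble::tibble(
    id = id,
    subject_id = paste0(substr(man$rhythm, 1, 1), "_",
                        sprintf("%05d", ceiling(within_rhythm / records_per_subject))),
    rhythm = rhythm_factor(man$rhythm),
    noise_factor = man$noise_factor,
    qa_true = qa_from_noise(man$noise_factor),
    seed = as.integer((base + 48271 * (id %% 44739)) %% 2147483647L)
  )
}

#' Simulate a stratified PPG dataset
#'
#' Generates paired clean/corrupted 25-s PPG records, evenly stratified over
#' rhythm and noise factor.  Per-subject physiology (mean heart rate,
#' interval variability) is drawn from subject-derived seeds, so the whole
#' dataset is a pure function of its configuration and `seed`.  With `out`
#' set, records are synthesised and written chunk-wise to a dataset
#' container (see [write_container()]) so arbitrarily large corpora never
#' occupy memory at once.
#'
#' @inheritParams simulate_manifest
#' @param mod A [modulation_spec()].
#' @param fs Sampling rate in Hz.
#' @param duration Record duration in seconds (default 25).
#' @param out Optional container directory; when given, records are streamed
#'   there and only the manifest is returned.
#' @param chunk_size Records per chunk when streaming (default 1000).
#' @return Tibble of records (list-columns `clean`, `corrupted`) or, when
#'   `out` is given, the manifest tibble invisibly.
#' @export
simulate_ppg_dataset <- function(n_records, rhythms = rhythm_levels(),
                                 noise_factors = ppgnet::noise_factors(),
                                 weights = NULL, mod = modulation_spec(),
                                 fs = 128, duration = 25,
                                 records_per_subject = 5, seed = 1L,
                                 out = NULL, chunk_size = 1000L) {
  man <- simulate_manifest(n_records, rhythms, noise_factors, weights,
                           records_per_subject, seed)
  gen_chunk <- function(rows) {
    recs <- purrr::pmap(
      list(rows$rhythm, rows$noise_factor, rows$seed, rows$subject_id),
      function(rhythm, nf, rec_seed, subject_id) {
        subj_seed <- derive_seed(seed, paste0("subject::", subject_id))
        set.seed(subj_seed)
        if (rhythm == "SINUS") {
          hr <- stats::runif(1, 50, 100)
          rrv <- stats::runif(1, 0.02, 0.08)
        } else {
          hr <- stats::runif(1, 70, 140)
          rrv <- stats::runif(1, 0.18, 0.30)
        }
        spec <- beat_train_spec(as.character(rhythm), mean_hr = hr,
                                duration = duration, rr_variability = rrv)
        simulate_ppg(spec, mod, nf, fs, rec_seed)
      })
    dplyr::bind_cols(rows[, c("id", "subject_id")], dplyr::bind_rows(recs))
  }
  if (is.null(out)) return(gen_chunk(man))
  chunks <- split(seq_len(nrow(man)), ceiling(seq_len(nrow(man)) / chunk_size))
  for (k in seq_along(chunks)) {
    write_container(gen_chunk(man[chunks[[k]], , drop = FALSE]), out,
                    append = k > 1, seed = seed)
  }
  invisible(man)
}
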