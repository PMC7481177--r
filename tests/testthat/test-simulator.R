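test_that("beat train specifications are validated field by field", {
  expect_error(beat_train_spec("SINUS", mean_hr = 300), "mean_hr")
  expect_error(beat_train_spec("SINUS", duration = -1), "duration")
  expect_error(beat_train_spec("SINUS", rr_variability = 0.3), "rr_variability")
  expect_error(beat_train_spec("AF", rr_variability = 0.05), "rr_variability")
  expect_error(modulation_spec(bw_freq = 2), "bw_freq")
  expect_error(modulation_spec(am_depth = 1), "am_depth")
})

test_that("zero variability yields perfectly regular beat intervals", {
  set.seed(1)
  rr <- make_rr_series(beat_train_spec("SINUS", mean_hr = 60, duration = 25,
                                       rr_variability = 0))
  expect_true(all(rr == 1.0))
  expect_gte(sum(rr), 25)
})

test_that("AF intervals reproduce the requested coefficient of variation", {
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    rr <- make_rr_series(beat_train_spec("AF", mean_hr = 90, duration = 60,
                                         rr_variability = 0.24))
    cv <- sd(rr) / mean(rr)
    if (cv >= 0.18 && cv <= 0.30) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("the canonical noise-factor set is offered", {
  expect_equal(noise_factors(), c(0.001, 0.25, 0.5, 0.75, 1, 2, 5))
})

test_that("modulation with zero depth leaves the bare pulse train", {
  rr <- rep(1, 25)
  m0 <- modulation_spec(bw_amp = 0, am_depth = 0)
  set.seed(10); a <- synthesize_clean_ppg(rr, m0, fs = 128, duration = 25)
  set.seed(77); b <- synthesize_clean_ppg(rr, m0, fs = 128, duration = 25)
  expect_identical(a, b)      # phases are irrelevant with modulation off
  expect_gte(min(a), 0)       # bare template train is non-negative
  # baseline wander adds a bounded sinusoid on top of the pulse train
  set.seed(10)
  c1 <- synthesize_clean_ppg(rr, modulation_spec(bw_amp = 0.3, am_depth = 0),
                             fs = 128, duration = 25)
  d <- c1 - a
  expect_lt(max(abs(d)), 0.3 + 1e-9)
  expect_gt(sd(d), 0.15)      # genuinely oscillating, not constant
})

test_that("a 25-s record at 60 bpm carries 25 +/- 1 systolic peaks", {
  for (s in 1:5) {
    set.seed(s)
    rr <- make_rr_series(beat_train_spec("SINUS", 60, 25, 0))
    x <- synthesize_clean_ppg(rr, fs = 128, duration = 25)
    expect_gte(length(detect_peaks(x, 128)), 24)
    expect_lte(length(detect_peaks(x, 128)), 26)
  }
})

test_that("peak-interval irregularity separates AF from sinus rhythm", {
  wins <- fixture_windows()
  low <- wins[wins$noise_factor <= 0.25, ]
  r <- vapply(low$samples, rmssd, 0, fs = 32)
  af <- r[low$rhythm == "AF"]
  si <- r[low$rhythm == "SINUS"]
  expect_gt(mean(af, na.rm = TRUE), mean(si, na.rm = TRUE))
})

test_that("corruption adds Gaussian noise scaled to the signal sd", {
  set.seed(3)
  x <- synthesize_clean_ppg(rep(0.8, 32), fs = 128, duration = 25)
  expect_identical(corrupt_signal(x, 0), x)
  set.seed(4)
  y <- corrupt_signal(x, 1)
  expect_equal(length(y), length(x))
  ratio <- sd(y - x) / sd(x)
  expect_gt(ratio, 0.9); expect_lt(ratio, 1.1)
  expect_error(corrupt_signal(x, -1), "noise_factor")
})

test_that("corruption energy matches the squared noise factor within 10%", {
  set.seed(9)
  x <- synthesize_clean_ppg(rep(0.8, 32), fs = 128, duration = 25)
  for (nf in c(0.5, 1, 2)) {
    set.seed(nf * 100)
    y <- corrupt_signal(x, nf)
    ratio <- mean((y - x)^2) / (stats::var(x) * nf^2)
    expect_gt(ratio, 0.9); expect_lt(ratio, 1.1)
  }
})

test_that("dataset generation stratifies evenly and is seed-deterministic", {
  man <- simulate_manifest(14, seed = 2)
  expect_equal(nrow(man), 14)
  expect_true(all(table(man$rhythm, man$noise_factor) == 1))
  expect_error(simulate_manifest(15, seed = 2), "stratify")
  a <- simulate_ppg_dataset(14, seed = 2)
  b <- simulate_ppg_dataset(14, seed = 2)
  expect_identical(a, b)
  expect_identical(as.character(a$rhythm),
                   as.character(simulate_manifest(14, seed = 2)$rhythm))
})

test_that("weighted stratification allocates by largest remainder", {
  w <- rep(0, 14); w[1] <- 3; w[8] <- 1
  man <- simulate_manifest(8, weights = w, seed = 1)
  expect_equal(nrow(man), 8)
  expect_equal(sum(man$rhythm == "SINUS" & man$noise_factor == 0.001), 6)
  expect_equal(sum(man$rhythm == "AF" & man$noise_factor == 0.001), 2)
})

test_that("a million-record manifest is planned without overflow", {
  man <- simulate_manifest(999992, records_per_subject = 100, seed = 3)
  expect_equal(nrow(man), 999992)
  expect_true(all(man$seed >= 0 & man$seed < 2^31))
  expect_false(anyNA(man$seed))
})

test_that("streamed chunked generation matches in-memory generation", {
  dir <- withr::local_tempdir()
  simulate_ppg_dataset(28, seed = 6, out = file.path(dir, "c"),
                       chunk_size = 10L)
  streamed <- read_container(file.path(dir, "c"))
  inmem <- simulate_ppg_dataset(28, seed = 6)
  expect_equal(streamed$clean, inmem$clean)
  expect_equal(streamed$corrupted, inmem$corrupted)
  expect_equal(as.character(streamed$rhythm), as.character(inmem$rhythm))
})
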