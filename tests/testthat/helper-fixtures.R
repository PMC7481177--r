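# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# A moderate stratified window set: 30 records per rhythm x noise stratum.
fixture_windows <- function() {
  with_cache("windows", {
    recs <- simulate_ppg_dataset(420, seed = 101)
    w <- preprocess_records(recs)
    w$qa <- qa_oracle(w)
    w
  })
}

# A small trained classifier (and its training windows) for explain/model
# tests that need a fitted model.
fixture_fit <- function() {
  with_cache("fit", {
    w <- fixture_windows()
    m <- build_afnet("MT_RANDOM", seed = 5)
    fit <- suppressMessages(train_afnet(m, w, epochs = 2, seed = 5))
    list(fit = fit, windows = w)
  })
}

# Independent brute-force metric oracles (deliberately naive).
bf_confusion <- function(truth, estimate, classes) {
  truth <- as.character(truth); estimate <- as.character(estimate)
  do.call(rbind, lapply(classes, function(cl) {
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (i in seq_along(truth)) {
      t_pos <- truth[i] == cl
      p_pos <- estimate[i] == cl
      if (t_pos && p_pos) tp <- tp + 1
      if (!t_pos && p_pos) fp <- fp + 1
      if (t_pos && !p_pos) fn <- fn + 1
      if (!t_pos && !p_pos) tn <- tn + 1
    }
    data.frame(class = cl, tp = tp, fp = fp, tn = tn, fn = fn)
  }))
}

bf_metric <- function(num, den, fill = 0) if (den > 0) num / den else fill

bf_weighted_mean <- function(v, w) {
  ok <- !is.na(v)
  sum(v[ok] * w[ok]) / sum(w[ok])
}
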