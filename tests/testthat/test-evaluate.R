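test_that("confusion counts match hand counts and validate labels", {
  cc <- confusion(c("AF", "AF", "NSR"), c("AF", "NSR", "NSR"),
                  c("AF", "NSR"))
  af <- cc[cc$class == "AF", ]
  expect_equal(c(af$tp, af$fn, af$tn, af$fp), c(1, 1, 1, 0))
  perfect <- confusion(c("A", "B", "A"), c("A", "B", "A"), c("A", "B"))
  expect_true(all(perfect$fp == 0) && all(perfect$fn == 0))
  expect_error(confusion(c("A", "C"), c("A", "A"), c("A", "B")), "outside")
  expect_error(confusion(c("A"), c("A", "B")), "length")
})

test_that("confusion counts agree with a brute-force tally on random labels", {
  classes <- c("X", "Y", "Z")
  set.seed(123)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    truth <- sample(classes, n, TRUE)
    est <- sample(classes, n, TRUE)
    got <- as.data.frame(confusion(truth, est, classes))
    want <- bf_confusion(truth, est, classes)
    expect_equal(got[c("class", "tp", "fp", "tn", "fn")], want,
                 ignore_attr = TRUE)
    expect_true(all(got$tp + got$fp + got$tn + got$fn == n))
  }
})

test_that("per-class metrics follow their defining ratios and conventions", {
  m <- metrics_from_counts(tibble::tibble(tp = 925, fp = 3, tn = 1000, fn = 4))
  expect_equal(m$sensitivity, 925 / 929)
  expect_equal(m$fnr, 4 / 929)
  expect_identical(m$sensitivity + m$fnr, 1)
  perfect <- metrics_from_counts(tibble::tibble(tp = 10, fp = 0, tn = 5, fn = 0))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$fpr, 0)
  expect_equal(perfect$fnr, 0)
  expect_warning(
    degen <- metrics_from_counts(tibble::tibble(tp = 0, fp = 0, tn = 5, fn = 2)),
    "zero-denominator")
  expect_equal(degen$precision, 0)
  expect_equal(degen$f1, 0)
  expect_error(metrics_from_counts(tibble::tibble(tp = -1, fp = 0, tn = 0, fn = 0)),
               "non-negative")
})

test_that("identities sensitivity+FNR=1 and specificity+FPR=1 hold exactly", {
  set.seed(99)
  for (rep in 1:50) {
    cnt <- tibble::tibble(tp = sample(1:500, 1), fp = sample(1:500, 1),
                          tn = sample(1:500, 1), fn = sample(1:500, 1))
    m <- metrics_from_counts(cnt)
    expect_identical(m$sensitivity + m$fnr, 1)
    expect_identical(m$specificity + m$fpr, 1)
    expect_true(all(unlist(m[c("sensitivity", "specificity", "fpr", "fnr",
                               "precision", "f1")]) >= 0))
    expect_true(all(unlist(m[c("sensitivity", "specificity", "fpr", "fnr",
                               "precision", "f1")]) <= 1))
  }
})

test_that("the weighted macro average reduces correctly at its limits", {
  cnt <- confusion(c("A", "A", "B", "B"), c("A", "B", "B", "A"), c("A", "B"))
  m <- metrics_from_counts(cnt)
  eq <- weighted_macro(m, supports = c(1, 1))
  expect_equal(eq$sensitivity, mean(m$sensitivity))
  lop <- weighted_macro(m, supports = c(999, 1))
  expect_lt(abs(lop$sensitivity - m$sensitivity[1]),
            0.001 * abs(diff(m$sensitivity)) + 1e-12)
  expect_error(weighted_macro(m, supports = c(0, 0)), "supports")
})

test_that("the weighted macro average matches brute force on random inputs", {
  classes <- c("P", "Q", "R")
  set.seed(7)
  for (rep in 1:100) {
    truth <- sample(classes, 30, TRUE)
    est <- sample(classes, 30, TRUE)
    m <- metrics_from_counts(confusion(truth, est, classes), quiet = TRUE)
    agg <- weighted_macro(m)
    for (col in c("sensitivity", "specificity", "fpr", "fnr", "f1")) {
      expect_equal(agg[[col]], bf_weighted_mean(m[[col]], m$support))
    }
  }
})

test_that("metrics agree with brute force exhaustively on two-window problems", {
  classes <- c("A", "B", "C")
  grid <- expand.grid(t1 = classes, t2 = classes, p1 = classes, p2 = classes,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    truth <- c(grid$t1[i], grid$t2[i])
    est <- c(grid$p1[i], grid$p2[i])
    got <- metrics_from_counts(confusion(truth, est, classes), quiet = TRUE)
    want <- bf_confusion(truth, est, classes)
    expect_equal(got$tp, want$tp)
    expect_equal(got$fn, want$fn)
    for (j in seq_len(3)) {
      expect_equal(got$sensitivity[j], bf_metric(want$tp[j], want$tp[j] + want$fn[j]))
      expect_equal(got$specificity[j], bf_metric(want$tn[j], want$tn[j] + want$fp[j]))
    }
  }
})

test_that("quality filtering evaluates exactly the excellent windows", {
  pred <- tibble::tibble(
    rhythm = factor(rep(c("SINUS", "AF"), each = 4), c("SINUS", "AF")),
    af_pred = factor(c("SINUS", "SINUS", "AF", "SINUS",
                       "AF", "AF", "SINUS", "AF"), c("SINUS", "AF")),
    qa = factor(c("EXCELLENT", "EXCELLENT", "POOR", "EXCELLENT",
                  "EXCELLENT", "ACCEPTABLE", "EXCELLENT", "EXCELLENT"),
                c("EXCELLENT", "ACCEPTABLE", "POOR")))
  out <- qa_filtered_eval(pred, quiet = TRUE)
  expect_equal(out$retained, 6)
  expect_equal(out$retention, 6 / 8)
  all_exc <- pred
  all_exc$qa <- factor("EXCELLENT", levels(pred$qa))
  expect_equal(glance(qa_filtered_eval(all_exc, quiet = TRUE)$report),
               glance(metrics_report(pred$rhythm, pred$af_pred, quiet = TRUE)))
  none <- pred
  none$qa <- factor("POOR", levels(pred$qa))
  expect_error(qa_filtered_eval(none), class = "ppgnet_empty_report")
})

test_that("per-individual aggregation nests weighted macro within subject", {
  pred <- tibble::tibble(
    subject_id = rep("S1", 6),
    rhythm = factor(c("AF", "AF", "SINUS", "SINUS", "AF", "SINUS"),
                    c("SINUS", "AF")),
    af_pred = factor(c("AF", "SINUS", "SINUS", "AF", "AF", "SINUS"),
                     c("SINUS", "AF")))
  single <- per_individual_aggregate(pred)
  overall <- glance(metrics_report(pred$rhythm, pred$af_pred, quiet = TRUE))
  expect_equal(single$sensitivity, overall$sensitivity)
  expect_equal(single$f1, overall$f1)
  twice <- dplyr::bind_rows(pred, dplyr::mutate(pred, subject_id = "S2"))
  dup <- per_individual_aggregate(twice)
  expect_equal(dup$sensitivity, single$sensitivity)
  expect_equal(dup$n_subjects, 2L)
})

test_that("per-individual aggregation matches brute force and drops undefined metrics", {
  classes <- c("SINUS", "AF")
  set.seed(11)
  pred <- tibble::tibble(
    subject_id = rep(paste0("S", 1:5), each = 20),
    rhythm = factor(sample(classes, 100, TRUE), classes),
    af_pred = factor(sample(classes, 100, TRUE), classes))
  got <- per_individual_aggregate(pred)
  per <- lapply(split(pred, pred$subject_id), function(d) {
    cnt <- bf_confusion(d$rhythm, d$af_pred, classes)
    sens <- vapply(seq_len(2), function(j)
      bf_metric(cnt$tp[j], cnt$tp[j] + cnt$fn[j], NA_real_), 0)
    sup <- cnt$tp + cnt$fn
    c(sens = bf_weighted_mean(sens, sup), n = nrow(d))
  })
  per <- do.call(rbind, per)
  expect_equal(got$sensitivity, bf_weighted_mean(per[, "sens"], per[, "n"]))
  # a one-class subject produces undefined specificity, excluded with a note
  solo <- tibble::tibble(
    subject_id = c(rep("S1", 4), rep("S2", 4)),
    rhythm = factor(c(rep("AF", 4), rep("SINUS", 2), rep("AF", 2)), classes),
    af_pred = factor(rep(c("AF", "SINUS"), 4), classes))
  expect_message(out <- per_individual_aggregate(solo), "excluded")
  expect_true(is.finite(out$sensitivity))
})
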