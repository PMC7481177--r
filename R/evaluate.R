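#' One-vs-rest confusion counts
#'
#' Exact integer confusion counts per class, treating each class in turn as
#' positive.  For every class, `tp + fp + tn + fn` equals the number of
#' windows.
#'
#' @param truth,estimate Vectors (factor or character) of equal length.
#' @param classes Class set; labels outside it are an error.  Defaults to
#'   the union of levels/values in `truth` and `estimate`.
#' @return Tibble with columns `class`, `tp`, `fp`, `tn`, `fn`, `support`.
#' @export
confusion <- function(truth, estimate, classes = NULL) {
  if (length(truth) != length(estimate)) {
    abort_field("estimate", "must have the same length as truth")
  }
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  if (is.null(classes)) classes <- sort(unique(c(truth, estimate)))
  bad <- setdiff(unique(c(truth, estimate)), classes)
  if (length(bad)) {
    abort_field("classes", paste("labels outside the class set:",
                                 paste(bad, collapse = ", ")))
  }
  purrr::map_dfr(classes, function(cl) {
    tp <- sum(truth == cl & estimate == cl)
    fp <- sum(truth != cl & estimate == cl)
    fn <- sum(truth == cl & estimate != cl)
    tn <- length(truth) - tp - fp - fn
    tibble::tibble(class = cl, tp = tp, fp = fp, tn = tn, fn = fn,
                   support = tp + fn)
  })
}

#' Per-class metrics from confusion counts
#'
#' Sensitivity (recall) `tp/(tp+fn)`, specificity `tn/(tn+fp)`,
#' false-positive rate `fp/(fp+tn)`, false-negative rate `fn/(fn+tp)`,
#' precision `tp/(tp+fp)`, and F1 (the harmonic mean of precision and
#' recall).  By construction sensitivity + FNR = 1 and specificity + FPR
#' = 1 whenever the denominators are positive.  A zero denominator yields 0
#' with a warning (or `NA` with `na_undefined = TRUE`, used by the
#' per-individual aggregation to drop undefined metrics instead).
#'
#' @param counts Tibble from [confusion()] (columns `tp`, `fp`, `tn`,
#'   `fn`; extra columns such as `tp`-derived `support` are kept).
#' @param na_undefined Return `NA` instead of 0 for undefined metrics.
#' @param quiet Suppress the zero-denominator warning.
#' @return `counts` with metric columns appended.
#' @export
metrics_from_counts <- function(counts, na_undefined = FALSE, quiet = FALSE) {
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(counts)))
  if (any(counts[c("tp", "fp", "tn", "fn")] < 0)) {
    abort_field("counts", "must be non-negative")
  }
  fill <- if (na_undefined) NA_real_ else 0
  div <- function(num, den) ifelse(den > 0, num / den, fill)
  out <- counts
  out$sensitivity <- div(counts$tp, counts$tp + counts$fn)
  out$specificity <- div(counts$tn, counts$tn + counts$fp)
  out$fpr <- div(counts$fp, counts$fp + counts$tn)
  out$fnr <- div(counts$fn, counts$fn + counts$tp)
  out$precision <- div(counts$tp, counts$tp + counts$fp)
  pr <- out$precision + out$sensitivity
  out$f1 <- ifelse(!is.na(pr) & pr > 0,
                   2 * out$precision * out$sensitivity / pr, fill)
  degenerate <- any((counts$tp + counts$fn) == 0 | (counts$tn + counts$fp) == 0 |
                      (counts$tp + counts$fp) == 0)
  if (degenerate && !quiet) {
    rlang::warn(paste("zero-denominator metric set to",
                      if (na_undefined) "NA" else "0"))
  }
  out
}

#' Support-weighted macro average
#'
#' Aggregates per-class metrics as `sum(support_c * metric_c) /
#' sum(support_c)`; with equal supports this is the plain macro mean.
#' `NA` metrics (undefined denominators under `na_undefined = TRUE`) are
#' excluded from their metric's average.
#'
#' @param metrics Tibble from [metrics_from_counts()].
#' @param supports Non-negative class weights, not all zero (defaults to
#'   the `support` column, i.e. true class frequencies).
#' @return One-row tibble of aggregated metrics with `weighting =
#'   "WEIGHTED_MACRO"` and `n = sum(supports)`.
#' @export
weighted_macro <- function(metrics, supports = metrics$support) {
  if (any(supports < 0) || sum(supports) == 0) {
    abort_field("supports", "must be non-negative and not all zero")
  }
  wm <- function(v) {
    ok <- !is.na(v)
    if (!any(ok & supports > 0)) return(NA_real_)
    sum(v[ok] * supports[ok]) / sum(supports[ok])
  }
  tibble::tibble(
    sensitivity = wm(metrics$sensitivity),
    specificity = wm(metrics$specificity),
    fpr = wm(metrics$fpr), fnr = wm(metrics$fnr),
    precision = wm(metrics$precision), f1 = wm(metrics$f1),
    weighting = "WEIGHTED_MACRO", n = sum(supports)
  )
}

#' Full metrics report for a prediction set
#'
#' Convenience wrapper: confusion counts, per-class metrics, and the
#' support-weighted macro aggregate, bundled as a `metrics_report`.
#'
#' @inheritParams confusion
#' @param quiet Suppress zero-denominator warnings.
#' @return A `metrics_report` (list with `per_class` and `aggregate`
#'   tibbles); `tidy()` and `glance()` methods return them.
#' @export
metrics_report <- function(truth, estimate, classes = NULL, quiet = FALSE) {
  per_class <- metrics_from_counts(confusion(truth, estimate, classes),
                                   quiet = quiet)
  structure(list(per_class = per_class,
                 aggregate = weighted_macro(per_class),
                 weighting = "WEIGHTED_MACRO"),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> weighted macro-average over",
      nrow(x$per_class), "classes, n =", x$aggregate$n, "\n")
  print(x$aggregate[, c("sensitivity", "specificity", "fpr", "fnr", "f1")])
  invisible(x)
}

#' Evaluate only windows of excellent signal quality
#'
#' Applies the quality gate used for deployment-style reporting: metrics
#' are computed over windows whose quality label (predicted or oracle) is
#' `EXCELLENT`, and the retained count and fraction are reported alongside.
#'
#' @param predictions Tibble with truth, estimate and quality columns.
#' @param truth,estimate,qa Column names (defaults `rhythm`, `af_pred`,
#'   `qa`).
#' @param classes Optional class set for the confusion counts.
#' @param quiet Suppress zero-denominator warnings.
#' @return List: `report` (a [metrics_report()]), `retained`, `total`,
#'   `retention`.
#' @export
qa_filtered_eval <- function(predictions, truth = "rhythm",
                             estimate = "af_pred", qa = "qa",
                             classes = NULL, quiet = FALSE) {
  stopifnot(all(c(truth, estimate, qa) %in% names(predictions)))
  if (anyNA(predictions[[qa]])) {
    abort_field("qa", "every prediction needs a quality label")
  }
  keep <- as.character(predictions[[qa]]) == "EXCELLENT"
  if (!any(keep)) {
    rlang::abort("no windows of EXCELLENT quality retained; report would be empty",
                 class = "ppgnet_empty_report")
  }
  kept <- predictions[keep, , drop = FALSE]
  list(report = metrics_report(kept[[truth]], kept[[estimate]], classes,
                               quiet = quiet),
       retained = sum(keep), total = nrow(predictions),
       retention = mean(keep))
}

#' Metrics aggregated across individuals
#'
#' Computes the weighted macro-averaged metrics within each subject, then
#' averages across subjects with window counts as weights.  Metrics that
#' are undefined for a subject (e.g. specificity when a subject has only
#' one true class) are excluded from that metric's average, with a message.
#'
#' @param predictions Tibble with truth, estimate and subject columns.
#' @param truth,estimate,subject Column names.
#' @param classes Optional class set.
#' @return One-row tibble of across-individual metrics plus `n_subjects`.
#' @export
per_individual_aggregate <- function(predictions, truth = "rhythm",
                                     estimate = "af_pred",
                                     subject = "subject_id",
                                     classes = NULL) {
  stopifnot(all(c(truth, estimate, subject) %in% names(predictions)))
  if (is.null(classes)) {
    classes <- sort(unique(c(as.character(predictions[[truth]]),
                             as.character(predictions[[estimate]]))))
  }
  per_subj <- predictions |>
    dplyr::group_by(.subject = .data[[subject]]) |>
    dplyr::group_modify(function(d, key) {
      m <- metrics_from_counts(confusion(d[[truth]], d[[estimate]], classes),
                               na_undefined = TRUE, quiet = TRUE)
      agg <- weighted_macro(m)
      agg$n_windows <- nrow(d)
      agg
    }) |>
    dplyr::ungroup()
  cols <- c("sensitivity", "specificity", "fpr", "fnr", "precision", "f1")
  dropped <- sum(is.na(per_subj[cols]))
  if (dropped > 0) {
    rlang::inform(sprintf(
      "%d undefined per-subject metric value(s) excluded from the across-individual average",
      dropped))
  }
  out <- tibble::as_tibble(lapply(per_subj[cols], function(v) {
    ok <- !is.na(v)
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * per_subj$n_windows[ok]) / sum(per_subj$n_windows[ok])
  }))
  out$weighting <- "PER_INDIVIDUAL"
  out$n_subjects <- nrow(per_subj)
  out
}
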