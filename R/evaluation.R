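## Diagnostic-performance engine. TT is the positive class everywhere.

#' Confusion counts at a decision threshold
#'
#' @param calls character vector of calls (`"TT"`/`"IDA"`).
#' @param labels character vector of true labels, same length.
#' @return object of class `confusion_counts` with fields `tp`, `fp`,
#'   `fn`, `tn`.
#' @examples
#' confusion_counts(c("TT", "TT", "IDA"), c("TT", "IDA", "IDA"))
#' @export
confusion_counts <- function(calls, labels) {
  if (length(calls) != length(labels))
    stop_ts("calls and labels differ in length (", length(calls), " vs ",
            length(labels), ")")
  chk <- function(x, what) {
    if (length(x) && any(!x %in% c("TT", "IDA")))
      stop_ts(what, " must be \"TT\" or \"IDA\"")
  }
  chk(calls, "calls"); chk(labels, "labels")
  structure(list(
    tp = sum(calls == "TT" & labels == "TT"),
    fp = sum(calls == "TT" & labels == "IDA"),
    fn = sum(calls == "IDA" & labels == "TT"),
    tn = sum(calls == "IDA" & labels == "IDA")
  ), class = "confusion_counts")
}

#' Build confusion counts from raw integers
#'
#' @param tp,fp,fn,tn nonnegative integers; TT is the positive class.
#' @return `confusion_counts`.
#' @export
as_confusion_counts <- function(tp, fp, fn, tn) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(v < 0) || any(v != round(v)))
    stop_ts("counts must be nonnegative integers")
  structure(as.list(v), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  FP %d  FN %d  TN %d  (n = %d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

clopper_pearson <- function(x, n) {
  ## exact binomial interval; lower bound is exactly 0 at x = 0 and the
  ## upper exactly 1 at x = n
  as.numeric(binom.test(x, n)$conf.int)
}

#' Accuracy metrics (with exact binomial CIs) from confusion counts
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(FP+TN), accuracy =
#' (TP+TN)/n, all as percentages; Youden index = sensitivity/100 +
#' specificity/100 - 1 as a fraction. The three proportions carry exact
#' Clopper-Pearson 95% intervals. AUC is not derivable from a single
#' confusion table; see [auc()].
#'
#' @param counts `confusion_counts`.
#' @return object of class `performance_metrics`: `accuracy`,
#'   `sensitivity`, `specificity` (percent), `youden` (fraction), and
#'   `<metric>_ci` two-element vectors.
#' @examples
#' metrics_from_counts(as_confusion_counts(188, 22, 41, 179))
#' @export
metrics_from_counts <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n_pos <- counts$tp + counts$fn
  n_neg <- counts$fp + counts$tn
  if (n_pos == 0 || n_neg == 0)
    stop_ts("metrics need at least one subject in each class ",
            "(TP+FN > 0 and FP+TN > 0)")
  n <- n_pos + n_neg
  sens <- counts$tp / n_pos
  spec <- counts$tn / n_neg
  acc <- (counts$tp + counts$tn) / n
  structure(list(
    accuracy = 100 * acc,
    sensitivity = 100 * sens,
    specificity = 100 * spec,
    youden = sens + spec - 1,
    accuracy_ci = 100 * clopper_pearson(counts$tp + counts$tn, n),
    sensitivity_ci = 100 * clopper_pearson(counts$tp, n_pos),
    specificity_ci = 100 * clopper_pearson(counts$tn, n_neg),
    counts = counts
  ), class = "performance_metrics")
}

#' @export
print.performance_metrics <- function(x, ...) {
  cat(sprintf(
    "<performance_metrics> acc %.2f%% (%.2f-%.2f)  sens %.2f%% (%.2f-%.2f)  spec %.2f%% (%.2f-%.2f)  youden %.2f\n",
    round_half_up(x$accuracy), x$accuracy_ci[1], x$accuracy_ci[2],
    round_half_up(x$sensitivity), x$sensitivity_ci[1], x$sensitivity_ci[2],
    round_half_up(x$specificity), x$specificity_ci[1], x$specificity_ci[2],
    round_half_up(x$youden)))
  invisible(x)
}

## ---------------------------------------------------------------------
## ROC machinery

check_scores_labels <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop_ts("scores and labels differ in length")
  if (any(!labels %in% c("TT", "IDA")))
    stop_ts("labels must be \"TT\" or \"IDA\"")
  if (any(!is.finite(scores)))
    stop_ts("scores must be finite")
  if (!all(c("TT", "IDA") %in% labels))
    stop_ts("both classes must be present")
}

roc_thresholds <- function(scores) {
  s <- sort(unique(scores))
  if (length(s) == 1L) c(-Inf, Inf)
  else c(-Inf, (s[-length(s)] + s[-1]) / 2, Inf)
}

#' Empirical ROC curve
#'
#' Thresholds are placed at midpoints between consecutive distinct
#' observed scores, plus infinite endpoints, so tied subjects always fall
#' together on one side of every threshold. With `direction = "lower"`
#' (smaller scores favor TT) a subject is called TT when its score is
#' below the threshold; with `"higher"`, above.
#'
#' @param scores finite numeric scores.
#' @param labels `"TT"`/`"IDA"` truth, both classes present.
#' @param direction `"lower"` or `"higher"`: which side of the threshold
#'   is called TT.
#' @return object of class `roc_curve`: a data frame with columns
#'   `threshold`, `fpr`, `tpr`, `sensitivity`, `specificity`, ordered
#'   from (0,0) to (1,1), with the direction stored as an attribute.
#' @examples
#' roc_curve(c(1, 2, 3, 4), c("TT", "TT", "IDA", "IDA"), "lower")
#' @export
roc_curve <- function(scores, labels, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  check_scores_labels(scores, labels)
  is_tt <- labels == "TT"
  m <- sum(is_tt); n <- sum(!is_tt)
  th <- roc_thresholds(scores)
  pts <- vapply(th, function(t) {
    called_tt <- if (direction == "lower") scores < t else scores > t
    c(fpr = sum(called_tt & !is_tt) / n, tpr = sum(called_tt & is_tt) / m)
  }, c(fpr = 0, tpr = 0))
  out <- data.frame(threshold = th, fpr = pts["fpr", ], tpr = pts["tpr", ])
  out <- out[order(out$fpr, out$tpr), ]
  rownames(out) <- NULL
  out$sensitivity <- 100 * out$tpr
  out$specificity <- 100 * (1 - out$fpr)
  structure(out, class = c("roc_curve", "data.frame"),
            direction = direction, n_tt = m, n_ida = n)
}

trapezoid_area <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

delong_variance <- function(scores, is_tt, direction) {
  x <- scores[is_tt]; y <- scores[!is_tt]
  m <- length(x); n <- length(y)
  ## psi(x, y): 1 when the TT score lies on the TT side of the IDA score
  cmp <- outer(x, y, function(a, b)
    if (direction == "lower") (a < b) + 0.5 * (a == b)
    else (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(cmp)   # placement of each TT subject
  v01 <- colMeans(cmp)   # placement of each IDA subject
  list(auc = mean(cmp), var = var(v10) / m + var(v01) / n)
}

#' Area under the ROC curve with DeLong confidence interval
#'
#' The trapezoid area under the midpoint-threshold empirical ROC curve,
#' which equals the Mann-Whitney concordance probability (ties counted
#' one half): the probability that a random TT subject's score lies on
#' the TT side of a random IDA subject's score. The 95% CI uses DeLong's
#' placement-value variance estimate, truncated to [0, 1]; it collapses
#' to a point when the variance is zero (perfect separation).
#'
#' @inheritParams roc_curve
#' @param conf confidence level (default 0.95).
#' @return list with `auc`, `ci` (length-2), `direction`.
#' @examples
#' auc(c(1, 2, 3, 4), c("TT", "TT", "IDA", "IDA"), "lower")$auc  # 1
#' @export
auc <- function(scores, labels, direction = c("lower", "higher"),
                conf = 0.95) {
  direction <- match.arg(direction)
  check_scores_labels(scores, labels)
  d <- delong_variance(scores, labels == "TT", direction)
  z <- qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(max(d$var, 0))
  list(auc = d$auc,
       ci = c(max(0, d$auc - half), min(1, d$auc + half)),
       direction = direction)
}

#' Youden-optimal cutpoint
#'
#' Maximizes the Youden index (sensitivity + specificity - 1) over the
#' same midpoint threshold grid as [roc_curve()]. Ties between equally
#' good thresholds resolve to the one with the highest sensitivity and
#' then to the smallest threshold value -- in a screening setting,
#' sensitivity is favored.
#'
#' @inheritParams roc_curve
#' @return list with `cutoff`, `youden`, `sensitivity`, `specificity`
#'   (the latter two in percent).
#' @examples
#' youden_optimal_cutpoint(c(1, 2, 3, 4), c("TT", "TT", "IDA", "IDA"),
#'                         "lower")  # cutoff 2.5, youden 1
#' @export
youden_optimal_cutpoint <- function(scores, labels,
                                    direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  rc <- roc_curve(scores, labels, direction)
  j <- rc$tpr - rc$fpr
  best <- which(j == max(j))
  if (length(best) > 1L) {
    best <- best[rc$tpr[best] == max(rc$tpr[best])]
    if (length(best) > 1L)
      best <- best[which.min(rc$threshold[best])]
  }
  list(cutoff = rc$threshold[best], youden = j[best],
       sensitivity = 100 * rc$tpr[best], specificity = 100 * (1 - rc$fpr[best]))
}

## ---------------------------------------------------------------------
## Cohort-level evaluation report

#' Evaluate the formula panel on a labeled cohort
#'
#' Produces a diagnostic-performance table with one row per evaluable
#' formula: DeLong-CI AUC, the Youden-optimal cutoff found on this
#' cohort, the cutoff actually used for calls (published or optimal, per
#' `cutoff_policy`), confusion counts and accuracy metrics. Formulas
#' whose required fields are missing for any subject are returned in the
#' `skipped` attribute with the missing fields named. Rows are ranked by
#' Youden index, descending, by default.
#'
#' @param cohort labeled canonical cohort data frame with at least one
#'   subject in each class.
#' @param cutoff_policy `"published"` (default) or `"optimal"`: threshold
#'   used for the confusion counts and derived metrics.
#' @param mode unit mode passed to [evaluate_formula()].
#' @param formula_ids subset of slugs (default: all 44).
#' @param rank_by column to sort by, descending (default `"youden"`); use
#'   `NULL` to keep registry order.
#' @return data frame of class `cohort_evaluation`; skipped formulas in
#'   `attr(, "skipped")`.
#' @export
evaluate_cohort <- function(cohort, cutoff_policy = c("published", "optimal"),
                            mode = "paper", formula_ids = NULL,
                            rank_by = "youden") {
  cutoff_policy <- match.arg(cutoff_policy)
  cohort <- as_cbc_cohort(cohort)
  if (anyNA(cohort$label))
    stop_ts("evaluate_cohort requires a label for every subject")
  if (!all(c("TT", "IDA") %in% cohort$label))
    stop_ts("cohort must contain both TT and IDA subjects")
  specs <- registry()
  if (!is.null(formula_ids)) {
    bad <- setdiff(formula_ids, names(specs))
    if (length(bad)) stop_ts("unknown formula id: ", paste(bad, collapse = ", "))
    specs <- specs[formula_ids]
  }
  skipped <- list()
  rows <- list()
  for (spec in specs) {
    missing <- spec$required_fields[vapply(spec$required_fields, function(f)
      anyNA(cohort[[f]]), logical(1))]
    if (length(missing)) {
      skipped[[spec$id]] <- paste("missing:", paste(missing, collapse = ", "))
      next
    }
    score <- evaluate_formula(spec, cohort, mode)
    dir <- formula_direction(spec)
    a <- auc(score, cohort$label, dir)
    oc <- youden_optimal_cutpoint(score, cohort$label, dir)
    cutoff_used <- if (cutoff_policy == "published") spec$cutoff else oc$cutoff
    tt <- apply_comparator(score, spec$comparator, cutoff_used)
    cc <- confusion_counts(ifelse(tt, "TT", "IDA"), cohort$label)
    pm <- metrics_from_counts(cc)
    rows[[spec$id]] <- data.frame(
      formula_id = spec$id, name = spec$name,
      auc = a$auc, auc_lo = a$ci[1], auc_hi = a$ci[2],
      optimal_cutoff = oc$cutoff, published_cutoff = spec$cutoff,
      cutoff_used = cutoff_used, cutoff_policy = cutoff_policy,
      comparator = spec$comparator,
      tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
      accuracy = pm$accuracy, sensitivity = pm$sensitivity,
      specificity = pm$specificity, youden = pm$youden,
      sensitivity_lo = pm$sensitivity_ci[1],
      sensitivity_hi = pm$sensitivity_ci[2],
      specificity_lo = pm$specificity_ci[1],
      specificity_hi = pm$specificity_ci[2],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop_ts("no evaluable formula for this cohort")
  rownames(out) <- NULL
  if (!is.null(rank_by)) {
    if (!rank_by %in% names(out)) stop_ts("unknown rank_by column: ", rank_by)
    out <- out[order(out[[rank_by]], decreasing = TRUE), ]
    rownames(out) <- NULL
  }
  structure(out, class = c("cohort_evaluation", "data.frame"),
            skipped = skipped)
}

#' Write an evaluation report
#'
#' `write_report_csv()` rounds percent metrics and Youden to two decimal
#' places and AUC to three (half-up, presentation only);
#' `write_report_json()` writes the full-precision table.
#'
#' @param report `cohort_evaluation` data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  out <- as.data.frame(report)
  for (col in c("accuracy", "sensitivity", "specificity", "youden",
                "sensitivity_lo", "sensitivity_hi",
                "specificity_lo", "specificity_hi"))
    out[[col]] <- round_half_up(out[[col]], 2)
  for (col in c("auc", "auc_lo", "auc_hi"))
    out[[col]] <- round_half_up(out[[col]], 3)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report_csv
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(
    list(report = as.data.frame(report),
         skipped = attr(report, "skipped") %||% list()),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Dump ROC curve points for a set of formulas
#'
#' Long-format table (formula_id, threshold, fpr, tpr) suitable for
#' plotting ROC comparisons.
#'
#' @inheritParams evaluate_cohort
#' @return data frame.
#' @export
roc_points <- function(cohort, formula_ids = NULL, mode = "paper") {
  cohort <- as_cbc_cohort(cohort)
  specs <- registry()
  if (!is.null(formula_ids)) {
    bad <- setdiff(formula_ids, names(specs))
    if (length(bad)) stop_ts("unknown formula id: ", paste(bad, collapse = ", "))
    specs <- specs[formula_ids]
  }
  rows <- list()
  for (spec in specs) {
    ok <- !vapply(spec$required_fields, function(f) anyNA(cohort[[f]]),
                  logical(1))
    if (!all(ok)) next
    score <- evaluate_formula(spec, cohort, mode)
    rc <- roc_curve(score, cohort$label, formula_direction(spec))
    rows[[spec$id]] <- data.frame(formula_id = spec$id,
                                  threshold = rc$threshold,
                                  fpr = rc$fpr, tpr = rc$tpr,
                                  stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reference validation-study confusion counts
#'
#' The per-formula confusion counts (TP, FP, FN, TN at the published
#' cutoffs; 229 TT and 201 IDA first-trimester subjects) and printed
#' metrics reported by the validation study that introduced the XS-1
#' index. Used as a regression fixture: feeding each count quadruple
#' through [metrics_from_counts()] must reproduce every printed metric at
#' two-decimal rounding.
#'
#' @return data frame with one row per formula.
#' @export
reference_counts <- function() {
  read.csv(system.file("extdata", "reference_confusion_counts.csv",
                       package = "thalscreen", mustWork = TRUE),
           stringsAsFactors = FALSE)
}
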