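test_that("confusion counts tally calls against truth with TT positive", {
  cc <- confusion_counts(c("TT", "TT", "TT", "IDA", "IDA"),
                         c("TT", "TT", "TT", "IDA", "IDA"))
  expect_identical(unclass(cc)[c("tp", "fp", "fn", "tn")],
                   list(tp = 3L, fp = 0L, fn = 0L, tn = 2L))
  # an everyone-is-TT caller on a 229/201 cohort
  labels <- rep(c("TT", "IDA"), c(229, 201))
  cc2 <- confusion_counts(rep("TT", 430), labels)
  expect_identical(c(cc2$tp, cc2$fp, cc2$fn, cc2$tn), c(229L, 201L, 0L, 0L))

  cc3 <- confusion_counts(character(0), character(0))
  expect_identical(c(cc3$tp, cc3$fp, cc3$fn, cc3$tn), c(0L, 0L, 0L, 0L))

  expect_error(confusion_counts("TT", c("TT", "IDA")), "length")
  expect_error(confusion_counts("maybe", "TT"), "must be")
})

test_that("metrics match the printed two-decimal values for known count sets", {
  m <- metrics_from_counts(as_confusion_counts(188, 22, 41, 179))
  expect_equal(round_half_up(m$sensitivity), 82.10)
  expect_equal(round_half_up(m$specificity), 89.05)
  expect_equal(round_half_up(m$accuracy), 85.35)
  expect_equal(round_half_up(m$youden), 0.71)

  # a formula can do worse than chance: negative Youden
  b <- metrics_from_counts(as_confusion_counts(131, 169, 98, 32))
  expect_equal(round_half_up(b$youden), -0.27)

  z <- metrics_from_counts(as_confusion_counts(0, 0, 5, 5))
  expect_equal(z$sensitivity, 0)
  expect_equal(z$specificity, 100)

  expect_error(metrics_from_counts(as_confusion_counts(0, 0, 0, 5)),
               "each class")
})

test_that("proportion intervals are exact Clopper-Pearson with hard boundaries", {
  m <- metrics_from_counts(as_confusion_counts(0, 0, 10, 10))
  expect_identical(m$sensitivity_ci[1], 0)
  expect_identical(m$specificity_ci[2], 100)
  # interval always contains the point estimate
  for (cc in list(c(188, 22, 41, 179), c(3, 1, 2, 4))) {
    mm <- metrics_from_counts(do.call(as_confusion_counts, as.list(cc)))
    expect_true(mm$sensitivity_ci[1] <= mm$sensitivity &&
                  mm$sensitivity <= mm$sensitivity_ci[2])
    expect_true(mm$specificity_ci[1] <= mm$specificity &&
                  mm$specificity <= mm$specificity_ci[2])
    expect_true(mm$accuracy_ci[1] <= mm$accuracy &&
                  mm$accuracy <= mm$accuracy_ci[2])
  }
  # cross-check one interval against binom.test directly
  ci <- stats::binom.test(188, 229)$conf.int
  m188 <- metrics_from_counts(as_confusion_counts(188, 22, 41, 179))
  expect_equal(m188$sensitivity_ci, 100 * as.numeric(ci))
})

test_that("sensitivity depends only on the TT margin, specificity on the IDA margin", {
  a <- metrics_from_counts(as_confusion_counts(10, 3, 5, 7))
  b <- metrics_from_counts(as_confusion_counts(10, 50, 5, 2))
  expect_identical(a$sensitivity, b$sensitivity)
  c1 <- metrics_from_counts(as_confusion_counts(1, 3, 9, 7))
  expect_identical(a$specificity, c1$specificity)
})

test_that("ROC curves run (0,0) to (1,1), monotone, with tied scores together", {
  rc <- roc_curve(c(1, 2, 3, 4), c("TT", "TT", "IDA", "IDA"), "lower")
  expect_identical(c(rc$fpr[1], rc$tpr[1]), c(0, 0))
  expect_identical(c(rc$fpr[nrow(rc)], rc$tpr[nrow(rc)]), c(1, 1))
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
  expect_true(any(rc$fpr == 0 & rc$tpr == 1)) # perfect separation corner

  flat <- roc_curve(rep(2, 6), rep(c("TT", "IDA"), 3), "lower")
  expect_identical(nrow(flat), 2L)
  expect_identical(flat$fpr, c(0, 1))
  expect_identical(flat$tpr, c(0, 1))

  expect_error(roc_curve(1:3, rep("TT", 3), "lower"), "both classes")
})

test_that("ROC points match a brute-force threshold sweep on a tied 6-subject set", {
  scores <- c(1, 2, 2, 3, 3, 4)
  labels <- c("TT", "TT", "IDA", "TT", "IDA", "IDA")
  rc <- roc_curve(scores, labels, "lower")
  sweep <- unique(t(vapply(seq(0, 5, by = 0.25), function(t) {
    c(fpr = mean(scores[labels == "IDA"] < t),
      tpr = mean(scores[labels == "TT"] < t))
  }, c(fpr = 0, tpr = 0))))
  got <- unique(rc[, c("fpr", "tpr")])
  expect_identical(nrow(got), nrow(sweep))
  for (i in seq_len(nrow(sweep)))
    expect_true(any(got$fpr == sweep[i, "fpr"] & got$tpr == sweep[i, "tpr"]))
})

test_that("trapezoid AUC equals pairwise concordance and honors symmetries", {
  expect_identical(auc(c(1, 2, 3, 4), c("TT", "TT", "IDA", "IDA"),
                       "lower")$auc, 1)
  expect_identical(auc(rep(1, 8), rep(c("TT", "IDA"), 4), "lower")$auc, 0.5)

  inst <- random_roc_instance(20)
  a <- auc(inst$scores, inst$labels, inst$direction)
  expect_equal(a$auc, oracle_auc(inst$scores, inst$labels, inst$direction),
               tolerance = 1e-12)
  # curve integration agrees with the rank statistic
  rc <- roc_curve(inst$scores, inst$labels, inst$direction)
  trap <- sum(diff(rc$fpr) * (rc$tpr[-1] + rc$tpr[-nrow(rc)]) / 2)
  expect_equal(trap, a$auc, tolerance = 1e-12)

  # complement and monotone-transform invariance (tie-free scores)
  set.seed(31)
  s <- rnorm(30)
  l <- rep(c("TT", "IDA"), 15)
  expect_equal(auc(s, l, "lower")$auc + auc(-s, l, "lower")$auc, 1)
  expect_equal(auc(exp(s), l, "lower")$auc, auc(s, l, "lower")$auc)
})

test_that("DeLong intervals bracket the AUC and match pROC", {
  skip_if_not_installed("pROC")
  inst <- random_roc_instance(77)
  a <- auc(inst$scores, inst$labels, inst$direction)
  expect_true(a$ci[1] <= a$auc && a$auc <= a$ci[2])
  pr <- pROC::roc(response = inst$labels, predictor = inst$scores,
                  levels = c("IDA", "TT"),
                  direction = if (inst$direction == "lower") ">" else "<",
                  quiet = TRUE)
  expect_equal(a$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_equal(a$ci, as.numeric(pROC::ci.auc(pr, method = "delong"))[c(1, 3)],
               tolerance = 1e-9)
})

test_that("the Youden-optimal cutpoint matches exhaustive search with stated tie-breaks", {
  oc <- youden_optimal_cutpoint(c(1, 2, 3, 4), c("TT", "TT", "IDA", "IDA"),
                                "lower")
  expect_equal(oc$cutoff, 2.5)
  expect_equal(oc$youden, 1)

  same <- youden_optimal_cutpoint(c(1, 2, 1, 2, 1, 2, 1, 2),
                                  rep(c("TT", "IDA"), each = 4), "lower")
  expect_equal(same$youden, 0)

  for (seed in 1:25) {
    inst <- random_roc_instance(seed)
    oc <- youden_optimal_cutpoint(inst$scores, inst$labels, inst$direction)
    expect_equal(oc$youden,
                 oracle_best_youden(inst$scores, inst$labels, inst$direction),
                 tolerance = 1e-12, label = paste("seed", seed))
    # stated tie-break: no equal-Youden threshold has higher sensitivity
    rc <- roc_curve(inst$scores, inst$labels, inst$direction)
    ties <- abs((rc$tpr - rc$fpr) - oc$youden) < 1e-12
    expect_gte(oc$sensitivity + 1e-9, max(100 * rc$tpr[ties]))
  }
})

test_that("cohort evaluation reports every evaluable formula with conserved margins", {
  cohort <- generate_cohort(cohort_spec(n_tt = 60, n_ida = 50), seed = 17)
  rep_pub <- evaluate_cohort(cohort, cutoff_policy = "published")
  expect_identical(nrow(rep_pub), 44L)
  expect_true(all(rep_pub$tp + rep_pub$fn == 60))
  expect_true(all(rep_pub$fp + rep_pub$tn == 50))
  # default ranking: Youden descending
  expect_true(all(diff(rep_pub$youden) <= 1e-12))

  # the optimal policy never does worse than the published cutoff
  rep_opt <- evaluate_cohort(cohort, cutoff_policy = "optimal",
                             rank_by = NULL)
  pub <- rep_pub[match(rep_opt$formula_id, rep_pub$formula_id), ]
  expect_true(all(rep_opt$youden >= pub$youden - 1e-12))

  # dropping mpv silences exactly the MPV-dependent formula
  no_mpv <- cohort
  no_mpv$mpv <- NA_real_
  rep2 <- evaluate_cohort(no_mpv)
  expect_identical(nrow(rep2), 43L)
  expect_named(attr(rep2, "skipped"), "chandra")

  expect_error(evaluate_cohort(cohort[cohort$label == "TT", ]),
               "both TT and IDA")
  expect_error(evaluate_cohort(transform(cohort, label = NA)), "label")
})

test_that("report writers round only at presentation and dump ROC points", {
  cohort <- generate_cohort(cohort_spec(n_tt = 30, n_ida = 30), seed = 23)
  report <- evaluate_cohort(cohort)
  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")
  write_report_csv(report, csv)
  write_report_json(report, json)
  back <- read.csv(csv)
  expect_identical(nrow(back), 44L)
  expect_equal(back$youden, round_half_up(report$youden, 2))
  jb <- jsonlite::fromJSON(json)
  expect_equal(jb$report$youden, report$youden, tolerance = 1e-12)

  pts <- roc_points(cohort, formula_ids = c("mentzer", "shine_lal"))
  expect_setequal(unique(pts$formula_id), c("mentzer", "shine_lal"))
  expect_true(all(pts$fpr >= 0 & pts$fpr <= 1 & pts$tpr >= 0 & pts$tpr <= 1))
})
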