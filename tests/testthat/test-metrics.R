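# Evaluation metrics and fold aggregation

test_that("confusion counts and summary metrics follow the formulas", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unlist(cc[c("TP", "FN", "TN", "FP")]),
               c(TP = 1, FN = 1, TN = 1, FP = 1))
  perfect <- confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(perfect$FP + perfect$FN, 0)
  expect_equal(unname(summary_metrics(perfect)), rep(1, 5))

  cc2 <- structure(list(TP = 3, FP = 1, FN = 1, TN = 5),
                   class = "confusion_counts")
  m <- summary_metrics(cc2)
  expect_equal(unname(m), c(0.8, 0.75, 5 / 6, 0.75, 0.75))
  expect_equal(m[["sensitivity"]] * (cc2$TP + cc2$FN), cc2$TP)

  warns <- capture_warnings(
    m0 <- summary_metrics(confusion_counts(c(0, 0), c(0, 0))))
  expect_true(all(grepl("undefined", warns)))
  expect_true(is.nan(m0[["sensitivity"]]))
  expect_true(is.nan(m0[["precision"]]))
  expect_error(confusion_counts(c(1, 0), c(1)), "length")
})

test_that("pairwise AUC matches a double-loop oracle including tie handling", {
  expect_equal(auc_pairwise(c(0.3, 0.4), c(0.1, 0.2)), 1.0)
  expect_equal(auc_pairwise(0.3, 0.3, tie_mode = "strict"), 0.0)
  expect_equal(auc_pairwise(0.3, 0.3, tie_mode = "half"), 0.5)
  set.seed(20)
  for (i in 1:5) {
    pos <- round(runif(20), 2)   # rounding forces some ties
    neg <- round(runif(20), 2)
    expect_equal(auc_pairwise(pos, neg, "strict"), oracle_auc(pos, neg))
    expect_equal(auc_pairwise(pos, neg, "half"), oracle_auc(pos, neg, half = TRUE))
    expect_lte(auc_pairwise(pos, neg, "strict"), auc_pairwise(pos, neg, "half"))
  }
  pos <- c(0.11, 0.52, 0.93); neg <- c(0.2, 0.4)   # no ties: modes agree
  expect_equal(auc_pairwise(pos, neg, "strict"), auc_pairwise(pos, neg, "half"))
  expect_error(auc_pairwise(numeric(0), 1), "nonempty")
})

test_that("reference fold table: F1 recomputation identifies the printed rounding", {
  ref <- rgd_reference_folds()
  expect_equal(nrow(ref), 10)
  f1 <- f1_score(ref$precision_pct / 100, ref$sensitivity_pct / 100)
  consistent <- abs(f1 - ref$f1) <= 5e-5
  # folds printed with enough precision recompute exactly; the rest reflect
  # 4-significant-digit input rounding, and fold 5's printed precision is
  # irreconcilable with its printed F1
  expect_true(all(consistent[c(1, 2, 3, 8, 10)]))
  expect_false(any(consistent[c(4, 5, 6, 7, 9)]))
  expect_gt(abs(f1[5] - ref$f1[5]), 0.04)
  expect_true(all(abs(f1 - ref$f1)[c(4, 6, 7, 9)] < 1e-4))
  expect_equal(round(f1[1], 4), 0.9153)
  expect_equal(round(f1[2], 4), 0.9355)
})

test_that("fold aggregation reproduces the published means", {
  ref <- rgd_reference_folds()
  m <- cbind(accuracy = ref$accuracy_pct, sensitivity = ref$sensitivity_pct,
             specificity = ref$specificity_pct, precision = ref$precision_pct,
             f1 = ref$f1, auc = ref$auc)
  agg <- aggregate_folds(m)
  expect_equal(round(unname(agg$mean["accuracy"]), 2), 93.25)
  expect_equal(round(unname(agg$mean["sensitivity"]), 2), 89.22)
  expect_equal(round(unname(agg$mean["specificity"]), 2), 95.82)
  expect_equal(round(unname(agg$mean["precision"]), 2), 92.46)
  expect_equal(round(unname(agg$mean["f1"]), 4), 0.9114)
  expect_equal(round(unname(agg$mean["auc"]), 4), 0.9629)

  single <- aggregate_folds(m[1, , drop = FALSE])
  expect_equal(unname(single$mean), unname(m[1, ]))
  expect_equal(unname(single$sd), rep(0, 6))
})

test_that("eval reports aggregate and export", {
  set.seed(2)
  reps <- lapply(1:3, function(i) {
    y <- rbinom(40, 1, 0.5)
    p <- ifelse(y == 1, runif(40, 0.3, 1), runif(40, 0, 0.7))
    eval_report(y, p)
  })
  agg <- aggregate_folds(reps)
  expect_equal(dim(agg$folds), c(3L, 6L))
  expect_true(all(agg$folds >= 0 & agg$folds <= 1))
  f <- withr::local_tempfile(fileext = ".csv")
  write_report(agg, f)
  expect_true(file.exists(f))
  expect_true(file.exists(sub("csv$", "txt", f)))
  got <- utils::read.csv(f)
  expect_equal(nrow(got), 4)   # 3 folds + mean row
})
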