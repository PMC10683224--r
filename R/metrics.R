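# Evaluation metrics ------------------------------------------------------------
#
# Malignant is the positive class throughout. AUC follows the pairwise
# ranking estimator: the fraction of (negative, positive) pairs where the
# positive sample scores strictly higher; ties count 0 in strict mode (the
# default) or 0.5 under the standard Mann-Whitney convention.

#' Confusion counts
#'
#' @param labels 0/1 truth (1 = malignant).
#' @param predictions 0/1 predicted classes.
#' @return An object of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(labels, predictions) {
  check_flag(length(labels) == length(predictions) && length(labels) > 0,
             "labels", "must match predictions in positive length")
  check_flag(all(labels %in% c(0, 1)) && all(predictions %in% c(0, 1)),
             "labels", "labels and predictions must be 0/1")
  structure(list(TP = sum(labels == 1 & predictions == 1),
                 TN = sum(labels == 0 & predictions == 0),
                 FP = sum(labels == 0 & predictions == 1),
                 FN = sum(labels == 1 & predictions == 0)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  FN %d  TN %d  FP %d (n = %d)\n",
              x$TP, x$FN, x$TN, x$FP, x$TP + x$TN + x$FP + x$FN))
  invisible(x)
}

#' Accuracy, sensitivity, specificity, precision and F1 from counts
#'
#' Exact formula evaluation; a zero denominator yields `NaN` with a warning.
#'
#' @param counts a [confusion_counts()].
#' @return Named numeric vector with `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `f1`.
#' @export
#' @examples
#' summary_metrics(confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1)))
summary_metrics <- function(counts) {
  check_flag(inherits(counts, "confusion_counts"), "counts",
             "must be a confusion_counts object")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what), call. = FALSE)
      return(NaN)
    }
    num / den
  }
  with(counts, {
    acc <- safe_div(TP + TN, TP + TN + FP + FN, "accuracy")
    sens <- safe_div(TP, TP + FN, "sensitivity")
    spec <- safe_div(TN, TN + FP, "specificity")
    prec <- safe_div(TP, TP + FP, "precision")
    f1 <- if (is.nan(prec) || is.nan(sens) || prec + sens == 0) {
      warning("f1 undefined", call. = FALSE)
      NaN
    } else 2 * prec * sens / (prec + sens)
    c(accuracy = acc, sensitivity = sens, specificity = spec,
      precision = prec, f1 = f1)
  })
}

#' F1 score from precision and recall
#'
#' @param precision,recall values in `[0, 1]`.
#' @return `2 * precision * recall / (precision + recall)`.
#' @export
f1_score <- function(precision, recall) {
  2 * precision * recall / (precision + recall)
}

#' Pairwise-ranking AUC
#'
#' `AUC = sum over (negative, positive) pairs of B(f(neg) < f(pos)) /
#' (|negatives| * |positives|)`. In `"strict"` mode (default) ties contribute
#' 0; in `"half"` mode ties are credited 0.5 (the Mann-Whitney convention).
#'
#' @param scores_pos scores of positive (malignant) samples.
#' @param scores_neg scores of negative (benign) samples.
#' @param tie_mode `"strict"` or `"half"`.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc_pairwise(c(0.3, 0.4), c(0.1, 0.2))  # 1
auc_pairwise <- function(scores_pos, scores_neg, tie_mode = c("strict", "half")) {
  tie_mode <- match.arg(tie_mode)
  check_flag(length(scores_pos) > 0 && length(scores_neg) > 0,
             "scores", "both classes must be nonempty")
  # rank-based count of pairs with neg < pos, O((n+m) log(n+m))
  r <- rank(c(scores_neg, scores_pos), ties.method = "average")
  n0 <- length(scores_neg); n1 <- length(scores_pos)
  u <- sum(r[n0 + seq_len(n1)]) - n1 * (n1 + 1) / 2   # wins + 0.5 * ties
  if (tie_mode == "half") return(u / (n0 * n1))
  # subtract half-credited ties to get the strict count
  ties <- 0
  tt <- table(c(scores_neg, scores_pos))
  if (any(tt > 1)) {
    tn <- table(scores_neg)
    tp <- table(scores_pos)
    common <- intersect(names(tn), names(tp))
    ties <- sum(as.numeric(tn[common]) * as.numeric(tp[common]))
  }
  (u - ties / 2) / (n0 * n1)
}

#' Evaluation report for one fold
#'
#' @param labels 0/1 truth.
#' @param probabilities predicted malignancy probabilities.
#' @param threshold decision threshold (class 1 iff probability >= threshold).
#' @param tie_mode AUC tie handling, see [auc_pairwise()].
#' @return An object of class `eval_report`: confusion counts plus the six
#'   metrics.
#' @export
eval_report <- function(labels, probabilities, threshold = 0.5,
                        tie_mode = "strict") {
  preds <- as.integer(probabilities >= threshold)
  counts <- confusion_counts(labels, preds)
  m <- summary_metrics(counts)
  auc <- auc_pairwise(probabilities[labels == 1], probabilities[labels == 0],
                      tie_mode = tie_mode)
  structure(list(counts = counts, metrics = c(m, auc = auc)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("<eval_report> acc %.4f  sens %.4f  spec %.4f  prec %.4f",
                     "  F1 %.4f  AUC %.4f\n"),
              m["accuracy"], m["sensitivity"], m["specificity"],
              m["precision"], m["f1"], m["auc"]))
  invisible(x)
}

#' Aggregate per-fold metrics
#'
#' Unweighted arithmetic mean and population standard deviation across folds
#' (not pooled counts).
#'
#' @param reports list of [eval_report()] objects, or a numeric matrix with
#'   one row per fold.
#' @return List with `mean` and `sd` named vectors and the per-fold matrix
#'   `folds`.
#' @export
aggregate_folds <- function(reports) {
  m <- if (is.matrix(reports)) reports
       else do.call(rbind, lapply(reports, function(r) r$metrics))
  check_flag(nrow(m) >= 1, "reports", "needs at least one fold")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  list(mean = colMeans(m), sd = apply(m, 2, pop_sd), folds = m)
}

#' Write per-fold and mean metrics as CSV and a text table
#'
#' @param agg an [aggregate_folds()] result.
#' @param file CSV output path; a `.txt` table is written alongside it.
#' @return Invisibly, the data frame written.
#' @export
write_report <- function(agg, file) {
  df <- as.data.frame(agg$folds)
  df <- cbind(fold = seq_len(nrow(df)), df)
  mean_row <- c(NA, agg$mean)
  out <- rbind(df, stats::setNames(as.list(mean_row), names(df)))
  utils::write.csv(out, file, row.names = FALSE)
  txt <- sub("\\.csv$", ".txt", file)
  lines <- c(sprintf("%-6s %s", "fold",
                     paste(sprintf("%12s", colnames(agg$folds)), collapse = " ")),
             vapply(seq_len(nrow(agg$folds)), function(i)
               sprintf("%-6d %s", i,
                       paste(sprintf("%12.4f", agg$folds[i, ]), collapse = " ")),
               character(1)),
             sprintf("%-6s %s", "mean",
                     paste(sprintf("%12.4f", agg$mean), collapse = " ")),
             sprintf("%-6s %s", "sd",
                     paste(sprintf("%12.4f", agg$sd), collapse = " ")))
  writeLines(lines, txt)
  invisible(out)
}

#' Reference fold-level results of the original 10-fold LIDC-IDRI evaluation
#'
#' The published per-fold accuracy, sensitivity, specificity and precision (in
#' percent), F1 score and AUC of the RGD ensemble on LIDC-IDRI, as printed;
#' used to check the metric formulas for internal consistency.
#'
#' @return Data frame with one row per fold.
#' @export
rgd_reference_folds <- function() {
  utils::read.csv(system.file("extdata", "rgd_lidc_reference_folds.csv",
                              package = "rgdfusion"))
}
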