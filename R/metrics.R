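# Evaluation metrics: accuracy and sensitivity at a decision threshold, the
# ROC curve swept over the observed scores, trapezoidal AUC (equivalent to
# the Mann-Whitney pairwise-ordering statistic with ties counted half), and
# the per-lesion-type accuracy breakdown.

#' Classification metrics for one task
#'
#' @param labels binary ground truth: logical, or numeric/integer 0/1
#'   (1 = positive class).
#' @param scores predicted positive-class scores in `[0, 1]`.
#' @param threshold decision threshold, default 0.5.
#' @return object of class `"eval_report"`: `accuracy`, `sensitivity`,
#'   `specificity`, `roc_points` (data frame `fpr`, `tpr` from (0,0) to
#'   (1,1)), `auc` (trapezoidal; `NA` with a warning when only one class is
#'   present), `threshold`, `n`.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(as.logical(labels))
  if (length(labels) != length(scores)) stop("labels and scores lengths differ")
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  acc <- (tp + tn) / length(labels)
  sens <- if (n_pos > 0L) tp / n_pos else NA_real_
  spec <- if (n_neg > 0L) tn / n_neg else NA_real_
  if (n_pos == 0L || n_neg == 0L) {
    warning("AUC undefined: only one class present in labels")
    roc <- data.frame(fpr = c(0, 1), tpr = c(0, 1))
    auc <- NA_real_
  } else {
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; y <- labels[ord]
    # cut after each distinct score value
    keep <- c(s[-length(s)] != s[-1L], TRUE)
    tpr <- c(0, cumsum(y)[keep] / n_pos)
    fpr <- c(0, cumsum(1 - y)[keep] / n_neg)
    roc <- data.frame(fpr = fpr, tpr = tpr)
    auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  }
  structure(list(accuracy = acc, sensitivity = sens, specificity = spec,
                 roc_points = roc, auc = auc, threshold = threshold,
                 n = length(labels)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report (n = %d, threshold = %.2f)\n", x$n, x$threshold))
  cat(sprintf("  accuracy:    %.4f\n  sensitivity: %.4f\n", x$accuracy, x$sensitivity))
  cat(sprintf("  specificity: %.4f\n  AUC:         %s\n", x$specificity,
              if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc)))
  invisible(x)
}

#' Per-lesion-type accuracy breakdown
#'
#' Splits the abnormal cases by lesion type (mass vs calcification) and
#' reports the proportion classified correctly within each subset. Abnormal
#' cases without a recorded lesion type are excluded with a warning.
#'
#' @param cases list of [case_pair()].
#' @param correct logical vector, one entry per case: was the case's
#'   prediction correct for the task under evaluation.
#' @return named numeric vector `c(mass = ..., calcification = ...)`;
#'   a type with no cases reports `NaN`.
#' @export
per_lesion_breakdown <- function(cases, correct) {
  stopifnot(length(cases) == length(correct))
  abn <- vapply(cases, function(cs) cs$label != "normal", TRUE)
  type <- vapply(cases, function(cs)
    if (is.null(cs$lesion_type)) NA_character_ else cs$lesion_type, "")
  missing <- abn & is.na(type)
  if (any(missing))
    warning(sprintf("%d abnormal case(s) without lesion_type excluded from breakdown",
                    sum(missing)))
  out <- vapply(LESION_TYPES, function(lt) {
    sel <- abn & !is.na(type) & type == lt
    mean(correct[sel])
  }, 1)
  names(out) <- LESION_TYPES
  out
}

#' Mean metrics over a fold plan
#'
#' Convenience aggregator: computes [compute_metrics()] within each fold and
#' returns per-fold reports plus the mean of accuracy, sensitivity and AUC
#' over folds.
#'
#' @param plan [make_folds()] result.
#' @param labels,scores as in [compute_metrics()].
#' @param threshold decision threshold.
#' @return list with `per_fold` (list of eval_reports) and `mean` (named
#'   numeric vector).
#' @export
crossval_metrics <- function(plan, labels, scores, threshold = 0.5) {
  stopifnot(inherits(plan, "fold_plan"))
  reports <- lapply(seq_len(plan$k), function(f) {
    sel <- plan$fold == f
    compute_metrics(labels[sel], scores[sel], threshold)
  })
  m <- c(accuracy = mean(vapply(reports, `[[`, 1, "accuracy")),
         sensitivity = mean(vapply(reports, `[[`, 1, "sensitivity")),
         auc = mean(vapply(reports, `[[`, 1, "auc")))
  list(per_fold = reports, mean = m)
}
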