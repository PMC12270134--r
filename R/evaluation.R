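#' Confusion matrix for binary labels
#'
#' Counts with the internal +1 class (the minority / metastatic designation)
#' as positive.
#'
#' @param y_true,y_pred equal-length label vectors in -1/+1 (0/1 accepted).
#' @param positive which internal label counts as positive (default +1);
#'   swapping it exchanges TP with TN and FP with FN.
#' @return object of class `confusion_matrix` with counts `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion <- function(y_true, y_pred, positive = 1L) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  yt <- canonicalize_labels(y_true)$labels
  yp <- canonicalize_labels(y_pred)$labels
  pos <- as.integer(positive)
  structure(list(TP = sum(yt == pos & yp == pos),
                 TN = sum(yt != pos & yp != pos),
                 FP = sum(yt != pos & yp == pos),
                 FN = sum(yt == pos & yp != pos)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP %d  FN %d\n                   FP %d  TN %d\n",
              x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

#' The ten confusion-matrix performance metrics
#'
#' Sensitivity/recall (TPR), specificity (SPC), precision (PPV), negative
#' predictive value (NPV), false positive rate (FPR), false discovery rate
#' (FDR), false negative rate (FNR), accuracy (ACC), F1 score and Matthews
#' correlation coefficient (MCC). Lower is better for FPR, FDR and FNR;
#' higher for the rest. Any metric with a zero denominator is set to 0 and
#' recorded in `undefined` rather than propagating NaN.
#'
#' @param cm a [confusion()] matrix (or list with TP/TN/FP/FN).
#' @return object of class `metrics_report`: the ten named scalars plus
#'   `undefined` (character vector of flagged metrics).
#' @examples
#' cm <- list(TP = 19, FN = 11, TN = 102, FP = 36)
#' round(compute_metrics(cm)$F1, 3)  # 0.447
#' @export
compute_metrics <- function(cm) {
  TP <- cm$TP; TN <- cm$TN; FP <- cm$FP; FN <- cm$FN
  if (TP + TN + FP + FN < 1) stop("empty confusion matrix", call. = FALSE)
  undefined <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      return(0)
    }
    num / den
  }
  mcc_den2 <- prod(c(TP + FP, TP + FN, TN + FP, TN + FN))
  out <- list(
    TPR = safe(TP, TP + FN, "TPR"),
    SPC = safe(TN, FP + TN, "SPC"),
    PPV = safe(TP, TP + FP, "PPV"),
    NPV = safe(TN, TN + FN, "NPV"),
    FPR = safe(FP, FP + TN, "FPR"),
    FDR = safe(FP, FP + TP, "FDR"),
    FNR = safe(FN, FN + TP, "FNR"),
    ACC = (TP + TN) / (TN + FP + FN + TP),
    F1 = safe(2 * TP, 2 * TP + FP + FN, "F1"),
    MCC = if (mcc_den2 == 0) { undefined <- c(undefined, "MCC"); 0 }
          else (TP * TN - FP * FN) / sqrt(mcc_den2))
  structure(c(out, list(undefined = undefined)), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  v <- unlist(x[metric_names()])
  cat("<metrics_report>\n")
  print(round(v, digits))
  if (length(x$undefined))
    cat("flagged undefined (reported as 0):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

metric_names <- function() {
  c("TPR", "SPC", "PPV", "NPV", "FPR", "FDR", "FNR", "ACC", "F1", "MCC")
}

## metrics where a lower value wins the comparison
lower_is_better <- function() c("FPR", "FDR", "FNR")

#' Comparative scoring of two metric reports
#'
#' Awards one point per metric to the strictly better side: higher wins for
#' TPR, SPC, PPV, NPV, ACC, F1 and MCC; lower wins for FPR, FDR and FNR.
#' Values are rounded to `digits` decimals first (matching published
#' reporting precision), so equality at that precision counts as a tie.
#'
#' @param report_a,report_b [compute_metrics()] reports (or named lists
#'   containing the ten metrics).
#' @param digits rounding applied before comparison (default 3).
#' @return object of class `comparative_score`: `wins_a`, `wins_b`, `ties`
#'   (always summing to 10), and per-metric outcomes.
#' @export
comparative_score <- function(report_a, report_b, digits = 3) {
  nm <- metric_names()
  a <- round(unlist(report_a[nm]), digits)
  b <- round(unlist(report_b[nm]), digits)
  flip <- nm %in% lower_is_better()
  a_better <- ifelse(flip, a < b, a > b)
  b_better <- ifelse(flip, a > b, a < b)
  outcome <- ifelse(a_better, "a", ifelse(b_better, "b", "tie"))
  structure(list(wins_a = sum(a_better), wins_b = sum(b_better),
                 ties = sum(!a_better & !b_better),
                 outcome = stats::setNames(outcome, nm)),
            class = "comparative_score")
}

#' @export
print.comparative_score <- function(x, ...) {
  cat(sprintf("<comparative_score> a: %d, b: %d, ties: %d\n",
              x$wins_a, x$wins_b, x$ties))
  invisible(x)
}

#' Cross-validated metric report
#'
#' Stratified k-fold cross-validation of an arbitrary classifier: each fold
#' is held out once, the classifier is fitted on the remainder, and the ten
#' metrics are computed on the held-out predictions. Reports per-fold
#' metrics plus mean and population standard deviation (divide by the fold
#' count) per metric.
#'
#' @param ds a [labeled_dataset()].
#' @param fit_fun `function(train_ds)` returning a fitted model.
#' @param predict_fun `function(model, train_ds, test_ds)` returning -1/+1
#'   labels.
#' @param folds number of folds (default 5); every class must have at least
#'   `folds` samples.
#' @param seed integer seed for fold assignment.
#' @return object of class `cv_report`: `per_fold` (list of metric reports),
#'   `mean`, `sd` (named numeric vectors over the ten metrics), `folds`.
#' @export
crossval_report <- function(ds, fit_fun, predict_fun, folds = 5, seed = NULL) {
  stopifnot(inherits(ds, "labeled_dataset"))
  folds <- stop_if_not_count(folds, "folds", min = 2L)
  fold_id <- stratified_folds(ds$labels, folds, seed)
  per_fold <- lapply(seq_len(folds), function(fd) {
    tr <- subset_dataset(ds, which(fold_id != fd))
    va <- subset_dataset(ds, which(fold_id == fd))
    model <- fit_fun(tr)
    compute_metrics(confusion(va$labels, predict_fun(model, tr, va)))
  })
  nm <- metric_names()
  vals <- vapply(per_fold, function(r) unlist(r[nm]), numeric(length(nm)))
  mu <- rowMeans(vals)
  sdv <- sqrt(rowMeans(sweep(vals, 1L, mu)^2))     # population form
  structure(list(per_fold = per_fold, mean = mu, sd = sdv,
                 folds = folds, fold_id = fold_id),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, digits = 3, ...) {
  cat(sprintf("<cv_report> %d folds (mean +/- population sd)\n", x$folds))
  tab <- sprintf("%s %.*f +/- %.*f", format(names(x$mean), width = 4),
                 digits, x$mean, digits, x$sd)
  cat(paste0("  ", tab, collapse = "\n"), "\n")
  invisible(x)
}

#' Render two metric reports as an aligned comparison table
#'
#' Markdown layout mirroring published side-by-side metric tables, with the
#' comparative score as the last row.
#' @param report_a,report_b metric reports.
#' @param names_ab column names for the two classifiers.
#' @param digits rounding for display and tie detection.
#' @return character vector of markdown lines.
#' @export
format_comparison_table <- function(report_a, report_b,
                                    names_ab = c("A", "B"), digits = 3) {
  nm <- metric_names()
  cs <- comparative_score(report_a, report_b, digits = digits)
  rows <- vapply(nm, function(m) {
    sprintf("| %s | %.3f | %.3f |", m, report_a[[m]], report_b[[m]])
  }, character(1))
  c(sprintf("| Metric | %s | %s |", names_ab[1], names_ab[2]),
    "| --- | --- | --- |",
    rows,
    sprintf("| Comparative score | %d%s | %d%s |",
            cs$wins_a, if (cs$ties) sprintf(" + %d tie", cs$ties) else "",
            cs$wins_b, if (cs$ties) sprintf(" + %d tie", cs$ties) else ""))
}

#' Bar chart of two metric reports side by side
#' @inheritParams format_comparison_table
#' @param ... passed to [graphics::barplot()].
#' @export
plot_metric_comparison <- function(report_a, report_b, names_ab = c("A", "B"), ...) {
  nm <- metric_names()
  m <- rbind(unlist(report_a[nm]), unlist(report_b[nm]))
  graphics::barplot(m, beside = TRUE, names.arg = nm, las = 2,
                    legend.text = names_ab, ylim = c(0, 1), ...)
  invisible(NULL)
}
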