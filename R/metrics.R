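#' Fuse the two classifier score sets by averaging
#'
#' The hybrid detector averages the per-class probabilities of the
#' improved LinkNet (`ILn^o`) and GhostNet (`Gn^o`) branches; the argmax
#' of the fused scores is the predicted label.
#'
#' @param iln,gnet score matrices (classes x samples) with identical
#'   class ordering (row names, when present, must match).
#' @return fused score matrix of the same shape.
#' @export
fuse_scores <- function(iln, gnet) {
  if (!identical(dim(iln), dim(gnet)))
    stop("score sets have different shapes")
  if (!is.null(rownames(iln)) && !is.null(rownames(gnet)) &&
      !identical(rownames(iln), rownames(gnet)))
    stop("score sets have mismatched class sets: ",
         paste(rownames(iln), collapse = "/"), " vs ",
         paste(rownames(gnet), collapse = "/"))
  (iln + gnet) / 2
}

#' Confusion matrix with patient as the positive class
#'
#' @param predictions,labels character vectors over
#'   `c("healthy", "patient")`, equal length.
#' @return list of class `pd_confusion` with counts `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels))
  bad <- setdiff(unique(c(predictions, labels)), LABELS)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  structure(list(
    tp = sum(predictions == "patient" & labels == "patient"),
    fp = sum(predictions == "patient" & labels == "healthy"),
    fn = sum(predictions == "healthy" & labels == "patient"),
    tn = sum(predictions == "healthy" & labels == "healthy")),
    class = "pd_confusion")
}

#' Confusion matrix from explicit counts
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @return a `pd_confusion`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn), class = "pd_confusion")
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Classification metrics of a confusion matrix
#'
#' Accuracy, sensitivity (recall of the patient class), specificity,
#' precision, F-measure, Matthews correlation coefficient, negative
#' predictive value, and the complementary error rates FPR, FNR, FDR. A
#' metric with an empty margin is reported as `NA` (the undefined
#' sentinel, serialised as `null`), never silently zero. The complement
#' identities `sensitivity + fnr = specificity + fpr = precision + fdr
#' = 1` hold exactly whenever both sides are defined.
#'
#' @param cm a `pd_confusion`.
#' @return list of class `pd_metrics`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "pd_confusion"))
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  total <- tp + fp + fn + tn
  if (total == 0) stop("empty confusion matrix")
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  npv <- safe_div(tn, tn + fn)
  f <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
       else 2 * prec * sens / (prec + sens)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  structure(list(
    accuracy = (tp + tn) / total,
    sensitivity = sens, specificity = spec, precision = prec,
    f_measure = f, mcc = mcc, npv = npv,
    fpr = if (is.na(spec)) NA_real_ else 1 - spec,
    fnr = if (is.na(sens)) NA_real_ else 1 - sens,
    fdr = if (is.na(prec)) NA_real_ else 1 - prec),
    class = "pd_metrics")
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique patient-class scores (plus sentinels
#' closing both endpoints); AUC by the trapezoidal rule.
#'
#' @param scores numeric patient-class probabilities.
#' @param labels character labels over `c("healthy", "patient")`; both
#'   classes must be present.
#' @return list of class `pd_roc` with `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == "patient"
  if (!any(pos) || all(pos))
    stop("ROC needs at least one sample of each class")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # cumulative counts at each distinct threshold (predict positive if
  # score >= threshold)
  keep <- c(diff(s) != 0, TRUE)
  tpr <- c(0, cumsum(p)[keep] / sum(pos))
  fpr <- c(0, cumsum(!p)[keep] / sum(!pos))
  thresholds <- c(Inf, s[keep])
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = auc),
            class = "pd_roc")
}
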