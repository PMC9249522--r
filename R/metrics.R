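#' Segmentation overlap metrics
#'
#' Area overlap (AOM, the Jaccard index), over-segmentation (AVM:
#' segmented area outside the gold standard, relative to the segmentation)
#' and under-segmentation (AUM: gold-standard area missed, relative to the
#' gold standard), plus the composite measure
#' `CM = (AOM + (1 - AVM) + (1 - AUM)) / 3`.
#'
#' An empty segmentation against a nonempty gold standard is reported with
#' the documented convention `AOM = 0, AVM = 1, AUM = 1`.
#'
#' @param Rs binary segmentation mask (matrix or array).
#' @param Rg binary gold-standard mask, same shape, nonempty.
#' @return List with `AOM`, `AVM`, `AUM`, `CM` in `[0, 1]`.
#' @export
segmentation_metrics <- function(Rs, Rg) {
  Rs <- Rs > 0; Rg <- Rg > 0
  if (!identical(dim(Rs), dim(Rg))) stop("mask shapes differ")
  if (!any(Rg)) stop("gold-standard mask is empty")
  if (!any(Rs))
    return(list(AOM = 0, AVM = 1, AUM = 1, CM = composite_measure(0, 1, 1)))
  inter <- sum(Rs & Rg); uni <- sum(Rs | Rg)
  aom <- inter / uni
  avm <- sum(Rs & !Rg) / sum(Rs)
  aum <- sum(Rg & !Rs) / sum(Rg)
  list(AOM = aom, AVM = avm, AUM = aum, CM = composite_measure(aom, avm, aum))
}

#' Composite segmentation measure
#'
#' `CM = (AOM + (1 - AVM) + (1 - AUM)) / 3`: one number that rewards
#' overlap and punishes both over- and under-segmentation equally.
#'
#' @param AOM,AVM,AUM overlap, over-, and under-segmentation ratios.
#' @return The composite measure.
#' @export
composite_measure <- function(AOM, AVM, AUM) {
  (AOM + (1 - AVM) + (1 - AUM)) / 3
}

#' Detection rate
#'
#' Fraction `F = A / B` of spiculated nodules whose spiculation was
#' detected, out of all spiculated nodules presented.
#'
#' @param detected count of detected cases (`0 <= detected <= total`).
#' @param total total case count (> 0).
#' @return The rate in `[0, 1]`.
#' @export
detection_rate <- function(detected, total) {
  if (total <= 0) stop("total must be > 0")
  if (detected < 0 || detected > total)
    stop("detected must lie in [0, total]")
  detected / total
}

#' Binary classification metrics from confusion counts
#'
#' Sensitivity `SEN = TP/(TP+FN)`, specificity `SPE = TN/(TN+FP)`,
#' accuracy `ACC = (TP+TN)/(TP+FP+TN+FN)`, and the false-positive fraction
#' `FPF = 1 - ACC`. A metric whose denominator is zero is reported as `NA`
#' while the others are still computed.
#'
#' @param TP,FP,FN,TN non-negative counts (or a single list with those
#'   names as first argument).
#' @param percent report on the 0-100 scale instead of 0-1.
#' @return List with `SEN`, `SPE`, `ACC`, `FPF`.
#' @export
classification_metrics <- function(TP, FP = NULL, FN = NULL, TN = NULL,
                                   percent = FALSE) {
  if (is.list(TP)) { c_ <- TP; TP <- c_$TP; FP <- c_$FP; FN <- c_$FN; TN <- c_$TN }
  counts <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  if (sum(counts) == 0) stop("at least one count must be positive")
  sen <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spe <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  acc <- (TP + TN) / sum(counts)
  fpf <- 1 - acc
  s <- if (percent) 100 else 1
  list(SEN = sen * s, SPE = spe * s, ACC = acc * s, FPF = fpf * s)
}

#' ROC points and area under the curve
#'
#' Standard threshold sweep over the unique scores (each threshold `t`
#' predicts positive where `score >= t`), with `(0,0)` and `(1,1)`
#' included; AUC by the trapezoid rule. AUC is invariant to strictly
#' monotone transforms of the scores.
#'
#' @param scores per-sample scores, larger = more positive.
#' @param labels binary labels (logical, 0/1, or the package's two class
#'   names with `"spiculated"` positive).
#' @return List with `points` (data frame `FPR`, `TPR` ordered by FPR) and
#'   `auc`.
#' @export
roc_points <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.character(labels) == "spiculated"
  labels <- labels > 0
  if (length(scores) != length(labels)) stop("length mismatch")
  if (!any(labels) || all(labels)) stop("both classes must be present")
  np <- sum(labels); nn <- sum(!labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / np, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / nn, 0)
  fpr <- c(0, fpr, 1); tpr <- c(0, tpr, 1)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(FPR = fpr, TPR = tpr), auc = auc)
}
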