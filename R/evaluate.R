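## Detection-performance evaluation on labelled cohorts: confusion
## matrix, sensitivity/specificity, ROC threshold sweep with trapezoidal
## AUC and the exact pairwise-concordance AUC.

#' Detection scores for every image of a cohort
#'
#' @param cohort a cohort list as returned by \code{\link{generateCohort}}
#'   (elements \code{images} and \code{labels}).
#' @param calibration a \linkS4class{Calibration}.
#' @param ... forwarded to \code{\link{detectNodule}}.
#' @return data.frame with columns \code{label} and \code{score} (kPa).
#' @export
cohortScores <- function(cohort, calibration, ...) {
  scores <- vapply(cohort$images, function(im)
    detectionScore(detectNodule(im, calibration, ...)), numeric(1))
  data.frame(label = as.integer(cohort$labels), score = scores)
}

#' Confusion matrix and rates from scores
#'
#' Positive call iff score strictly exceeds the threshold (ties score
#' negative, matching \code{\link{detectNodule}}). Rates are formed in
#' exact integer arithmetic before formatting; a single-class cohort
#' reports the undefined rate as NA, never 0.
#'
#' @param scores numeric detection scores.
#' @param labels 0/1 ground-truth labels.
#' @param threshold decision threshold (same units as the scores).
#' @return list with \code{tp}, \code{fp}, \code{tn}, \code{fn},
#'   \code{sensitivity}, \code{specificity} (proportions, NA when
#'   undefined).
#' @export
confusionFromScores <- function(scores, labels, threshold) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  pred <- scores > threshold
  tp <- sum(pred & labels == 1); fn <- sum(!pred & labels == 1)
  fp <- sum(pred & labels == 0); tn <- sum(!pred & labels == 0)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Score a cohort at a fixed operating point
#'
#' Runs \code{\link{detectNodule}} on every image and tabulates the
#' confusion matrix, sensitivity and specificity at the given threshold.
#'
#' @param cohort cohort list (see \code{\link{generateCohort}}).
#' @param calibration a \linkS4class{Calibration}.
#' @param decisionThreshold threshold in kPa (default 55).
#' @param ... forwarded to \code{\link{detectNodule}}.
#' @return list: \code{confusion} (tp/fp/tn/fn), \code{sensitivity},
#'   \code{specificity}, \code{scores} (data.frame label, score).
#' @export
scoreCohort <- function(cohort, calibration, decisionThreshold = 55, ...) {
  if (!length(cohort$images)) stop("cohort is empty")
  sc <- cohortScores(cohort, calibration,
                     decisionThreshold = decisionThreshold, ...)
  cm <- confusionFromScores(sc$score, sc$label, decisionThreshold)
  list(confusion = cm[c("tp", "fp", "tn", "fn")],
       sensitivity = cm$sensitivity, specificity = cm$specificity,
       scores = sc)
}

#' Exact concordance (Mann-Whitney) AUC
#'
#' Fraction of positive-negative pairs in which the positive scores
#' higher, ties counting one half.
#'
#' @param scores numeric detection scores.
#' @param labels 0/1 labels (both classes must be present).
#' @return AUC in [0, 1].
#' @export
concordanceAuc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg))
    stop("concordance AUC needs both classes")
  cmp <- outer(pos, neg, `-`)
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(pos) * length(neg))
}

#' ROC curve by threshold sweep
#'
#' Sweeps the decision threshold uniformly over the observed score range,
#' records (FPR, TPR) at each threshold (strict > rule), always includes
#' the (0,0) and (1,1) endpoints, and integrates the trapezoidal AUC.
#' The exact pairwise-concordance AUC is reported alongside.
#'
#' @param cohort cohort list, or NULL when \code{scores}/\code{labels}
#'   are given directly.
#' @param calibration a \linkS4class{Calibration} (used only with a
#'   cohort).
#' @param nThresholds number of swept thresholds (>= 2, default 101).
#' @param scores,labels optional precomputed scores and 0/1 labels.
#' @param ... forwarded to \code{\link{detectNodule}}.
#' @return list with \code{curve} (data.frame threshold, fpr, tpr),
#'   \code{auc} (trapezoid), \code{aucConcordance}.
#' @export
rocSweep <- function(cohort = NULL, calibration = NULL, nThresholds = 101,
                     scores = NULL, labels = NULL, ...) {
  if (nThresholds < 2) stop("nThresholds must be >= 2")
  if (is.null(scores)) {
    sc <- cohortScores(cohort, calibration, ...)
    scores <- sc$score; labels <- sc$label
  }
  if (!any(labels == 1) || !any(labels == 0))
    stop("ROC sweep needs both classes present")
  rng <- range(scores)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  thr <- seq(rng[2], rng[1], length.out = nThresholds)
  tpr <- vapply(thr, function(t) mean(scores[labels == 1] > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[labels == 0] > t), numeric(1))
  curve <- data.frame(threshold = c(Inf, thr, -Inf),
                      fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  curve <- curve[order(curve$fpr, curve$tpr), ]
  auc <- sum(diff(curve$fpr) * (curve$tpr[-1] + curve$tpr[-nrow(curve)]) / 2)
  list(curve = curve, auc = auc,
       aucConcordance = concordanceAuc(scores, labels))
}
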