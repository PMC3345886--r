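#' Confusion matrix of a score surface against observations
#'
#' Cells are classified present where `score >= threshold` (ties at the
#' threshold classify as present). Only cells that are unmasked, surveyed
#' and have a non-missing score are tallied.
#'
#' @param scores Numeric per-cell scores (favourability or probability),
#'   or a `fav_surface`.
#' @param det A [detection_grid()].
#' @param threshold Finite classification threshold.
#' @param score_kind `"favourability"` or `"probability"` (metadata only).
#' @return Object of class `confusion_matrix` with counts `TP`, `FP`,
#'   `TN`, `FN`, the `threshold`, and `score_kind`.
#' @examples
#' d <- detection_grid(c(1, 1, 1, 0, 0, 0))
#' confusion_matrix(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2), d, 0.5)
#' @export
confusion_matrix <- function(scores, det, threshold = 0.5,
                             score_kind = "favourability") {
  if (inherits(scores, "fav_surface")) scores <- scores$F
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  if (length(scores) != length(det$outcomes)) {
    stop("scores and detections differ in cell count", call. = FALSE)
  }
  keep <- !is.na(scores) & !is.na(det$outcomes)
  if (!any(keep)) stop("no evaluable cells", call. = FALSE)
  y <- det$outcomes[keep]
  pred <- scores[keep] >= threshold
  structure(
    list(TP = sum(pred & y == 1L), FP = sum(pred & y == 0L),
         TN = sum(!pred & y == 0L), FN = sum(!pred & y == 1L),
         threshold = threshold, score_kind = score_kind),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> threshold %.4g on %s scores\n",
              x$threshold, x$score_kind))
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(c("pred present", "pred absent"),
                              c("obs present", "obs absent")))
  print(m)
  invisible(x)
}

#' Threshold-dependent discrimination indices
#'
#' Computes the classification indices of the favourability-modelling
#' evaluation suite: sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' percent correctly classified `PCC = (TP+TN)/n` (also called overall
#' accuracy), positive and negative predictive power `PPP = TP/(TP+FP)`
#' and `NPP = TN/(TN+FN)`, true skill statistic
#' `TSS = sensitivity + specificity - 1`, and Cohen's Kappa. An index
#' whose denominator is zero is reported as `NA` (undefined), never
#' silently as 0.
#'
#' @param cm A [confusion_matrix()].
#' @return Named list with `sensitivity`, `specificity`, `pcc`, `ppp`,
#'   `npp`, `tss`, `kappa`.
#' @examples
#' cm <- structure(list(TP = 40, FN = 10, TN = 30, FP = 20,
#'                      threshold = 0.5, score_kind = "favourability"),
#'                 class = "confusion_matrix")
#' threshold_indices(cm)
#' @export
threshold_indices <- function(cm) {
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  n <- cm$TP + cm$FP + cm$TN + cm$FN
  sens <- safe_div(cm$TP, cm$TP + cm$FN)
  spec <- safe_div(cm$TN, cm$TN + cm$FP)
  pe <- safe_div((cm$TP + cm$FP) * (cm$TP + cm$FN) +
                 (cm$TN + cm$FN) * (cm$TN + cm$FP), n^2)
  po <- safe_div(cm$TP + cm$TN, n)
  kappa <- if (is.na(pe) || pe == 1) NA_real_ else (po - pe) / (1 - pe)
  list(
    sensitivity = sens,
    specificity = spec,
    pcc = po,
    ppp = safe_div(cm$TP, cm$TP + cm$FP),
    npp = safe_div(cm$TN, cm$TN + cm$FN),
    tss = sens + spec - 1,
    kappa = kappa
  )
}

#' Area under the ROC curve
#'
#' Threshold-independent discrimination: the probability that a randomly
#' chosen presence cell scores higher than a randomly chosen absence cell,
#' ties counting one half. Computed via the rank-sum (Mann-Whitney)
#' statistic with midranks, which handles ties exactly:
#' `AUC = (sum of presence ranks - n1(n1+1)/2) / (n1 n0)`.
#'
#' @param scores Numeric per-cell scores or a `fav_surface`.
#' @param det A [detection_grid()].
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, det) {
  if (inherits(scores, "fav_surface")) scores <- scores$F
  keep <- !is.na(scores) & !is.na(det$outcomes)
  y <- det$outcomes[keep]
  s <- scores[keep]
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 < 1L || n0 < 1L) {
    stop("AUC needs at least one presence and one absence", call. = FALSE)
  }
  r <- rank(s)  # midranks
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Resolve a threshold policy to a numeric threshold
#'
#' @param scores Per-cell scores (already on the scale to be thresholded).
#' @param det A [detection_grid()].
#' @param policy Either a single number (fixed threshold), `"default"`
#'   (0.5 — on the favourability scale this classifies present exactly
#'   where `P` exceeds the training prevalence), `"prevalence"` (the
#'   observed prevalence of `det`), or `"maxTSS"` (the observed score that
#'   maximizes TSS; the smallest such score on ties).
#' @return A single numeric threshold.
#' @export
resolve_threshold <- function(scores, det, policy = "default") {
  if (is.numeric(policy)) return(policy[1])
  switch(policy,
    default = 0.5,
    prevalence = det$n1 / (det$n1 + det$n0),
    maxTSS = {
      keep <- !is.na(scores) & !is.na(det$outcomes)
      cand <- sort(unique(scores[keep]))
      tss <- vapply(cand, function(th) {
        threshold_indices(confusion_matrix(scores, det, th))$tss
      }, numeric(1))
      cand[which.max(tss)]
    },
    stop("unknown threshold policy: ", policy, call. = FALSE)
  )
}

#' Full discrimination report for a model on observed data
#'
#' Builds the favourability surface of `coefs` on `grid`, resolves the
#' threshold policy, and returns the confusion matrix together with the
#' seven threshold-dependent indices and AUC.
#'
#' @param coefs A [coefficient_set()].
#' @param grid An [env_grid()].
#' @param det A [detection_grid()].
#' @param threshold_policy See [resolve_threshold()].
#' @param prevalence_source Passed to [favourability_surface()].
#' @return Object of class `performance_report`.
#' @export
evaluate_model <- function(coefs, grid, det, threshold_policy = "default",
                           prevalence_source = "training") {
  surf <- favourability_surface(coefs, grid, prevalence_source)
  th <- resolve_threshold(surf$F, det, threshold_policy)
  cm <- confusion_matrix(surf$F, det, th)
  performance_report(cm, auc = auc(surf$F, det),
                     model_label = coefs$label)
}

#' Assemble a performance report from a confusion matrix and AUC
#'
#' @param cm A [confusion_matrix()].
#' @param auc AUC value (may be `NA` if not computed).
#' @param model_label Model label carried through to outputs.
#' @return Object of class `performance_report`: the indices of
#'   [threshold_indices()], `auc`, `confusion`, `model_label`.
#' @export
performance_report <- function(cm, auc = NA_real_, model_label = "") {
  idx <- threshold_indices(cm)
  structure(c(idx, list(auc = auc, confusion = cm,
                        model_label = model_label)),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("<performance_report> %s (threshold %.4g)\n",
              if (nzchar(x$model_label)) x$model_label else "(unlabelled)",
              x$confusion$threshold))
  v <- unlist(x[c("sensitivity", "specificity", "pcc", "ppp", "npp",
                  "tss", "kappa", "auc")])
  print(round(v, 4))
  invisible(x)
}

#' @export
as.data.frame.performance_report <- function(x, ...) {
  data.frame(model = x$model_label,
             threshold = x$confusion$threshold,
             TP = x$confusion$TP, FP = x$confusion$FP,
             TN = x$confusion$TN, FN = x$confusion$FN,
             sensitivity = x$sensitivity, specificity = x$specificity,
             pcc = x$pcc, ppp = x$ppp, npp = x$npp, tss = x$tss,
             kappa = x$kappa, auc = x$auc)
}
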