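# Inter-hemispheric asymmetry biomarker: asymmetry index, normative
# limits from healthy controls, 2/3-SD classification and discrimination
# metrics. AI is computed on uncorrected measures, the contralateral side
# being each scan's internal reference.

#' Asymmetry index between left and right measures
#'
#' `AI = (lh - rh) / (lh + rh)`: zero for perfect symmetry, bounded in
#' \[-1, +1\], scale invariant, and antisymmetric under swapping sides.
#'
#' @param lh,rh non-negative measures (vectorized); `lh + rh` must be
#'   positive.
#' @return Numeric vector of asymmetry indices.
#' @examples
#' asymmetryIndex(3000, 3500)  # -0.076923
#' @export
asymmetryIndex <- function(lh, rh) {
  if (any(lh < 0) || any(rh < 0)) stop("measures must be non-negative")
  if (any(lh + rh <= 0)) stop("lh + rh must be positive")
  (lh - rh) / (lh + rh)
}

#' Normative asymmetry limits from healthy-control AI values
#'
#' Mean and sample SD (n - 1 denominator) over all HC scans, with
#' two-sided decision limits at mean +/- 2 SD and +/- 3 SD. Limits are
#' centred on the HC mean rather than zero because healthy controls show
#' a small negative mean volume AI (slightly larger right hippocampus).
#'
#' @param hc_ai numeric vector of HC asymmetry indices (>= 10 values).
#' @param metric measure name the AI refers to, `"volume"` or
#'   `"surface_to_volume_ratio"`.
#' @return An [AsymmetryLimits-class].
#' @export
fitNormativeLimits <- function(hc_ai, metric = "volume") {
  hc_ai <- hc_ai[is.finite(hc_ai)]
  if (length(hc_ai) < 10L) stop("need at least 10 HC AI values")
  m <- mean(hc_ai)
  s <- sd(hc_ai)
  if (s <= 0) stop("zero spread in HC AI values")
  new("AsymmetryLimits", metric = metric, hc_mean_ai = m, hc_sd_ai = s,
      n_hc = length(hc_ai),
      thresholds = list("2SD" = c(m - 2 * s, m + 2 * s),
                        "3SD" = c(m - 3 * s, m + 3 * s)))
}

# direction an *increase* of the left-side measure moves the AI is always
# positive; what differs per metric is which direction disease pushes it:
# volume drops with HS (AI below lower limit => left-abnormal) while the
# surface-to-volume ratio increases (AI above upper limit => left-abnormal)
.metric_conventions <- c(volume = "loss", surface_to_volume_ratio = "gain")

#' Classify scans by asymmetry against normative limits
#'
#' AI values inside the limits are `within-norm`; outside, the abnormal
#' side follows the metric's disease direction: for volume (which HS
#' decreases) AI below the lower limit flags the left side; for the
#' surface-to-volume ratio (which HS increases) AI above the upper limit
#' flags the left side.
#'
#' @param ai numeric vector of asymmetry indices.
#' @param limits an [AsymmetryLimits-class].
#' @param level `"3SD"` (default) or `"2SD"`.
#' @param convention override the metric convention: `"loss"` (disease
#'   lowers the measure) or `"gain"`; defaults to the convention registered
#'   for `limits@metric`.
#' @return Factor with levels `within-norm`, `left-abnormal`,
#'   `right-abnormal`.
#' @export
classifyByAsymmetry <- function(ai, limits, level = c("3SD", "2SD"),
                                convention = NULL) {
  stopifnot(is(limits, "AsymmetryLimits"))
  level <- match.arg(level)
  if (is.null(convention)) {
    if (!limits@metric %in% names(.metric_conventions))
      stop("unknown metric convention for '", limits@metric,
           "'; pass convention = \"loss\" or \"gain\"")
    convention <- .metric_conventions[[limits@metric]]
  }
  convention <- match.arg(convention, c("loss", "gain"))
  th <- limits@thresholds[[level]]
  lab <- rep("within-norm", length(ai))
  low <- ai < th[1]
  high <- ai > th[2]
  if (convention == "loss") {
    lab[low] <- "left-abnormal"
    lab[high] <- "right-abnormal"
  } else {
    lab[high] <- "left-abnormal"
    lab[low] <- "right-abnormal"
  }
  factor(lab, levels = c("within-norm", "left-abnormal", "right-abnormal"))
}

#' Sensitivity, specificity and F1 for unilateral HS detection
#'
#' Evaluates predictions on the unilateral-HS vs all-other-epilepsies
#' contrast only: rows with group `HC` or `HS-bilateral` are dropped.
#' Positive class = unilateral HS; predicted positive = any abnormal
#' label. With no positive predictions F1 is defined as 0.
#'
#' @param predictions factor from [classifyByAsymmetry()].
#' @param groups group labels aligned with `predictions`.
#' @return List with `sensitivity`, `specificity`, `f1`, and the confusion
#'   counts `tp`, `fp`, `tn`, `fn`.
#' @export
binaryMetrics <- function(predictions, groups) {
  keep <- groups %in% c("HS-left", "HS-right", "EPI-other")
  predictions <- predictions[keep]
  groups <- groups[keep]
  truth_pos <- groups %in% c("HS-left", "HS-right")
  if (!any(truth_pos) || all(truth_pos))
    stop("need both unilateral HS and all-other-epilepsies scans")
  pred_pos <- predictions != "within-norm"
  tp <- sum(pred_pos & truth_pos)
  fp <- sum(pred_pos & !truth_pos)
  fn <- sum(!pred_pos & truth_pos)
  tn <- sum(!pred_pos & !truth_pos)
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Rank-based ROC AUC (Mann-Whitney)
#'
#' AUC equals the Mann-Whitney U statistic normalized by `n_pos * n_neg`,
#' with ties counted 0.5; computed from midranks, so it is invariant under
#' strictly monotone transforms of the scores.
#'
#' @param scores numeric scores (here typically the absolute AI).
#' @param labels logical or coercible: `TRUE` for the positive class (HS).
#' @return AUC in \[0, 1\].
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("scores/labels must be complete")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("need both classes to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' Empirical ROC curve over all distinct score thresholds (predict
#' positive when `score >= threshold`).
#'
#' @inheritParams rocAuc
#' @return data.frame with `threshold`, `fpr`, `tpr`, from (1,1) to (0,0).
#' @export
rocCurve <- function(scores, labels) {
  labels <- as.logical(labels)
  th <- c(-Inf, sort(unique(scores)), Inf)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("need both classes")
  out <- lapply(th, function(t) {
    pred <- scores >= t
    data.frame(threshold = t,
               fpr = sum(pred & !labels) / n_neg,
               tpr = sum(pred & labels) / n_pos)
  })
  do.call(rbind, out)
}
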