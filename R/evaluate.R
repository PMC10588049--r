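#' FDR / power evaluation against simulation truth
#'
#' Calls are compared against known true differences using
#' `FDR = FP / (TP + FP)` and `power = TP / (TP + FN)`; the FDR is defined
#' as 0 when no calls are made.
#'
#' @name evaluate
NULL

#' Confusion counts at one threshold
#'
#' @param truth Logical (or 0/1) vector: which tests are true differences.
#' @param scores Numeric scores, same length.
#' @param threshold Calling threshold.
#' @param direction `"le"`: call when `score <= threshold` (p-values,
#'   s-values, lfsr); `"ge"`: call when `score >= threshold` (divergence or
#'   magnitude scores).
#' @return Named numeric vector `(tp, fp, tn, fn)`.
#' @export
confusion_at <- function(truth, scores, threshold,
                         direction = c("le", "ge")) {
  direction <- match.arg(direction)
  stopifnot(length(truth) == length(scores))
  truth <- as.logical(truth)
  calls <- if (direction == "le") scores <= threshold else scores >= threshold
  c(tp = sum(calls & truth), fp = sum(calls & !truth),
    tn = sum(!calls & !truth), fn = sum(!calls & truth))
}

#' FDR / power curve over all score thresholds
#'
#' Sweeps the threshold over the sorted unique scores, from strictest to
#' loosest. Power is non-decreasing as the threshold loosens; the curve is
#' invariant to strictly monotone transformations of the scores.
#'
#' @inheritParams confusion_at
#' @return A data frame of class `eval_curve` with columns `threshold`,
#'   `tp`, `fp`, `tn`, `fn`, `fdr`, `power`.
#' @export
fdr_power_curve <- function(truth, scores, direction = c("le", "ge")) {
  direction <- match.arg(direction)
  stopifnot(length(truth) == length(scores))
  truth <- as.logical(truth)
  thr <- sort(unique(scores), decreasing = (direction == "ge"))
  npos <- sum(truth)
  nneg <- sum(!truth)
  # cumulative tabulation: order tests from strictest-calling to loosest
  o <- order(scores, decreasing = (direction == "ge"))
  st <- scores[o]
  cum_tp <- cumsum(truth[o])
  cum_fp <- cumsum(!truth[o])
  # index of the last test called at each threshold; st is sorted in
  # calling order so this is a count of tests at or past the threshold
  pos <- if (direction == "le") findInterval(thr, st)
         else findInterval(-thr, -st)
  tp <- cum_tp[pos]
  fp <- cum_fp[pos]
  fdr <- ifelse(tp + fp == 0, 0, fp / (tp + fp))
  power <- if (npos == 0) rep(0, length(thr)) else tp / npos
  structure(data.frame(threshold = thr, tp = tp, fp = fp,
                       tn = nneg - fp, fn = npos - tp,
                       fdr = fdr, power = power),
            class = c("eval_curve", "data.frame"))
}

#' Restrict the evaluation universe by effect sign
#'
#' Unsigned ranking scores (such as divergence measures) cannot flag
#' negative differences, so comparisons against them omit tests whose true
#' effect is negative. Zero-effect tests are retained (they are nulls).
#'
#' @param truth_effects Signed vector of true effects.
#' @param mode `"all"` (identity) or `"positive_only"`.
#' @return Logical vector: which tests stay in the evaluation.
#' @export
signed_tests_filter <- function(truth_effects,
                                mode = c("all", "positive_only")) {
  mode <- match.arg(mode)
  if (mode == "all")
    rep(TRUE, length(truth_effects))
  else
    truth_effects >= 0
}
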