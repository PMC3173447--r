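#' Median kinetic parameters of a fitted map
#'
#' Tumour-level summary used for pre/post comparison: the median `ktrans` and
#' `ve` over the fitted voxels only.
#'
#' @param map A `param_map` from [fit_tofts_map()].
#' @return Named numeric vector `c(ktrans = ..., ve = ...)`.
#' @export
summarize_roi <- function(map) {
  if (!inherits(map, "param_map")) stop_input("`map` must be a param_map")
  v <- map$voxels[map$voxels$fitted, ]
  if (nrow(v) == 0L) stop_input("no fitted voxels in the map")
  c(ktrans = stats::median(v$ktrans), ve = stats::median(v$ve))
}

#' Percent change between two exams
#'
#' `100 * (post - pre) / pre`. Full precision is returned; round for display
#' with [round_percent()].
#'
#' @param pre,post Parameter value before and after treatment; `pre` must be
#'   positive.
#' @return Percent change (vectorised).
#' @export
percent_change <- function(pre, post) {
  if (any(pre <= 0)) stop_input("`pre` must be positive")
  100 * (post - pre) / pre
}

#' Round a percentage for table display
#'
#' Rounds half away from zero to integer percent, the convention used when
#' comparing against printed clinical tables.
#'
#' @param x Percent value(s).
#' @return Integer percent(s).
#' @export
round_percent <- function(x) round_half_up(x)

#' Classify a kinetic-parameter change against a cutoff
#'
#' A patient is called a responder when the parameter dropped at least as far
#' as the cutoff (`change <= cutoff`) and a non-responder otherwise
#' (`change > cutoff`, strict). The boundary is inclusive toward responder:
#' a change exactly equal to the cutoff counts as response.
#'
#' @param change Percent change(s) in the parameter.
#' @param cutoff Cutoff in percent (e.g. -72).
#' @return Factor with levels `responder`, `non_responder`.
#' @export
classify_by_cutoff <- function(change, cutoff) {
  factor(ifelse(change > cutoff, "non_responder", "responder"),
         levels = c("responder", "non_responder"))
}

#' Joint Ktrans/Ve cutoff classification
#'
#' Flags non-response when either parameter fails to drop past its cutoff:
#' `non_responder` iff `ktrans_change > ktrans_cutoff` OR
#' `ve_change > ve_cutoff`; responder otherwise.
#'
#' @param ktrans_change,ve_change Percent changes.
#' @param ktrans_cutoff,ve_cutoff Cutoffs in percent (defaults -82 and -72).
#' @return Factor with levels `responder`, `non_responder`.
#' @export
classify_combined <- function(ktrans_change, ve_change,
                              ktrans_cutoff = -82, ve_cutoff = -72) {
  factor(ifelse(ktrans_change > ktrans_cutoff | ve_change > ve_cutoff,
                "non_responder", "responder"),
         levels = c("responder", "non_responder"))
}

#' WHO size-based response classification
#'
#' Conventional anatomic criterion: responder iff the tumour size decreased
#' by at least 50% (`size_change <= -50`).
#'
#' @param size_change Percent change(s) in tumour size.
#' @return Factor with levels `responder`, `non_responder`.
#' @export
who_size_classify <- function(size_change) {
  factor(ifelse(size_change <= -50, "responder", "non_responder"),
         levels = c("responder", "non_responder"))
}

#' Diagnostic performance of a binary classification
#'
#' Confusion counts and the standard rates, with exact (Clopper-Pearson)
#' binomial 95% confidence intervals for sensitivity and specificity.
#' Rates are reported both as raw fractions and rounded half-away-from-zero
#' to integer percent.
#'
#' @param predicted,truth Vectors of equal length holding class labels.
#' @param positive The label counted as positive (e.g. `"non_responder"`).
#' @return An object of class `classification_result` with elements `tp`,
#'   `fp`, `tn`, `fn`, `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy` (integer percents), `rates` (raw fractions),
#'   `sensitivity_ci`, `specificity_ci` (percent bounds), `positive`.
#' @export
diagnostic_performance <- function(predicted, truth, positive) {
  if (length(predicted) != length(truth))
    stop_input("`predicted` and `truth` must have the same length")
  truth_pos <- truth == positive
  if (all(truth_pos) || !any(truth_pos))
    stop_input("`truth` must contain both classes")
  pred_pos <- predicted == positive
  tp <- sum(pred_pos & truth_pos)
  fp <- sum(pred_pos & !truth_pos)
  fn <- sum(!pred_pos & truth_pos)
  tn <- sum(!pred_pos & !truth_pos)
  rates <- c(sensitivity = tp / (tp + fn),
             specificity = tn / (tn + fp),
             ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
             npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
             accuracy = (tp + tn) / (tp + tn + fp + fn))
  ci <- function(k, n) round_half_up(100 * as.numeric(stats::binom.test(k, n)$conf.int))
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = round_half_up(100 * rates[["sensitivity"]]),
    specificity = round_half_up(100 * rates[["specificity"]]),
    ppv = round_half_up(100 * rates[["ppv"]]),
    npv = round_half_up(100 * rates[["npv"]]),
    accuracy = round_half_up(100 * rates[["accuracy"]]),
    rates = rates,
    sensitivity_ci = ci(tp, tp + fn),
    specificity_ci = ci(tn, tn + fp),
    positive = positive), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> positive = %s\n", x$positive))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sensitivity %d%% (95%% CI %d%%, %d%%)  specificity %d%% (95%% CI %d%%, %d%%)\n",
              x$sensitivity, x$sensitivity_ci[1], x$sensitivity_ci[2],
              x$specificity, x$specificity_ci[1], x$specificity_ci[2]))
  cat(sprintf("  PPV %d%%  NPV %d%%  accuracy %d%%\n", x$ppv, x$npv, x$accuracy))
  invisible(x)
}
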