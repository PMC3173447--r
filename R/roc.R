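#' Pair-counting (Mann-Whitney) AUC
#'
#' Area under the ROC curve as the probability that a randomly drawn positive
#' scores above a randomly drawn negative, with ties counted one half:
#' `AUC = mean over all (pos, neg) pairs of [pos > neg] + 0.5 [pos == neg]`.
#'
#' @param scores_pos Scores of the positive class.
#' @param scores_neg Scores of the negative class.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0L || length(scores_neg) == 0L)
    stop_input("both score groups must be non-empty")
  mean(outer(scores_pos, scores_neg, ">") +
         0.5 * outer(scores_pos, scores_neg, "=="))
}

# placement values: for each positive, the fraction of negatives it beats
# (ties half), and symmetrically for each negative
placements <- function(scores_pos, scores_neg) {
  psi <- outer(scores_pos, scores_neg, ">") +
    0.5 * outer(scores_pos, scores_neg, "==")
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' Empirical ROC curve
#'
#' Thresholds at every unique score (plus the two degenerate extremes); a
#' subject is called positive when its score strictly exceeds the threshold.
#' The trapezoidal area of the stored points equals the pair-counting AUC.
#' Placement values are retained for the DeLong covariance computation.
#'
#' @param scores Numeric scores, higher = more positive-like.
#' @param labels Class labels, same length.
#' @param positive Label of the positive class.
#' @return An object of class `roc_result` with `thresholds`, `tpr`, `fpr`,
#'   `auc`, `n_pos`, `n_neg` and placement values `v10`, `v01`.
#' @export
empirical_roc <- function(scores, labels, positive) {
  if (length(scores) != length(labels))
    stop_input("`scores` and `labels` must have the same length")
  is_pos <- labels == positive
  if (all(is_pos) || !any(is_pos))
    stop_input("both classes must be present")
  sp <- scores[is_pos]
  sn <- scores[!is_pos]
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(c) mean(sp > c), numeric(1))
  fpr <- vapply(thr, function(c) mean(sn > c), numeric(1))
  pl <- placements(sp, sn)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr,
                 auc = sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2),
                 n_pos = length(sp), n_neg = length(sn),
                 v10 = pl$v10, v01 = pl$v01),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%d positives, %d negatives, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, length(x$thresholds)))
  invisible(x)
}

test_result <- function(statistic, p_value, method, ...) {
  structure(c(list(statistic = statistic, p_value = p_value, method = method),
              list(...)),
            class = "kinetic_test")
}

#' @export
print.kinetic_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  invisible(x)
}

#' DeLong test for two correlated (paired) AUCs
#'
#' Compares the AUCs of two score systems evaluated on the same subjects,
#' using the placement-value covariance estimator of the AUC difference and a
#' two-sided z test. When the placement values are degenerate (zero estimated
#' variance of the difference), the test is flagged and `p = 1` is returned.
#'
#' @param scores_a,scores_b Paired scores for the same subjects.
#' @param labels Common class labels.
#' @param positive Label of the positive class.
#' @return A test result with `statistic` (z), `p_value`, `auc_a`, `auc_b`,
#'   `var_diff` and a `degenerate` flag.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels, positive) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop_input("paired scores and labels must have the same length")
  is_pos <- labels == positive
  if (all(is_pos) || !any(is_pos)) stop_input("both classes must be present")
  pa <- placements(scores_a[is_pos], scores_a[!is_pos])
  pb <- placements(scores_b[is_pos], scores_b[!is_pos])
  m <- sum(is_pos)
  n <- sum(!is_pos)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (!is.finite(var_diff) || var_diff <= .Machine$double.eps) {
    return(test_result(0, 1, "DeLong paired AUC comparison",
                       auc_a = pa$auc, auc_b = pb$auc,
                       var_diff = var_diff, degenerate = TRUE))
  }
  z <- (pa$auc - pb$auc) / sqrt(var_diff)
  test_result(z, 2 * stats::pnorm(-abs(z)), "DeLong paired AUC comparison",
              auc_a = pa$auc, auc_b = pb$auc,
              var_diff = var_diff, degenerate = FALSE)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples with midrank tie handling.
#' The exact distribution is used for small tie-free samples
#' (`n * m <= 400`); otherwise the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return A test result with the U statistic (for `x` vs `y`), `p_value`,
#'   and a `ties` flag.
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided") {
  if (length(x) == 0L || length(y) == 0L)
    stop_input("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) * length(y) <= 400
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE))
  test_result(unname(wt$statistic), wt$p.value, "Mann-Whitney U",
              ties = ties, exact = exact)
}

#' Kruskal-Wallis rank test
#'
#' H statistic with midranks and the usual tie correction, referred to a
#' chi-square distribution with `k - 1` degrees of freedom. Intended for three
#' or more groups; with two groups it reduces to the squared Mann-Whitney
#' z statistic on tie-free data.
#'
#' @param groups List of two or more non-empty numeric samples.
#' @return A test result with `statistic` (H), `p_value` and `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_input("`groups` must be a list of at least two samples")
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop_input("all groups must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  kt <- stats::kruskal.test(x, g)
  test_result(unname(kt$statistic), kt$p.value, "Kruskal-Wallis",
              df = unname(kt$parameter))
}
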