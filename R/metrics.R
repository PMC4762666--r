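#' Sensitivity, specificity and balanced accuracy
#'
#' Sensitivity is the fraction of progressors (label 1) correctly called,
#' specificity the fraction of non-progressors (label 0) correctly called,
#' and the balanced accuracy rate BAR = (Sn + Sp) / 2 — the study's primary
#' performance measure, robust to the mild class imbalance of MCI cohorts.
#' When a class is absent from `labels`, its metric (and hence BAR) is
#' returned as `NA` with a `missing_class` flag rather than a silent number.
#'
#' @param labels true binary 0/1 labels.
#' @param predicted predicted binary 0/1 labels.
#' @return list with `sn`, `sp`, `bar` (proportions in `[0, 1]` or `NA`) and
#'   `missing_class`.
#' @export
classification_metrics <- function(labels, predicted) {
  labels <- as.integer(labels); predicted <- as.integer(predicted)
  if (length(labels) != length(predicted)) stopf("length mismatch")
  if (!all(c(labels, predicted) %in% c(0L, 1L)))
    stopf("labels and predictions must be binary 0/1")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  sn <- if (n_pos > 0) sum(predicted == 1L & labels == 1L) / n_pos else NA_real_
  sp <- if (n_neg > 0) sum(predicted == 0L & labels == 0L) / n_neg else NA_real_
  bar <- if (!is.na(sn) && !is.na(sp)) (sn + sp) / 2 else NA_real_
  list(sn = sn, sp = sp, bar = bar,
       missing_class = n_pos == 0L || n_neg == 0L)
}

#' Balanced accuracy from sensitivity and specificity
#'
#' @param sn,sp sensitivity and specificity (same scale, proportion or
#'   percent).
#' @return `(sn + sp) / 2` on the input scale.
#' @export
balanced_accuracy <- function(sn, sp) (sn + sp) / 2

#' Area under the ROC curve
#'
#' The Mann-Whitney form: the probability that a random progressor scores
#' above a random non-progressor, with half credit for ties, computed from
#' average ranks.
#'
#' @param labels binary 0/1 labels; both classes must be present.
#' @param scores real-valued risk scores (higher = more progressor-like).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) stopf("length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present for AUC")
  r <- rank(scores)                       # average ranks: ties get half credit
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Lin's concordance correlation coefficient on two paired vectors
#'
#' `CCC = 2 s_xy / (s_x^2 + s_y^2 + (xbar - ybar)^2)` with population
#' (divide-by-n) moments, Lin's original estimator.
#'
#' @param x,y paired numeric vectors.
#' @return the CCC in `[-1, 1]`.
#' @export
concordance_ccc <- function(x, y) {
  if (length(x) != length(y)) stopf("length mismatch")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxy <- mean((x - mx) * (y - my))
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' Probability calibration curve and concordance correlation
#'
#' Predictions are binned into `n_bins` equal-width probability
#' sub-intervals of `[0, 1]`; each non-empty bin contributes a pair (mean
#' predicted probability, observed event rate), and agreement between the
#' two is summarized by Lin's concordance correlation coefficient. A
#' well-calibrated model puts the pairs on the diagonal and the CCC near 1.
#' When predictions occupy fewer than `n_bins` sub-intervals the CCC is
#' flagged unavailable (`NA`), mirroring how over-concentrated probability
#' outputs leave the calibration curve undefined.
#'
#' @param probs predicted progression probabilities in `[0, 1]`.
#' @param labels observed binary 0/1 outcomes.
#' @param n_bins number of equal-width probability sub-intervals (default
#'   10, i.e. deciles of the probability axis).
#' @return list of class `calibration` with `curve` (data.frame: bin,
#'   mid, n, mean_predicted, observed_rate), `ccc` (`NA` when unavailable),
#'   `available`, and `n_occupied`.
#' @export
calibration_ccc <- function(probs, labels, n_bins = 10) {
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  labels <- as.integer(labels)
  if (length(probs) != length(labels)) stopf("length mismatch")
  bin <- pmin(floor(probs * n_bins) + 1L, n_bins)   # right edge joins last bin
  curve <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    data.frame(bin = b, mid = (b - 0.5) / n_bins, n = sum(sel),
               mean_predicted = if (any(sel)) mean(probs[sel]) else NA_real_,
               observed_rate = if (any(sel)) mean(labels[sel]) else NA_real_)
  }))
  occupied <- curve$n > 0
  available <- sum(occupied) >= n_bins
  ccc <- if (available)
    concordance_ccc(curve$mean_predicted[occupied],
                    curve$observed_rate[occupied]) else NA_real_
  structure(list(curve = curve, ccc = ccc, available = available,
                 n_occupied = sum(occupied)),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  if (x$available) {
    cat(sprintf("<calibration> CCC = %.4f over %d probability sub-intervals\n",
                x$ccc, x$n_occupied))
  } else {
    cat(sprintf(
      "<calibration> CCC unavailable: only %d of %d sub-intervals occupied\n",
      x$n_occupied, nrow(x$curve)))
  }
  invisible(x)
}

#' Corrected paired t-test for repeated cross-validation
#'
#' Performance estimates from the k*r folds of a repeated CV experiment are
#' positively correlated because training sets overlap, so the naive paired
#' t-test is anti-conservative. The corrected statistic inflates the
#' variance by the test/train size ratio:
#' `t = mean(d) / sqrt((1/(k r) + rho) * var(d))` with
#' `rho = (1/k) / (1 - 1/k)`, and the two-sided p-value is taken from a t
#' distribution with `r` degrees of freedom (the calibration for 10x10
#' experiments; 10 df there).
#'
#' @param diffs vector of `k * r` paired per-fold performance differences.
#' @param k folds per repetition.
#' @param r repetitions.
#' @return list with `t`, `p`, `df`, and `degenerate` (`TRUE` when the
#'   differences have zero variance but nonzero mean, in which case `p` is
#'   reported as 0).
#' @export
corrected_cv_ttest <- function(diffs, k, r) {
  if (length(diffs) != k * r)
    stopf("expected %d differences (k*r), got %d", k * r, length(diffs))
  m <- mean(diffs); s2 <- stats::var(diffs)
  rho <- (1 / k) / (1 - 1 / k)
  df <- r
  if (s2 == 0) {
    if (m == 0) return(list(t = 0, p = 1, df = df, degenerate = FALSE))
    return(list(t = sign(m) * Inf, p = 0, df = df, degenerate = TRUE))
  }
  t_stat <- m / sqrt((1 / (k * r) + rho) * s2)
  p <- 2 * stats::pt(-abs(t_stat), df = df)
  list(t = t_stat, p = p, df = df, degenerate = FALSE)
}
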