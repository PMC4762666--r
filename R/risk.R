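#' Predictive confidence of a probabilistic prediction
#'
#' Confidence is the difference between the predicted probabilities for the
#' two classes (for more than two classes: between the two largest). A
#' confidence of 0.4 corresponds to binary probabilities (0.70, 0.30).
#'
#' @param probabilities a probability vector over classes, or a matrix with
#'   one row per subject.
#' @return confidence value(s) in `[0, 1]`.
#' @export
confidence <- function(probabilities) {
  one <- function(p) {
    s <- sort(p, decreasing = TRUE)
    s[1] - s[2]
  }
  if (is.matrix(probabilities)) apply(probabilities, 1, one)
  else one(probabilities)
}

#' Accuracy under a reject option
#'
#' Classification with a reject option withholds predictions whose
#' confidence falls below a threshold. For each threshold the curve records
#' the coverage (fraction of subjects retained: confidence >= threshold)
#' and the balanced accuracy, sensitivity and specificity over the retained
#' subjects; raising the required confidence trades coverage for accuracy.
#' Metrics are flagged `NA` when a retained class is empty.
#'
#' @param predictions a `pmkl_prediction`, or a list with elements
#'   `confidence` and `label` (predicted 0/1).
#' @param labels true binary 0/1 labels.
#' @param thresholds ascending confidence thresholds in `[0, 1]`.
#' @return object of class `reject_option_curve`: data.frame with columns
#'   `threshold`, `coverage`, `n_retained`, `bar`, `sn`, `sp`.
#' @export
reject_option_curve <- function(predictions, labels,
                                thresholds = seq(0, 0.9, by = 0.1)) {
  conf <- predictions$confidence
  pred <- as.integer(predictions$label)
  labels <- as.integer(labels)
  if (length(conf) != length(labels)) stopf("length mismatch")
  if (any(thresholds < 0 | thresholds > 1)) stopf("thresholds must be in [0,1]")
  thresholds <- sort(thresholds)
  rows <- lapply(thresholds, function(th) {
    keep <- conf >= th
    if (!any(keep))
      return(data.frame(threshold = th, coverage = 0, n_retained = 0L,
                        bar = NA_real_, sn = NA_real_, sp = NA_real_))
    m <- classification_metrics(labels[keep], pred[keep])
    data.frame(threshold = th, coverage = mean(keep),
               n_retained = sum(keep), bar = m$bar, sn = m$sn, sp = m$sp)
  })
  structure(do.call(rbind, rows), class = c("reject_option_curve",
                                            "data.frame"))
}

#' Subgroup-stratified classification metrics
#'
#' Computes BAR/Sn/Sp within patient subgroups (age bands, sex, APOE
#' carrier status, time-to-progression bins, ...). When predictions from
#' several CV repetitions are supplied, per-stratum metrics are summarized
#' with a mean and a 95% confidence interval across repetitions; strata
#' smaller than `min_n` subjects are flagged unstable rather than dropped.
#'
#' @param predictions data.frame with columns `predicted` (0/1) and
#'   optionally `rep` (CV repetition index; absent = single run).
#' @param labels true binary 0/1 labels, aligned with one repetition's rows.
#' @param strata vector (or factor) assigning each subject to exactly one
#'   stratum; `NA` is not allowed.
#' @param min_n strata below this size are flagged (default 10).
#' @return object of class `stratified_report`: data.frame with one row per
#'   stratum: `n`, mean `bar`/`sn`/`sp` and their 95% CIs across
#'   repetitions, and an `unstable` flag.
#' @export
stratified_metrics <- function(predictions, labels, strata, min_n = 10) {
  labels <- as.integer(labels)
  n <- length(labels)
  strata <- as.factor(strata)
  if (length(strata) != n) stopf("strata must assign every subject")
  if (anyNA(strata)) stopf("every subject must belong to exactly one stratum")
  if (is.null(predictions$rep)) predictions$rep <- 1L
  reps <- sort(unique(predictions$rep))

  rows <- lapply(levels(strata), function(st) {
    idx <- which(strata == st)
    per_rep <- vapply(reps, function(rp) {
      d <- predictions[predictions$rep == rp, ]
      m <- classification_metrics(labels[idx], as.integer(d$predicted[idx]))
      c(m$bar, m$sn, m$sp)
    }, numeric(3))
    ci <- function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) return(c(NA_real_, NA_real_))
      se <- stats::sd(v) / sqrt(length(v))
      mean(v) + c(-1, 1) * stats::qt(0.975, length(v) - 1) * se
    }
    bar_ci <- ci(per_rep[1, ]); sn_ci <- ci(per_rep[2, ]); sp_ci <- ci(per_rep[3, ])
    data.frame(stratum = st, n = length(idx),
               bar = mean(per_rep[1, ], na.rm = TRUE),
               bar_lo = bar_ci[1], bar_hi = bar_ci[2],
               sn = mean(per_rep[2, ], na.rm = TRUE),
               sn_lo = sn_ci[1], sn_hi = sn_ci[2],
               sp = mean(per_rep[3, ], na.rm = TRUE),
               sp_lo = sp_ci[1], sp_hi = sp_ci[2],
               unstable = length(idx) < min_n)
  })
  structure(do.call(rbind, rows), class = c("stratified_report",
                                            "data.frame"))
}

#' Time-to-progression strata for progressors
#'
#' Bins progression times into the follow-up intervals
#' (0-6, 6-12, 12-18, 18-24, 24-36 months], or the coarse split at 18
#' months.
#'
#' @param times months to progression.
#' @param coarse if `TRUE`, two bins split at 18 months.
#' @return factor of time bins.
#' @export
time_bins <- function(times, coarse = FALSE) {
  breaks <- if (coarse) c(0, 18, 36) else c(0, 6, 12, 18, 24, 36)
  cut(times, breaks = breaks, include.lowest = FALSE)
}

#' Post-test probabilities of progression by Bayes' rule
#'
#' Given a pre-test probability of progression `prior` and a test with
#' sensitivity `sn` and specificity `sp`, the positive post-test probability
#' is `sn * prior / (sn * prior + (1 - sp) (1 - prior))` (probability of
#' progression given a "progressor" call) and the negative post-test
#' probability is `(1 - sn) * prior / ((1 - sn) * prior + sp (1 - prior))`
#' (probability of progression despite a "non-progressor" call).
#'
#' @param prior pre-test probability in `[0, 1]` (e.g. 0.30 for a 3-year
#'   MCI-to-dementia progression risk).
#' @param sn,sp sensitivity and specificity in `[0, 1]`.
#' @return list with `positive`, `negative`, and `degenerate` (flag set
#'   when a denominator vanishes and the value is defined by its limit).
#' @export
post_test_probability <- function(prior, sn, sp) {
  stopifnot(prior >= 0, prior <= 1, sn >= 0, sn <= 1, sp >= 0, sp <= 1)
  den_pos <- sn * prior + (1 - sp) * (1 - prior)
  den_neg <- (1 - sn) * prior + sp * (1 - prior)
  degenerate <- den_pos == 0 || den_neg == 0
  positive <- if (den_pos > 0) sn * prior / den_pos else prior
  negative <- if (den_neg > 0) (1 - sn) * prior / den_neg else prior
  list(positive = positive, negative = negative, degenerate = degenerate)
}

#' Spearman correlation between predicted risk and time to progression
#'
#' Among progressors, a well-behaved probabilistic model assigns larger
#' progression probabilities to subjects who progress sooner, giving a
#' negative rank correlation. Ties (the rule, since times sit on a 5-point
#' visit grid) are handled by average ranks; the two-sided p-value uses the
#' t approximation.
#'
#' @param probs predicted progression probabilities for progressors.
#' @param times months to progression, aligned with `probs`.
#' @return list with `rho` and `p`.
#' @export
risk_time_correlation <- function(probs, times) {
  if (length(probs) != length(times)) stopf("length mismatch")
  if (length(probs) < 4) stopf("need at least 4 progressors for a p-value")
  ct <- suppressWarnings(stats::cor.test(probs, times, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Baseline group comparisons between non-progressors and progressors
#'
#' For each requested variable (a feature or a stratum covariate), compares
#' the two outcome groups: continuous variables by a pooled-variance
#' two-sample t-test with per-group mean +/- SD; binary variables by a
#' Pearson chi-square test (no continuity correction) on the 2x2 table with
#' per-group prevalence. Degenerate cases (zero variance in both groups,
#' expected cell counts below 1) are flagged instead of tested.
#'
#' @param dataset a labelled [cohort_dataset()].
#' @param variables names of features and/or strata columns (default: all
#'   features).
#' @return data.frame, one row per variable: `type` ("continuous" or
#'   "binary"), group descriptives, `statistic`, `df`, `p`, `flag`.
#' @export
group_comparison <- function(dataset, variables = NULL) {
  if (is.null(dataset$labels)) stopf("group comparison needs labels")
  y <- dataset$labels
  variables <- variables %||% dataset$feature_names
  get_var <- function(v) {
    if (v %in% dataset$feature_names) dataset$features[, v]
    else if (!is.null(dataset$strata) && v %in% names(dataset$strata))
      dataset$strata[[v]]
    else stopf("unknown variable '%s'", v)
  }
  rows <- lapply(variables, function(v) {
    x <- as.numeric(get_var(v))
    g0 <- x[y == 0L]; g1 <- x[y == 1L]
    binary <- all(x %in% c(0, 1))
    if (binary) {
      tab <- table(factor(x, levels = c(0, 1)), factor(y, levels = c(0, 1)))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 1))
        return(data.frame(variable = v, type = "binary",
                          neg_mean = mean(g0), neg_sd = NA_real_,
                          pos_mean = mean(g1), pos_sd = NA_real_,
                          statistic = NA_real_, df = NA_real_, p = NA_real_,
                          flag = "low_expected_count"))
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      data.frame(variable = v, type = "binary",
                 neg_mean = mean(g0), neg_sd = NA_real_,
                 pos_mean = mean(g1), pos_sd = NA_real_,
                 statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value, flag = "")
    } else {
      if (stats::sd(g0) == 0 && stats::sd(g1) == 0)
        return(data.frame(variable = v, type = "continuous",
                          neg_mean = mean(g0), neg_sd = 0,
                          pos_mean = mean(g1), pos_sd = 0,
                          statistic = NA_real_, df = NA_real_, p = NA_real_,
                          flag = "zero_variance"))
      tt <- stats::t.test(g1, g0, var.equal = TRUE)
      data.frame(variable = v, type = "continuous",
                 neg_mean = mean(g0), neg_sd = stats::sd(g0),
                 pos_mean = mean(g1), pos_sd = stats::sd(g1),
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, flag = "")
    }
  })
  do.call(rbind, rows)
}
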