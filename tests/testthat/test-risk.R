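test_that("predictive confidence is the gap between class probabilities", {
  expect_equal(confidence(c(0.70, 0.30)), 0.4)
  expect_equal(confidence(c(0.5, 0.5)), 0)
  expect_equal(confidence(c(1, 0)), 1)
  # matrix input, and multiclass: gap between the two largest
  expect_equal(confidence(rbind(c(0.2, 0.8), c(0.45, 0.55))),
               c(0.6, 0.1))
  expect_equal(confidence(c(0.5, 0.3, 0.2)), 0.2)
})

test_that("reject-option curve trades coverage for accuracy correctly", {
  preds <- list(confidence = c(0.1, 0.3, 0.6, 0.9),
                label = c(1L, 0L, 1L, 0L))
  labels <- c(1L, 1L, 1L, 0L)
  rc <- reject_option_curve(preds, labels, thresholds = c(0, 0.5, 1))

  # threshold 0 retains everyone and reproduces the overall metrics
  overall <- classification_metrics(labels, preds$label)
  expect_equal(rc$coverage[1], 1)
  expect_equal(rc$bar[1], overall$bar)

  # threshold 0.5 retains exactly subjects 3 and 4 (hand enumeration)
  m2 <- classification_metrics(labels[3:4], preds$label[3:4])
  expect_equal(rc$coverage[2], 0.5)
  expect_equal(rc$n_retained[2], 2L)
  expect_equal(rc$bar[2], m2$bar)
  expect_equal(rc$sn[2], 1); expect_equal(rc$sp[2], 1)

  # threshold above the maximum confidence: zero coverage, flagged metrics
  expect_equal(rc$coverage[3], 0)
  expect_true(is.na(rc$bar[3]))

  # coverage is non-increasing in the threshold for arbitrary inputs
  set.seed(31)
  for (i in 1:20) {
    n <- 50
    p <- list(confidence = runif(n), label = sample(c(0L, 1L), n, TRUE))
    y <- sample(c(0L, 1L), n, TRUE)
    r <- reject_option_curve(p, y, thresholds = seq(0, 1, 0.05))
    expect_true(all(diff(r$coverage) <= 0))
    expect_equal(r$coverage[1], 1)
  }
})

test_that("stratified metrics match direct subset computation and pool back", {
  set.seed(17)
  n <- 6
  labels <- c(1, 1, 0, 0, 1, 0)
  pred <- data.frame(predicted = c(1, 0, 0, 1, 1, 0))
  strata <- c("a", "a", "a", "a", "b", "b")
  rep_ <- stratified_metrics(pred, labels, strata, min_n = 2)
  # per-stratum metrics equal direct computation on the subsets
  ma <- classification_metrics(labels[1:4], pred$predicted[1:4])
  mb <- classification_metrics(labels[5:6], pred$predicted[5:6])
  expect_equal(rep_$bar[rep_$stratum == "a"], ma$bar)
  expect_equal(rep_$sn[rep_$stratum == "b"], mb$sn)
  # stratum sizes partition the cohort
  expect_equal(sum(rep_$n), n)

  # single stratum = whole cohort: equals the overall metrics exactly
  whole <- stratified_metrics(pred, labels, rep("all", n))
  overall <- classification_metrics(labels, pred$predicted)
  expect_equal(whole$bar, overall$bar)
  expect_true(whole$unstable)           # n = 6 < 10 flagged, not dropped

  # an empty stratum level is reported and flagged, not silently dropped
  st <- factor(strata, levels = c("a", "b", "c"))
  rep3 <- stratified_metrics(pred, labels, st, min_n = 2)
  expect_equal(nrow(rep3), 3)
  expect_true(is.na(rep3$bar[rep3$stratum == "c"]) ||
                is.nan(rep3$bar[rep3$stratum == "c"]))
  expect_true(rep3$unstable[rep3$stratum == "c"])

  expect_error(stratified_metrics(pred, labels, strata[1:3]), "every subject")
})

test_that("time bins partition progressors on the follow-up grid", {
  t <- c(6, 12, 18, 24, 36)
  b <- time_bins(t)
  expect_equal(as.character(b), c("(0,6]", "(6,12]", "(12,18]", "(18,24]",
                                  "(24,36]"))
  bc <- time_bins(t, coarse = TRUE)
  expect_equal(as.character(bc), c("(0,18]", "(0,18]", "(0,18]", "(18,36]",
                                   "(18,36]"))
})

test_that("Bayes-rule post-test probabilities behave analytically", {
  # an uninformative test returns the prior on both sides
  u <- post_test_probability(0.3, 0.5, 0.5)
  expect_equal(u$positive, 0.3); expect_equal(u$negative, 0.3)

  # monotone in the prior; positive >= prior >= negative when sn + sp > 1
  priors <- seq(0.05, 0.95, 0.05)
  outs <- sapply(priors, function(p) {
    o <- post_test_probability(p, 0.834, 0.764)
    c(o$positive, o$negative)
  })
  expect_true(all(diff(outs[1, ]) > 0))
  expect_true(all(diff(outs[2, ]) > 0))
  expect_true(all(outs[1, ] >= priors & priors >= outs[2, ]))

  d <- post_test_probability(0, 0, 1)
  expect_true(d$degenerate)
})

test_that("risk-time correlation uses average ranks and the t approximation", {
  # strictly decreasing times in probability, no ties: rho = -1
  p <- c(0.9, 0.8, 0.6, 0.4, 0.2)
  t_ <- c(6, 12, 18, 24, 36)
  expect_equal(risk_time_correlation(p, t_)$rho, -1)

  # hand set with tied times: equals rank-then-Pearson (average ranks)
  p6 <- c(0.9, 0.7, 0.65, 0.5, 0.3, 0.2)
  t6 <- c(6, 6, 18, 18, 24, 36)
  out <- risk_time_correlation(p6, t6)
  expect_equal(out$rho, cor(rank(p6), rank(t6)))
  # and the p-value is the two-sided t approximation on that rho
  r <- cor(rank(p6), rank(t6)); n <- 6
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(out$p, 2 * pt(-abs(tstat), n - 2))

  # independent probabilities: null rho near zero
  set.seed(61)
  pn <- runif(1000); tn <- sample(c(6, 12, 18, 24, 36), 1000, TRUE)
  expect_lt(abs(risk_time_correlation(pn, tn)$rho), 0.07)

  expect_error(risk_time_correlation(c(0.1, 0.2, 0.3), c(6, 12, 18)),
               "at least 4")
})

test_that("group comparisons match their closed-form oracles", {
  X <- cbind(v = c(1, 2, 3, 4, 5, 6),
             b = c(0, 0, 1, 0, 1, 1))
  colnames(X) <- c("v", "b")
  ds <- cohort_dataset(X, setNames(c("CAM", "CRF"), c("v", "b")),
                       labels = c(0, 0, 0, 1, 1, 1))

  # {1,2,3} vs {4,5,6}: pooled-variance t by hand: mean diff 3, pooled s = 1,
  # se = sqrt(1/3 + 1/3), t = 3 / sqrt(2/3)
  gc <- group_comparison(ds, "v")
  expect_equal(gc$statistic, 3 / sqrt(2 / 3))
  expect_equal(gc$df, 4)

  # identical groups: t = 0, p = 1
  X2 <- cbind(w = c(1, 2, 3, 1, 2, 3))
  colnames(X2) <- "w"
  ds2 <- cohort_dataset(X2, setNames("CAM", "w"), labels = c(0, 0, 0, 1, 1, 1))
  gc2 <- group_comparison(ds2, "w")
  expect_equal(gc2$statistic, 0); expect_equal(gc2$p, 1)

  # 2x2 closed form N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)) on the
  # carrier-by-group table reconstructed from 41.7% of 120 / 66.2% of 139
  y <- c(rep(0, 120), rep(1, 139))
  carrier <- c(rep(1, 50), rep(0, 70), rep(1, 92), rep(0, 47))
  Xc <- cbind(apoe = carrier)
  dsc <- cohort_dataset(Xc, setNames("CRF", "apoe"), labels = y)
  gcc <- group_comparison(dsc, "apoe")
  a <- 50; b <- 92; cc <- 70; dd <- 47   # rows: carrier yes/no, cols: group
  N <- 259
  oracle <- N * (a * dd - b * cc)^2 /
    ((a + b) * (cc + dd) * (a + cc) * (b + dd))
  expect_equal(gcc$statistic, oracle)
  expect_lt(gcc$p, 0.001)

  # zero variance in both groups is flagged, not tested
  X3 <- cbind(z = rep(5, 6), ok = c(1, 2, 3, 4, 5, 6))
  colnames(X3) <- c("z", "ok")
  ds3 <- cohort_dataset(X3, setNames(c("CAM", "CAM"), c("z", "ok")),
                        labels = c(0, 0, 0, 1, 1, 1))
  gc3 <- group_comparison(ds3, "z")
  expect_equal(gc3$flag, "zero_variance")
  expect_true(is.na(gc3$p))
})
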