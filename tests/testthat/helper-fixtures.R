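# fixtures built in code: tiny cohorts, separated clouds, calibrated predictions

# two Gaussian clouds separated by 2*mu in p dimensions
make_clouds <- function(n_per = 30, p = 2, mu = 1.5, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p, -mu), n_per, p),
             matrix(rnorm(n_per * p, mu), n_per, p))
  colnames(x) <- paste0("v", seq_len(p))
  list(x = x, y = rep(c(0L, 1L), each = n_per))
}

# small labelled cohort written to CSV files; returns the paths
write_tiny_cohort <- function(dir, labels = c(0, 1, 0)) {
  feat <- data.frame(subject_id = c("a", "b", "c"),
                     f1 = c(1.5, 2.5, 3.5), f2 = c(10, 20, 30),
                     f3 = c(0.1, 0.2, 0.3), f4 = c(5, 6, 7))
  if (!is.null(labels)) feat$label <- labels
  fp <- file.path(dir, "features.csv")
  mp <- file.path(dir, "meta.csv")
  utils::write.csv(feat, fp, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(feature = paste0("f", 1:4),
                              source = c("CRF", "CAM", "MRI", "PPM")),
                   mp, row.names = FALSE, quote = FALSE)
  list(features = fp, meta = mp)
}

# self-consistent probabilistic predictions: labels drawn from their own
# predicted probabilities (the well-calibrated generator)
make_calibrated_predictions <- function(n = 2000, seed = 1) {
  set.seed(seed)
  p <- runif(n)
  y <- as.integer(runif(n) < p)
  list(prob = p, label = y,
       predicted = as.integer(p > 0.5),
       confidence = abs(2 * p - 1))
}

# brute-force plug-in mutual information oracle over an n x 2 code table
oracle_mi <- function(x_codes, y) {
  tab <- table(x_codes, y)
  n <- sum(tab)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    pxy <- tab[i, j] / n
    if (pxy > 0) mi <- mi + pxy * log(pxy / (px[i] * py[j]))
  }
  unname(mi)
}

fast_control <- function(seed = 1, n_iter = 200, burn_in = 60)
  pmkl_control(n_iter = n_iter, burn_in = burn_in, n_mc_probit = 200,
               seed = seed)
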