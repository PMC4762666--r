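# W matrices engineered so the coefficient-space margin a = (w1 - w2).k
# is set through the bias element alone
margin_W <- function(a, n_train = 3) {
  rbind(c(rep(0, n_train), 0), c(rep(0, n_train), a))
}
bias_row <- function(n_train = 3) c(rep(0, n_train), 1)

test_that("probit class probabilities match symmetry and the closed form", {
  # zero margin: exactly (0.5, 0.5) by symmetry of common random numbers
  P0 <- probit_class_probability(margin_W(0), bias_row(), n_mc = 500, seed = 1)
  expect_equal(unname(P0[1, ]), c(0.5, 0.5))

  # three identical classes: (1/3, 1/3, 1/3)
  W3 <- matrix(0.7, 3, 4)
  P3 <- probit_class_probability(W3, bias_row(), n_mc = 200, seed = 2)
  expect_equal(unname(P3[1, ]), rep(1 / 3, 3))

  # E[Phi(u + a)] = Phi(a / sqrt(2)): binary estimates within 3 MC SEs
  for (a in c(-2, -1, 1, 2)) {
    n_mc <- 1e4
    P <- probit_class_probability(margin_W(-a), bias_row(), n_mc = n_mc,
                                  seed = 7)
    target <- pnorm(a / sqrt(2))
    set.seed(123)                       # independent draw for the SE estimate
    se <- sd(pnorm(rnorm(n_mc) + a)) / sqrt(n_mc)
    expect_lt(abs(P[1, 1] - target), 3 * se + 1e-4)
  }

  # every probability vector sums to one
  set.seed(11)
  W <- matrix(rnorm(12), 3, 4)
  P <- probit_class_probability(W, matrix(rnorm(20), 5, 4), n_mc = 300,
                                seed = 4)
  expect_equal(rowSums(P), rep(1, 5))

  expect_error(probit_class_probability(margin_W(Inf), bias_row()),
               "non-finite")
})

test_that("Monte-Carlo probit error shrinks with the draw budget", {
  err <- sapply(c(1e2, 1e4), function(n_mc) {
    mean(sapply(c(-1.5, -0.5, 0.5, 1.5), function(a) {
      est <- sapply(1:20, function(s)
        probit_class_probability(margin_W(-a), bias_row(), n_mc = n_mc,
                                 seed = s)[1, 1])
      sqrt(mean((est - pnorm(a / sqrt(2)))^2))
    }))
  })
  expect_lt(err[2], err[1] / 3)   # ~10x draws -> ~10x smaller RMSE
})

test_that("the fit separates planted clusters and is reproducible", {
  cl <- make_clouds(n_per = 50, mu = 1.5, seed = 2)
  fit <- pmkl(cl$x, cl$y, control = fast_control(seed = 3, n_iter = 400,
                                                 burn_in = 120))
  pr <- predict(fit, cl$x)
  m <- classification_metrics(cl$y, as.integer(pr$label))
  expect_gte(m$bar, 0.95)

  fit2 <- pmkl(cl$x, cl$y, control = fast_control(seed = 3, n_iter = 400,
                                                  burn_in = 120))
  expect_identical(fit$W, fit2$W)
  expect_identical(fit$beta, fit2$beta)

  expect_error(pmkl(cl$x, rep(1, nrow(cl$x))), "2 classes")
})

test_that("a point-mass beta reproduces the single-kernel fit exactly", {
  cl <- make_clouds(n_per = 25, seed = 5)
  colnames(cl$x) <- c("v1", "v2")
  sm <- setNames(c("CAM", "MRI"), c("v1", "v2"))
  single <- pmkl(cl$x, cl$y,
                 kernels = kernel_spec("linear", name = "all"),
                 control = fast_control(seed = 9))
  # two kernels, beta fixed at (1, 0): kernel 1 is the same linear kernel
  mkl <- pmkl(cl$x, cl$y,
              kernels = list(kernel_spec("linear", name = "all"),
                             kernel_spec("gaussian", features = "MRI")),
              source_map = sm, beta = c(1, 0),
              control = fast_control(seed = 9))
  expect_equal(mkl$W, single$W)
  p1 <- predict(single, cl$x); p2 <- predict(mkl, cl$x)
  expect_equal(p1$prob, p2$prob)
})

test_that("scaling the coefficients sharpens binary probabilities", {
  set.seed(14)
  W <- margin_W(0.8)
  k_rows <- matrix(c(0, 0, 0, 1), 1)
  for (cc in c(2, 5)) {
    p1 <- probit_class_probability(W, k_rows, n_mc = 2000, seed = 6)[1, ]
    p2 <- probit_class_probability(W * cc, k_rows, n_mc = 2000, seed = 6)[1, ]
    expect_gt(abs(p2[1] - 0.5), abs(p1[1] - 0.5))
  }
})

test_that("decision rule: threshold, argmax and the conservative tie", {
  P <- rbind(c(0.30, 0.70), c(0.50, 0.50), c(0.70, 0.30))
  colnames(P) <- c("0", "1")
  out <- pmkl:::classify_probabilities(P, c(0L, 1L), threshold = 0.5)
  expect_equal(out$label, c(1L, 0L, 0L))      # exact tie -> non-progressor
  expect_equal(out$tie, c(FALSE, TRUE, FALSE))
  expect_equal(out$confidence, c(0.4, 0, 0.4))
})

test_that("kernel weights concentrate on the informative source", {
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(n_neg = 40, n_pos = 40,
                      features_per_source = c(CAM = 15, MRI = 15),
                      informative_per_source = c(CAM = 5, MRI = 0),
                      effect_size = 1.5, binary_covariates = NULL, seed = s)
    sim <- simulate_cohort(cfg)
    std <- standardize(sim$dataset, seq_len(80))
    ctl <- pmkl_control(n_iter = 500, burn_in = 150, n_mc_probit = 100,
                        beta_every = 5, seed = s)
    fit <- pmkl(std$features, std$labels,
                kernels = list(kernel_spec("linear", features = "CAM"),
                               kernel_spec("linear", features = "MRI")),
                source_map = std$source_map, control = ctl)
    which.max(fit$beta) == 1L
  }, logical(1))
  expect_gte(sum(hits), 8)
})

test_that("serialized models reload to identical predictions", {
  cl <- make_clouds(n_per = 20, seed = 8)
  fit <- pmkl(cl$x, cl$y, kernels = kernel_spec("gaussian"),
              control = fast_control(seed = 4))
  path <- withr::local_tempfile(fileext = ".json")
  write_pmkl(fit, path)
  back <- read_pmkl(path)
  p1 <- predict(fit, cl$x, seed = 5)
  p2 <- predict(back, cl$x, seed = 5)
  expect_equal(p1$prob, p2$prob, tolerance = 1e-12)
  expect_equal(back$beta, fit$beta)
})
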