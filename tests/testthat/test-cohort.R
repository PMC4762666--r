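test_that("feature tables load with validated dimensions and labels", {
  dir <- withr::local_tempdir()
  paths <- write_tiny_cohort(dir)
  ds <- load_feature_table(paths$features, paths$meta)
  expect_s3_class(ds, "cohort_dataset")
  expect_equal(dim(ds), c(3L, 4L))
  expect_equal(ds$subject_ids, c("a", "b", "c"))
  expect_equal(ds$labels, c(0L, 1L, 0L))
  expect_equal(unname(ds$source_map), c("CRF", "CAM", "MRI", "PPM"))

  # without a label column the dataset is unlabeled
  paths2 <- write_tiny_cohort(withr::local_tempdir(), labels = NULL)
  ds2 <- load_feature_table(paths2$features, paths2$meta)
  expect_null(ds2$labels)
})

test_that("loader contract violations are fatal and name the culprit", {
  dir <- withr::local_tempdir()
  paths <- write_tiny_cohort(dir)

  # a feature absent from the metadata is named in the error
  meta_bad <- utils::read.csv(paths$meta)
  meta_bad <- meta_bad[meta_bad$feature != "f3", ]
  mp_bad <- file.path(dir, "meta_bad.csv")
  utils::write.csv(meta_bad, mp_bad, row.names = FALSE)
  expect_error(load_feature_table(paths$features, mp_bad), "f3")

  # duplicate subject id
  feat <- utils::read.csv(paths$features)
  feat$subject_id[2] <- "a"
  fp_dup <- file.path(dir, "dup.csv")
  utils::write.csv(feat, fp_dup, row.names = FALSE)
  expect_error(load_feature_table(fp_dup, paths$meta), "duplicate subject id")

  # non-binary label
  feat2 <- utils::read.csv(paths$features)
  feat2$label[1] <- 2
  fp_lab <- file.path(dir, "lab.csv")
  utils::write.csv(feat2, fp_lab, row.names = FALSE)
  expect_error(load_feature_table(fp_lab, paths$meta), "binary")

  # missing cell (complete-case design)
  feat3 <- utils::read.csv(paths$features)
  feat3$f2[3] <- NA
  fp_na <- file.path(dir, "na.csv")
  utils::write.csv(feat3, fp_na, row.names = FALSE)
  expect_error(load_feature_table(fp_na, paths$meta), "missing cell")
})

test_that("write/read round-trip reproduces the matrix bit-exactly", {
  set.seed(42)
  X <- matrix(signif(rnorm(60) * 10^sample(-3:3, 60, TRUE), 12), 10, 6)
  colnames(X) <- paste0("f", 1:6)
  ds <- cohort_dataset(X, setNames(rep(c("CAM", "MRI"), each = 3),
                                   colnames(X)),
                       labels = rep(c(0L, 1L), 5))
  dir <- withr::local_tempdir()
  fp <- file.path(dir, "feat.csv"); mp <- file.path(dir, "meta.csv")
  write_feature_table(ds, fp, mp)
  back <- load_feature_table(fp, mp)
  expect_identical(unname(back$features), unname(X))
  expect_identical(back$labels, ds$labels)
})

test_that("cohort invariants reject inconsistent time-to-progression", {
  X <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, paste0("f", 1:3)))
  sm <- setNames(rep("CAM", 3), paste0("f", 1:3))
  y <- c(0L, 1L, 1L, 0L)
  # valid: times on the visit grid for progressors only
  ds <- cohort_dataset(X, sm, labels = y,
                       time_to_progression = c(NA, 18, 36, NA))
  expect_equal(ds$time_to_progression, c(NA, 18, 36, NA))
  # a time for a non-progressor is fatal
  expect_error(cohort_dataset(X, sm, labels = y,
                              time_to_progression = c(12, 18, 36, NA)),
               "non-progressors")
  # off-grid time is fatal
  expect_error(cohort_dataset(X, sm, labels = y,
                              time_to_progression = c(NA, 17, 36, NA)),
               "visit grid")
})

test_that("standardize uses reference statistics only", {
  # reference rows (1,10) and (3,20): means (2,15), SDs (sqrt(2), 5*sqrt(2));
  # the held-out row (2,15) lands exactly on the reference means -> z = (0,0)
  X <- rbind(c(1, 10), c(3, 20), c(2, 15))
  colnames(X) <- c("f1", "f2")
  ds <- cohort_dataset(X, setNames(c("CAM", "CAM"), c("f1", "f2")))
  std <- standardize(ds, reference_rows = 1:2, skew_transform = FALSE)
  expect_equal(unname(std$features[3, ]), c(0, 0))
  # reference rows have mean 0 / sd 1 by definition
  expect_equal(unname(colMeans(std$features[1:2, ])), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(std$features[1:2, ], 2, sd)), c(1, 1),
               tolerance = 1e-10)

  # no peeking: perturbing held-out rows never changes the transform
  X2 <- X; X2[3, ] <- c(1e6, -1e6)
  ds2 <- cohort_dataset(X2, setNames(c("CAM", "CAM"), c("f1", "f2")))
  std2 <- standardize(ds2, reference_rows = 1:2, skew_transform = FALSE)
  expect_identical(attr(std, "transform"), attr(std2, "transform"))

  # a constant feature across reference rows maps to 0 with a warning
  X3 <- cbind(c(5, 5, 5), c(1, 2, 3))
  colnames(X3) <- c("c1", "c2")
  ds3 <- cohort_dataset(X3, setNames(c("CRF", "CRF"), c("c1", "c2")))
  expect_warning(std3 <- standardize(ds3, 1:3), "zero-variance")
  expect_equal(unname(std3$features[, 1]), c(0, 0, 0))

  expect_error(standardize(ds, integer(0)), "non-empty")
})

test_that("transform parameters reapply identically to held-out data", {
  set.seed(7)
  X <- matrix(rexp(50)^2, 10, 5, dimnames = list(NULL, paste0("f", 1:5)))
  ds <- cohort_dataset(X, setNames(rep("PPM", 5), paste0("f", 1:5)))
  std <- standardize(ds, 1:6)
  tr <- attr(std, "transform")
  again <- apply_standardization(tr, ds)
  expect_equal(again$features, std$features)
})

test_that("stratified folds balance both classes to within one subject", {
  # 10 + 10 at k = 10: every fold gets exactly one of each class
  fa <- split_stratified_folds(rep(c(0, 1), each = 10), k = 10, seed = 3)
  tab <- table(fa$assignment[1, ], rep(c(0, 1), each = 10))
  expect_true(all(tab == 1))

  # the study's class sizes: 139 progressors / 120 non-progressors
  y <- c(rep(1, 139), rep(0, 120))
  fa2 <- split_stratified_folds(y, k = 10, r = 2, seed = 11)
  for (rep_i in 1:2) {
    tab2 <- table(fa2$assignment[rep_i, ], y)
    expect_true(all(tab2[, "1"] %in% c(13, 14)))
    expect_true(all(tab2[, "0"] == 12))
  }
  # distinct repetitions use distinct permutations
  expect_false(identical(fa2$assignment[1, ], fa2$assignment[2, ]))

  # identical seed -> identical assignment
  fa3 <- split_stratified_folds(y, k = 10, r = 2, seed = 11)
  expect_identical(fa2$assignment, fa3$assignment)

  expect_error(split_stratified_folds(c(rep(0, 3), rep(1, 20)), k = 5),
               "fewer than k")
})

test_that("stratification invariant holds across random configurations", {
  set.seed(2024)
  for (i in 1:1000) {
    k <- sample(2:10, 1)
    n1 <- sample(k:60, 1); n0 <- sample(k:60, 1)
    y <- sample(c(rep(0, n0), rep(1, n1)))
    fa <- split_stratified_folds(y, k = k, seed = sample.int(1e6, 1))
    f <- fa$assignment[1, ]
    expect_true(all(tabulate(f, k) > 0) || n0 + n1 < k)
    for (cl in c(0, 1)) {
      counts <- tabulate(f[y == cl], k)
      share <- sum(y == cl) / k
      expect_true(all(abs(counts - share) < 1))
    }
  }
})
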