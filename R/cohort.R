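#' Multi-source cohort container
#'
#' A `cohort_dataset` bundles a subjects-by-features matrix with the metadata
#' the prognostic pipeline needs: a map from every feature to one of the four
#' data sources (CRF: clinical risk factors, CAM: cognitive/functional
#' assessments, MRI: morphometric measures, PPM: plasma proteomic markers),
#' an optional binary progression label (0 = non-progressive MCI, 1 =
#' progressive MCI), optional time to progression in months for progressors
#' (restricted to the follow-up visit grid 6/12/18/24/36), and an optional
#' table of stratification covariates.
#'
#' The container is strict by design: no missing cells are allowed (the study
#' design is complete-case; impute upstream if you must), feature names must
#' be unique and fully source-mapped, and labels may only be 0/1.
#'
#' @param features numeric matrix, subjects in rows, features in columns.
#' @param source_map named character vector mapping each feature name to one
#'   of `"CRF"`, `"CAM"`, `"MRI"`, `"PPM"`.
#' @param subject_ids character vector of unique subject identifiers;
#'   defaults to rownames of `features` or `S1..Sn`.
#' @param labels optional integer/numeric vector of 0/1 outcomes (1 =
#'   progressor).
#' @param time_to_progression optional numeric vector, `NA` for
#'   non-progressors, months on the visit grid for progressors.
#' @param strata optional data.frame of covariates, one row per subject.
#' @return an object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(features, source_map, subject_ids = NULL,
                           labels = NULL, time_to_progression = NULL,
                           strata = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  p <- ncol(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(p))
  feature_names <- colnames(features)
  if (anyDuplicated(feature_names))
    stopf("duplicate feature names: %s",
          paste(unique(feature_names[duplicated(feature_names)]), collapse = ", "))
  if (is.null(subject_ids)) {
    subject_ids <- rownames(features) %||% paste0("S", seq_len(n))
  }
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != n)
    stopf("subject_ids length (%d) != number of rows (%d)", length(subject_ids), n)
  if (anyDuplicated(subject_ids))
    stopf("duplicate subject id: %s",
          subject_ids[duplicated(subject_ids)][1])
  if (anyNA(features))
    stopf("feature matrix contains missing values (complete-case design; no imputation)")

  missing_map <- setdiff(feature_names, names(source_map))
  if (length(missing_map))
    stopf("feature(s) not mapped to a source: %s", paste(missing_map, collapse = ", "))
  source_map <- source_map[feature_names]
  bad_src <- setdiff(unique(source_map), SOURCES)
  if (length(bad_src))
    stopf("unknown source(s): %s (must be one of %s)",
          paste(bad_src, collapse = ", "), paste(SOURCES, collapse = ", "))

  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) stopf("labels length != number of subjects")
    if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
      stopf("labels must be binary 0 (N-MCI) / 1 (P-MCI)")
  }
  if (!is.null(time_to_progression)) {
    ttp <- as.numeric(time_to_progression)
    if (length(ttp) != n) stopf("time_to_progression length != number of subjects")
    if (is.null(labels)) stopf("time_to_progression requires labels")
    if (any(!is.na(ttp[labels == 0L])))
      stopf("time_to_progression must be NA for non-progressors")
    tv <- ttp[labels == 1L]
    if (any(!is.na(tv) & !(tv %in% VISIT_GRID)))
      stopf("progression times must lie on the visit grid {%s} months",
            paste(VISIT_GRID, collapse = ","))
    time_to_progression <- ttp
  }
  if (!is.null(strata)) {
    strata <- as.data.frame(strata)
    if (nrow(strata) != n) stopf("strata must have one row per subject")
  }

  structure(list(subject_ids = subject_ids,
                 features = features,
                 feature_names = feature_names,
                 source_map = source_map,
                 labels = labels,
                 time_to_progression = time_to_progression,
                 strata = strata),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d subjects x %d features\n",
              nrow(x$features), ncol(x$features)))
  tab <- table(factor(x$source_map, levels = SOURCES))
  cat("  sources:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  if (is.null(x$labels)) {
    cat("  unlabeled\n")
  } else {
    cat(sprintf("  labels: %d N-MCI / %d P-MCI\n",
                sum(x$labels == 0L), sum(x$labels == 1L)))
  }
  if (!is.null(x$time_to_progression))
    cat(sprintf("  progression times: median %g months\n",
                stats::median(x$time_to_progression, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.cohort_dataset <- function(x) dim(x$features)

# row/column subsetting that keeps all metadata aligned
subset_cohort <- function(dataset, rows = NULL, cols = NULL) {
  rows <- rows %||% seq_len(nrow(dataset$features))
  cols <- cols %||% seq_len(ncol(dataset$features))
  cohort_dataset(
    features = dataset$features[rows, cols, drop = FALSE],
    source_map = dataset$source_map[cols],
    subject_ids = dataset$subject_ids[rows],
    labels = if (!is.null(dataset$labels)) dataset$labels[rows],
    time_to_progression = if (!is.null(dataset$time_to_progression))
      dataset$time_to_progression[rows],
    strata = if (!is.null(dataset$strata)) dataset$strata[rows, , drop = FALSE]
  )
}

#' Read a cohort from delimited text files
#'
#' The feature table is CSV/TSV with a header row; the first column holds the
#' subject id, the reserved columns `label` and `time_months` (optional) hold
#' the binary outcome and the progression time, and every remaining column is
#' a feature. The metadata file is a CSV with columns `feature,source`
#' covering every feature. An optional strata CSV (first column = subject id)
#' supplies covariates, matched by id.
#'
#' @param feature_path path to the feature table (CSV, or TSV if the name
#'   ends in `.tsv`).
#' @param metadata_path path to the feature-to-source metadata CSV.
#' @param strata_path optional path to a covariate CSV keyed by subject id.
#' @return a validated [cohort_dataset()]; row order of the feature table is
#'   preserved.
#' @export
load_feature_table <- function(feature_path, metadata_path, strata_path = NULL) {
  sep <- if (grepl("\\.tsv$", feature_path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(feature_path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stopf("feature table needs an id column plus features")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stopf("duplicate subject id: %s", ids[duplicated(ids)][1])
  tab <- tab[, -1, drop = FALSE]

  labels <- NULL
  if ("label" %in% names(tab)) {
    labels <- tab[["label"]]
    if (anyNA(labels) || !all(labels %in% c(0, 1)))
      stopf("non-binary value in 'label' column")
    tab[["label"]] <- NULL
  }
  ttp <- NULL
  if ("time_months" %in% names(tab)) {
    ttp <- as.numeric(tab[["time_months"]])
    tab[["time_months"]] <- NULL
  }
  feat <- as.matrix(tab)
  if (!is.numeric(feat)) stopf("non-numeric feature cell(s) in %s", feature_path)
  if (anyNA(feat)) {
    bad <- which(is.na(feat), arr.ind = TRUE)[1, ]
    stopf("missing cell at subject '%s', feature '%s' (complete-case design)",
          ids[bad[1]], colnames(feat)[bad[2]])
  }
  rownames(feat) <- ids

  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  if (!all(c("feature", "source") %in% names(meta)))
    stopf("metadata must have columns 'feature' and 'source'")
  source_map <- stats::setNames(meta$source, meta$feature)

  strata <- NULL
  if (!is.null(strata_path)) {
    st <- utils::read.csv(strata_path, stringsAsFactors = FALSE)
    m <- match(ids, as.character(st[[1]]))
    if (anyNA(m)) stopf("strata file missing subject id: %s", ids[is.na(m)][1])
    strata <- st[m, -1, drop = FALSE]
    rownames(strata) <- NULL
  }

  cohort_dataset(feat, source_map, subject_ids = ids, labels = labels,
                 time_to_progression = ttp, strata = strata)
}

#' Write a cohort back to the delimited-text layout
#'
#' Inverse of [load_feature_table()]; numeric cells are written with 15
#' significant digits so values of up to 12 significant decimal digits
#' round-trip bit-exactly.
#'
#' @param dataset a [cohort_dataset()].
#' @param feature_path,metadata_path,strata_path output paths
#'   (`strata_path` only used when strata are present).
#' @return invisibly, `feature_path`.
#' @export
write_feature_table <- function(dataset, feature_path, metadata_path,
                                strata_path = NULL) {
  df <- as.data.frame(apply(dataset$features, 2, function(col)
    format(col, digits = 15, trim = TRUE, scientific = FALSE)),
    check.names = FALSE, stringsAsFactors = FALSE)
  out <- cbind(subject_id = dataset$subject_ids, df)
  if (!is.null(dataset$labels)) out$label <- dataset$labels
  if (!is.null(dataset$time_to_progression))
    out$time_months <- dataset$time_to_progression
  utils::write.csv(out, feature_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(feature = dataset$feature_names,
                              source = unname(dataset$source_map)),
                   metadata_path, row.names = FALSE, quote = FALSE)
  if (!is.null(strata_path) && !is.null(dataset$strata))
    utils::write.csv(cbind(subject_id = dataset$subject_ids, dataset$strata),
                     strata_path, row.names = FALSE, quote = FALSE)
  invisible(feature_path)
}

#' Standardize features using statistics from a reference (training) set
#'
#' Computes per-feature location/scale from `reference_rows` ONLY and applies
#' the transform to every row, so held-out subjects are scored without
#' peeking. Features that are heavily right-skewed on the reference rows
#' (skewness > `skew_threshold`) and non-negative are passed through `log1p`
#' first (proteomic analyte concentrations are classically log-normal);
#' zero-variance features are mapped to 0 with a warning.
#'
#' @param dataset a [cohort_dataset()].
#' @param reference_rows integer indices of the rows whose statistics define
#'   the transform (the training/development subjects).
#' @param skew_transform logical; enable the conditional `log1p`
#'   pre-transform (default `TRUE`).
#' @param skew_threshold skewness above which the pre-transform fires.
#' @return the transformed dataset, with the transform parameters attached as
#'   `attr(, "transform")` (a list with `center`, `scale`, `log1p`) for reuse
#'   via [apply_standardization()].
#' @export
standardize <- function(dataset, reference_rows,
                        skew_transform = TRUE, skew_threshold = 2) {
  if (length(reference_rows) == 0) stopf("reference_rows must be non-empty")
  X <- dataset$features
  ref <- X[reference_rows, , drop = FALSE]

  use_log <- rep(FALSE, ncol(X))
  if (skew_transform) {
    sk <- apply(ref, 2, sample_skewness)
    nonneg <- apply(ref, 2, function(v) min(v) >= 0)
    use_log <- sk > skew_threshold & nonneg
  }
  if (any(use_log)) {
    X[, use_log] <- log1p(X[, use_log, drop = FALSE])
    ref <- X[reference_rows, , drop = FALSE]
  }
  center <- colMeans(ref)
  scale_ <- apply(ref, 2, stats::sd)
  degenerate <- !is.finite(scale_) | scale_ == 0
  if (any(degenerate)) {
    warnf("%d zero-variance feature(s) on the reference rows mapped to 0",
          sum(degenerate))
    scale_[degenerate] <- 1
    center[degenerate] <- 0
  }
  Z <- sweep(sweep(X, 2, center, "-"), 2, scale_, "/")
  Z[, degenerate] <- 0

  tr <- list(center = center, scale = scale_, log1p = use_log,
             degenerate = degenerate)
  out <- dataset
  out$features <- Z
  attr(out, "transform") <- tr
  out
}

#' Apply a previously fitted standardization transform
#'
#' @param transform the `transform` attribute produced by [standardize()].
#' @param dataset a [cohort_dataset()] with the same features.
#' @return the transformed dataset.
#' @export
apply_standardization <- function(transform, dataset) {
  X <- dataset$features
  if (any(transform$log1p))
    X[, transform$log1p] <- log1p(X[, transform$log1p, drop = FALSE])
  Z <- sweep(sweep(X, 2, transform$center, "-"), 2, transform$scale, "/")
  Z[, transform$degenerate] <- 0
  out <- dataset
  out$features <- Z
  out
}

#' Stratified repeated k-fold assignment
#'
#' Assigns every subject to exactly one of `k` folds per repetition, keeping
#' each fold's class composition within one subject of the proportional
#' share. Distinct repetitions use distinct random permutations; the whole
#' assignment is deterministic given `seed`.
#'
#' @param labels binary 0/1 vector.
#' @param k folds per repetition.
#' @param r number of repetitions.
#' @param seed integer seed.
#' @return object of class `fold_assignment`: list with `k`, `r`, `seed`, and
#'   `assignment`, an `r` x `n` integer matrix of fold indices in `1..k`.
#' @export
split_stratified_folds <- function(labels, k, r = 1, seed = 1) {
  labels <- as.integer(labels)
  n <- length(labels)
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts < k))
    stopf("class %s has %d members, fewer than k = %d folds",
          names(counts)[counts < k][1], min(counts), k)
  assignment <- matrix(NA_integer_, nrow = r, ncol = n)
  with_seed(seed, {
    for (rep_i in seq_len(r)) {
      for (cl in c(0L, 1L)) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        assignment[rep_i, idx] <- rep_len(sample.int(k), length(idx))
      }
    }
  })
  structure(list(k = k, r = r, seed = as.integer(seed), assignment = assignment),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<fold_assignment> %d-fold x %d repetitions, %d subjects, seed %d\n",
              x$k, x$r, ncol(x$assignment), x$seed))
  invisible(x)
}
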