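#' Specification of one model in the prognostic model zoo
#'
#' A model is a data-source restriction plus a kernel preset plus the
#' candidate grid for the number of JMI-ranked features, evaluated under
#' nested cross-validation. Single-source models (CRF/CAM/MRI/PPM) use one
#' linear kernel on their source; CONCAT uses one linear kernel over all
#' sources considered jointly; the MKL presets build one kernel per source
#' (plus a global one for MKL-Gaussian) over the selected features.
#'
#' @param name model label; when it matches a preset name the preset (and,
#'   for single-source presets, the source restriction) is derived from it.
#' @param preset kernel preset, see [kernel_preset()].
#' @param sources sources whose features the model may use (default: all
#'   for multi-source presets, the source itself for single-source ones).
#' @param feature_grid ascending candidate numbers of features for the
#'   inner-loop wrapper stage (default 1:50).
#' @param control [pmkl_control()] for the final (outer) fits.
#' @param inner_control [pmkl_control()] for the inner-loop fits; defaults
#'   to a shortened chain so the wrapper grid stays tractable, while every
#'   final fit always uses `control`.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(name = "CONCAT", preset = name, sources = NULL,
                       feature_grid = 1:50, control = pmkl_control(),
                       inner_control = NULL) {
  feature_grid <- sort(unique(as.integer(feature_grid)))
  if (!length(feature_grid)) stopf("feature_grid must be nonempty")
  if (preset %in% SOURCES && is.null(sources)) sources <- preset
  sources <- sources %||% SOURCES
  if (is.null(inner_control))
    inner_control <- pmkl_control(n_iter = 300, burn_in = 100,
                                  n_mc_probit = 200, seed = control$seed)
  structure(list(name = name, preset = preset, sources = sources,
                 feature_grid = feature_grid, control = control,
                 inner_control = inner_control),
            class = "model_spec")
}

# build the preset's kernel specs for a given selected-feature source map
zoo_kernels <- function(preset, source_map) {
  present <- intersect(SOURCES, unique(source_map))
  kernel_preset(preset, sources_present = present)
}

# fit + predict one development/test split given already-chosen features
fit_and_predict <- function(dataset, dev, test, sel, spec, control, seed) {
  dev_ds <- subset_cohort(dataset, dev, sel)
  std_dev <- standardize(dev_ds, seq_along(dev))
  tr <- attr(std_dev, "transform")
  test_std <- apply_standardization(tr, subset_cohort(dataset, test, sel))
  kspecs <- zoo_kernels(spec$preset, std_dev$source_map)
  ctl <- control; ctl$seed <- seed
  fit <- pmkl(std_dev$features, std_dev$labels, kernels = kspecs,
              source_map = std_dev$source_map, control = ctl)
  pred <- predict(fit, test_std$features,
                  n_mc = control$n_mc_probit,
                  seed = child_seed(seed, 97L))
  list(fit = fit, pred = pred)
}

#' Nested stratified repeated cross-validation of one model
#'
#' The outer loop holds out each fold in turn as the test set; within the
#' remaining development set an inner stratified k-fold loop ranks features
#' by JMI on each inner training set and scores every candidate feature
#' count on the inner validation folds (the wrapper stage). The feature
#' count maximizing mean inner-validation balanced accuracy — smallest such
#' count on ties, favouring parsimony — becomes `D_optimal` for that outer
#' fold; the final model is trained on the full development set with the
#' top `D_optimal` development-ranked features and evaluated once on the
#' held-out test fold. Standardization statistics, JMI rankings, kernel
#' bandwidths and posterior fits are all computed strictly within
#' development data; test subjects enter only at the final prediction.
#'
#' @param dataset a labelled [cohort_dataset()].
#' @param spec a [model_spec()].
#' @param k folds (outer and inner loops; default 10).
#' @param r repetitions with different stratified partitions (default 10).
#' @param seed integer seed governing partitions and inference.
#' @param folds optional pre-computed [split_stratified_folds()] assignment
#'   (shared across specs for paired model comparisons).
#' @return object of class `pmkl_cv`: `estimates` (one row per
#'   repetition x fold: V-BAR, T-BAR, Sn, Sp, AUC, `d_optimal`),
#'   `oof` (out-of-fold predictions, one row per subject per repetition),
#'   `selection_freq` (per-feature selection frequency over the k*r final
#'   models), `calibration_by_rep`, pooled `calibration`, the `spec`, and
#'   the fold assignment.
#' @export
run_nested_cv <- function(dataset, spec, k = 10, r = 10, seed = 1,
                          folds = NULL) {
  if (is.null(dataset$labels)) stopf("nested CV needs a labelled dataset")
  keep <- which(dataset$source_map %in% spec$sources)
  if (!length(keep)) stopf("no features from sources %s",
                           paste(spec$sources, collapse = ","))
  ds <- subset_cohort(dataset, cols = keep)
  y <- ds$labels
  n <- length(y)
  folds <- folds %||% split_stratified_folds(y, k = k, r = r, seed = seed)
  stopifnot(folds$k == k, folds$r == r, ncol(folds$assignment) == n)
  grid <- spec$feature_grid[spec$feature_grid <= ncol(ds$features)]
  if (!length(grid)) stopf("feature_grid entirely above n_features")

  est <- list(); oof <- list(); selections <- list()
  for (rep_i in seq_len(r)) {
    fold_of <- folds$assignment[rep_i, ]
    oof_rep <- data.frame(subject = ds$subject_ids, label = y,
                          prob_pos = NA_real_, predicted = NA_integer_,
                          confidence = NA_real_, rep = rep_i,
                          fold = fold_of)
    for (f in seq_len(k)) {
      test <- which(fold_of == f)
      dev <- which(fold_of != f)
      stopifnot(length(intersect(dev, test)) == 0)   # leakage guard
      fseed <- child_seed(seed, rep_i * 1000L + f)

      # wrapper stage: inner CV over the candidate feature counts
      vbar <- NA_real_
      if (length(grid) > 1) {
        y_dev <- y[dev]
        inner <- split_stratified_folds(y_dev, k = k, r = 1,
                                        seed = child_seed(fseed, 5L))
        inner_of <- inner$assignment[1, ]
        bar_mat <- matrix(NA_real_, k, length(grid))
        for (g in seq_len(k)) {
          itr <- dev[inner_of != g]
          ival <- dev[inner_of == g]
          itr_ds <- subset_cohort(ds, itr)
          std_itr <- standardize(itr_ds, seq_along(itr))
          rk <- jmi_rank(std_itr, max_features = max(grid))
          for (d_i in seq_along(grid)) {
            sel <- rk$selected[seq_len(grid[d_i])]
            fp <- fit_and_predict(ds, itr, ival, sel, spec,
                                  spec$inner_control,
                                  child_seed(fseed, 10L + g))
            mets <- classification_metrics(y[ival],
                                           as.integer(fp$pred$label))
            bar_mat[g, d_i] <- mets$bar
          }
        }
        mean_bar <- colMeans(bar_mat, na.rm = TRUE)
        best <- max(mean_bar)
        d_opt <- grid[which(mean_bar == best)[1]]   # smallest count on ties
        vbar <- best
      } else d_opt <- grid[1]

      # final model on the development set
      dev_ds <- subset_cohort(ds, dev)
      std_dev <- standardize(dev_ds, seq_along(dev))
      rk_dev <- jmi_rank(std_dev, max_features = max(grid))
      sel <- rk_dev$selected[seq_len(d_opt)]
      fp <- fit_and_predict(ds, dev, test, sel, spec, spec$control,
                            child_seed(fseed, 1L))
      prob_pos <- fp$pred$prob[, 2]
      pred_lab <- as.integer(fp$pred$label)
      mets <- classification_metrics(y[test], pred_lab)
      auc <- if (length(unique(y[test])) == 2)
        roc_auc(y[test], prob_pos) else NA_real_

      est[[length(est) + 1L]] <- data.frame(
        rep = rep_i, fold = f, n_test = length(test),
        vbar = vbar, tbar = mets$bar, sn = mets$sn, sp = mets$sp,
        auc = auc, d_optimal = d_opt)
      oof_rep$prob_pos[test] <- prob_pos
      oof_rep$predicted[test] <- pred_lab
      oof_rep$confidence[test] <- fp$pred$confidence
      selections[[length(selections) + 1L]] <- keep[sel]
    }
    oof[[rep_i]] <- oof_rep
  }

  estimates <- do.call(rbind, est)
  oof_all <- do.call(rbind, oof)
  calib_rep <- lapply(oof, function(d) calibration_ccc(d$prob_pos, d$label))
  calib_pooled <- calibration_ccc(oof_all$prob_pos, oof_all$label)
  sel_freq <- selection_frequency(selections, ncol(dataset$features))
  names(sel_freq) <- dataset$feature_names

  structure(list(estimates = estimates, oof = oof_all,
                 selection_freq = sel_freq,
                 calibration_by_rep = calib_rep,
                 calibration = calib_pooled,
                 spec = spec, folds = folds, k = k, r = r, seed = seed),
            class = "pmkl_cv")
}

#' @export
print.pmkl_cv <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("<pmkl_cv> model '%s': %d-fold x %d repetitions (%d estimates)\n",
              x$spec$name, x$k, x$r, nrow(e)))
  cat(sprintf("  T-BAR %.1f%% +/- %.1f | Sn %.1f%% | Sp %.1f%% | AUC %.2f\n",
              100 * mean(e$tbar, na.rm = TRUE), 100 * stats::sd(e$tbar),
              100 * mean(e$sn, na.rm = TRUE), 100 * mean(e$sp, na.rm = TRUE),
              mean(e$auc, na.rm = TRUE)))
  if (!all(is.na(e$vbar)))
    cat(sprintf("  V-BAR %.1f%% | D_optimal median %g\n",
                100 * mean(e$vbar, na.rm = TRUE),
                stats::median(e$d_optimal)))
  invisible(x)
}

#' Summarize a nested-CV run into one performance row
#'
#' @param object a [run_nested_cv()] result.
#' @param ... unused.
#' @return data.frame with mean +/- SD of V-BAR, T-BAR, Sn, Sp, AUC over the
#'   k*r estimates, per-repetition CCC mean +/- SD (and the pooled CCC), and
#'   median +/- MAD of `D_optimal`.
#' @export
summary.pmkl_cv <- function(object, ...) {
  e <- object$estimates
  ccc_rep <- vapply(object$calibration_by_rep, function(cr)
    if (cr$available) cr$ccc else NA_real_, numeric(1))
  data.frame(
    model = object$spec$name,
    vbar_mean = mean(e$vbar, na.rm = TRUE), vbar_sd = stats::sd(e$vbar),
    tbar_mean = mean(e$tbar, na.rm = TRUE), tbar_sd = stats::sd(e$tbar),
    sn_mean = mean(e$sn, na.rm = TRUE), sn_sd = stats::sd(e$sn),
    sp_mean = mean(e$sp, na.rm = TRUE), sp_sd = stats::sd(e$sp),
    auc_mean = mean(e$auc, na.rm = TRUE), auc_sd = stats::sd(e$auc),
    ccc_mean = mean(ccc_rep, na.rm = TRUE),
    ccc_sd = stats::sd(ccc_rep[!is.na(ccc_rep)]),
    ccc_pooled = if (object$calibration$available)
      object$calibration$ccc else NA_real_,
    d_optimal_median = stats::median(e$d_optimal),
    d_optimal_mad = stats::mad(e$d_optimal, constant = 1),
    row.names = NULL)
}

#' Run and compare a zoo of model specifications
#'
#' Every spec is evaluated by [run_nested_cv()] on the same stratified fold
#' assignment, so per-fold performance estimates are paired across models;
#' pairwise differences in test balanced accuracy are tested with the
#' corrected repeated-CV t-test, and per-repetition calibration (CCC)
#' differences with an ordinary paired t-test across repetitions (only r
#' calibration values exist per model, one per repetition).
#'
#' @param dataset a labelled [cohort_dataset()].
#' @param specs list of [model_spec()]s.
#' @param k,r,seed as in [run_nested_cv()].
#' @return object of class `pmkl_zoo`: `summary` (one row per spec),
#'   `comparisons` (pairwise t/p for T-BAR and CCC), and the full `runs`.
#' @export
run_model_zoo <- function(dataset, specs, k = 10, r = 10, seed = 1) {
  if (!length(specs)) stopf("need at least one model spec")
  if (inherits(specs, "model_spec")) specs <- list(specs)
  folds <- split_stratified_folds(dataset$labels, k = k, r = r, seed = seed)
  runs <- lapply(specs, function(sp)
    run_nested_cv(dataset, sp, k = k, r = r, seed = seed, folds = folds))
  names(runs) <- vapply(specs, `[[`, "", "name")
  summ <- do.call(rbind, lapply(runs, summary))

  comparisons <- NULL
  if (length(runs) > 1) {
    pairs <- utils::combn(length(runs), 2)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      da <- runs[[a]]$estimates$tbar - runs[[b]]$estimates$tbar
      tt <- corrected_cv_ttest(da, k = k, r = r)
      ca <- vapply(runs[[a]]$calibration_by_rep,
                   function(cr) if (cr$available) cr$ccc else NA_real_,
                   numeric(1))
      cb <- vapply(runs[[b]]$calibration_by_rep,
                   function(cr) if (cr$available) cr$ccc else NA_real_,
                   numeric(1))
      cd <- ca - cb
      ccc_ok <- sum(!is.na(cd)) >= 2 && stats::sd(cd, na.rm = TRUE) > 0
      ct <- if (ccc_ok) stats::t.test(cd) else NULL
      data.frame(model_a = names(runs)[a], model_b = names(runs)[b],
                 tbar_t = tt$t, tbar_p = tt$p, tbar_df = tt$df,
                 ccc_t = if (ccc_ok) unname(ct$statistic) else NA_real_,
                 ccc_p = if (ccc_ok) ct$p.value else
                   if (all(!is.na(cd)) && all(cd == 0)) 1 else NA_real_)
    }))
  }
  structure(list(summary = summ, comparisons = comparisons, runs = runs,
                 k = k, r = r, seed = seed),
            class = "pmkl_zoo")
}

#' @export
print.pmkl_zoo <- function(x, ...) {
  cat(sprintf("<pmkl_zoo> %d models, %d-fold x %d repetitions\n",
              nrow(x$summary), x$k, x$r))
  s <- x$summary
  print(data.frame(model = s$model,
                   `T-BAR` = sprintf("%.1f +/- %.1f", 100 * s$tbar_mean,
                                     100 * s$tbar_sd),
                   Sn = sprintf("%.1f", 100 * s$sn_mean),
                   Sp = sprintf("%.1f", 100 * s$sp_mean),
                   AUC = sprintf("%.2f", s$auc_mean),
                   D_opt = sprintf("%g +/- %g", s$d_optimal_median,
                                   s$d_optimal_mad),
                   check.names = FALSE), row.names = FALSE)
  invisible(x)
}
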