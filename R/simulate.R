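#' Configuration for the synthetic multi-source cohort generator
#'
#' The generator emulates the structure of a two-group MCI cohort: four
#' feature sources of realistic dimensionality (16 clinical risk factors, 170
#' cognitive/functional scores, 452 MRI morphometric measures, 149 plasma
#' proteomic analytes), a small planted set of informative features carrying
#' standardized mean shifts between non-progressors and progressors,
#' equicorrelated within-source noise, binary covariates with group-specific
#' prevalences (an APOE-e4-like carrier flag by default), and progression
#' times on the follow-up visit grid {6, 12, 18, 24, 36} months with median
#' 18.
#'
#' @param n_neg,n_pos group sizes (default 120 non-progressors, 139
#'   progressors).
#' @param features_per_source named counts per source.
#' @param informative_per_source named counts of planted informative features.
#' @param effect_size standardized mean difference d on each informative
#'   feature; either a scalar or a named per-source vector.
#' @param within_source_correlation equicorrelation rho in [0, 1) shared by
#'   features of a source.
#' @param binary_covariates data.frame with columns `name`,
#'   `prevalence_neg`, `prevalence_pos`; each becomes a 0/1 feature (source
#'   CRF) and a stratum column.
#' @param time_probs probabilities over the visit grid {6,12,18,24,36} for
#'   progressors' time to progression.
#' @param time_coupling strength in [0, 1) of the negative association
#'   between latent risk and time to progression (0 = independent).
#' @param seed integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_neg = 120, n_pos = 139,
                       features_per_source = c(CRF = 16, CAM = 170,
                                               MRI = 452, PPM = 149),
                       informative_per_source = c(CRF = 1, CAM = 6,
                                                  MRI = 4, PPM = 0),
                       effect_size = 0.8,
                       within_source_correlation = 0.3,
                       binary_covariates = data.frame(
                         name = "apoe4_carrier",
                         prevalence_neg = 0.417,
                         prevalence_pos = 0.662),
                       time_probs = c(`6` = 0.10, `12` = 0.25, `18` = 0.25,
                                      `24` = 0.20, `36` = 0.20),
                       time_coupling = 0,
                       seed = 1) {
  stopifnot(n_neg > 0, n_pos > 0)
  if (is.null(names(features_per_source)) ||
      !all(names(features_per_source) %in% SOURCES))
    stopf("features_per_source must be named with sources %s",
          paste(SOURCES, collapse = ","))
  informative_per_source <-
    informative_per_source[names(features_per_source)]
  informative_per_source[is.na(informative_per_source)] <- 0
  names(informative_per_source) <- names(features_per_source)
  if (any(informative_per_source > features_per_source))
    stopf("informative_per_source exceeds features_per_source")
  rho <- within_source_correlation
  if (rho < 0 || rho >= 1)
    stopf("within_source_correlation must be in [0, 1)")
  if (length(effect_size) == 1) {
    effect_size <- stats::setNames(rep(effect_size, length(features_per_source)),
                                   names(features_per_source))
  } else {
    effect_size <- effect_size[names(features_per_source)]
    effect_size[is.na(effect_size)] <- 0
  }
  if (!is.null(binary_covariates)) {
    stopifnot(all(c("name", "prevalence_neg", "prevalence_pos") %in%
                    names(binary_covariates)),
              all(binary_covariates$prevalence_neg >= 0),
              all(binary_covariates$prevalence_neg <= 1),
              all(binary_covariates$prevalence_pos >= 0),
              all(binary_covariates$prevalence_pos <= 1))
  }
  time_probs <- time_probs / sum(time_probs)
  if (length(time_probs) != length(VISIT_GRID))
    stopf("time_probs must have one entry per visit (%d)", length(VISIT_GRID))
  if (time_coupling < 0 || time_coupling >= 1)
    stopf("time_coupling must be in [0, 1)")
  structure(list(n_neg = n_neg, n_pos = n_pos,
                 features_per_source = features_per_source,
                 informative_per_source = informative_per_source,
                 effect_size = effect_size,
                 within_source_correlation = rho,
                 binary_covariates = binary_covariates,
                 time_probs = time_probs,
                 time_coupling = time_coupling,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic labelled multi-source cohort
#'
#' Continuous features are drawn per source from an equicorrelated
#' multivariate normal (unit marginal variance) via the one-factor
#' construction `sqrt(rho) * g + sqrt(1 - rho) * e`; the progressor group's
#' mean is shifted by `d` (standardized units) on the planted informative
#' features. Binary covariates are drawn Bernoulli with group-specific
#' prevalence and appended both as features (source CRF) and as strata. The
#' per-subject latent risk score is the standardized mean of the subject's
#' informative-feature values (signal direction), and drives the optional
#' risk/time coupling in the progression times.
#'
#' @param config a [sim_config()].
#' @return list with elements `dataset` (a [cohort_dataset()], labels 0/1,
#'   progression times filled in for progressors) and `truth` (planted
#'   informative indices per source, effect sizes, latent risk per subject).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_neg + config$n_pos
    labels <- c(rep(0L, config$n_neg), rep(1L, config$n_pos))
    rho <- config$within_source_correlation

    blocks <- list(); names_all <- character(); src_all <- character()
    info_idx <- list(); effects <- numeric(); offset <- 0L
    for (src in names(config$features_per_source)) {
      p <- config$features_per_source[[src]]
      if (p == 0) next
      g <- rnorm(n)                       # shared within-source factor
      E <- matrix(rnorm(n * p), n, p)
      X <- sqrt(rho) * g + sqrt(1 - rho) * E
      m <- config$informative_per_source[[src]]
      d <- config$effect_size[[src]]
      if (d == 0) m <- 0L          # a zero shift plants no signal
      idx <- integer(0)
      if (m > 0) {
        idx <- seq_len(m)
        X[labels == 1L, idx] <- X[labels == 1L, idx] + d
      }
      nm <- sprintf("%s_%03d", src, seq_len(p))
      blocks[[src]] <- X
      names_all <- c(names_all, nm)
      src_all <- c(src_all, rep(src, p))
      info_idx[[src]] <- idx + offset
      effects <- c(effects, rep(d, m), rep(0, p - m))
      offset <- offset + p
    }
    X <- do.call(cbind, blocks)
    colnames(X) <- names_all
    source_map <- stats::setNames(src_all, names_all)

    # latent risk: standardized projection on the planted signal direction
    info_all <- unlist(info_idx, use.names = FALSE)
    if (length(info_all)) {
      risk <- rowMeans(X[, info_all, drop = FALSE])
      risk <- (risk - mean(risk)) / stats::sd(risk)
    } else {
      risk <- rnorm(n)
    }

    strata <- NULL
    if (!is.null(config$binary_covariates) && nrow(config$binary_covariates)) {
      bc <- config$binary_covariates
      cov_mat <- sapply(seq_len(nrow(bc)), function(i) {
        p_i <- ifelse(labels == 1L, bc$prevalence_pos[i], bc$prevalence_neg[i])
        as.numeric(runif(n) < p_i)
      })
      cov_mat <- matrix(cov_mat, nrow = n)
      colnames(cov_mat) <- bc$name
      X <- cbind(X, cov_mat)
      source_map <- c(source_map, stats::setNames(rep("CRF", nrow(bc)), bc$name))
      effects <- c(effects, rep(0, nrow(bc)))
      strata <- as.data.frame(cov_mat)
    }

    ttp <- simulate_progression_times(config, labels, risk)

    dataset <- cohort_dataset(X, source_map,
                              subject_ids = sprintf("SIM%04d", seq_len(n)),
                              labels = labels, time_to_progression = ttp,
                              strata = strata)
    truth <- list(informative = info_idx,
                  effect_sizes = effects,
                  latent_risk = risk)
    list(dataset = dataset, truth = truth)
  })
}

#' Draw progression times on the visit grid
#'
#' Progressors receive a time in {6, 12, 18, 24, 36} months from the
#' configured distribution (default median 18). With `time_coupling`
#' gamma > 0, times are drawn through a Gaussian copula against the latent
#' risk, making higher-risk subjects stochastically earlier progressors.
#'
#' @param config a [sim_config()].
#' @param labels binary vector.
#' @param latent_risk standardized latent risk, aligned with `labels`.
#' @return numeric vector: months for label-1 subjects, `NA` otherwise.
#' @export
simulate_progression_times <- function(config, labels, latent_risk) {
  stopifnot(length(labels) == length(latent_risk))
  n <- length(labels)
  ttp <- rep(NA_real_, n)
  pos <- which(labels == 1L)
  if (!length(pos)) return(ttp)
  gam <- config$time_coupling
  z <- rnorm(length(pos))
  u <- pnorm(-gam * latent_risk[pos] + sqrt(1 - gam^2) * z)
  cdf <- cumsum(config$time_probs)
  ttp[pos] <- VISIT_GRID[findInterval(u, cdf, left.open = TRUE) + 1L]
  ttp
}
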