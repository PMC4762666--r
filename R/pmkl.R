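#' Control parameters for pMKL posterior inference
#'
#' Inference is Gibbs sampling with the classic auxiliary-variable probit
#' augmentation: each subject carries one latent Gaussian score per class,
#' truncated so the observed class attains the maximum; regression
#' coefficients then have conjugate Gaussian updates. Kernel weights move on
#' the probability simplex by a Metropolis-within-Gibbs step with a
#' Dirichlet proposal.
#'
#' @param n_iter total Gibbs sweeps (default 2000).
#' @param burn_in sweeps discarded before posterior means are accumulated
#'   (default 500; must be `< n_iter`).
#' @param n_mc_probit Monte-Carlo draws realizing the expectation over the
#'   standard-normal mixing variable in the multinomial probit likelihood
#'   (default 1000), with common random numbers across classes.
#' @param prior_shape,prior_rate Gamma hyperprior on the precision `tau` of
#'   the zero-mean Gaussian prior on the regression coefficients
#'   (default 0.01/0.01, weakly informative).
#' @param dirichlet_conc concentration of the Dirichlet prior on the kernel
#'   weights (default 1 = flat on the simplex).
#' @param beta_every update the kernel weights every this many sweeps
#'   (each accepted move refreshes the cached eigendecomposition).
#' @param beta_proposal_conc concentration of the Dirichlet random-walk
#'   proposal (larger = smaller steps).
#' @param learn_beta if `FALSE`, the kernel weights stay fixed at their
#'   initial value (uniform, or a supplied point mass).
#' @param seed integer seed making the whole fit reproducible.
#' @return a list of class `pmkl_control`.
#' @export
pmkl_control <- function(n_iter = 2000, burn_in = 500, n_mc_probit = 1000,
                         prior_shape = 1e-2, prior_rate = 1e-2,
                         dirichlet_conc = 1, beta_every = 10,
                         beta_proposal_conc = 100, learn_beta = TRUE,
                         seed = 1) {
  stopifnot(n_iter > 0, burn_in >= 0, burn_in < n_iter, n_mc_probit > 0)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 n_mc_probit = as.integer(n_mc_probit),
                 prior_shape = prior_shape, prior_rate = prior_rate,
                 dirichlet_conc = dirichlet_conc,
                 beta_every = as.integer(beta_every),
                 beta_proposal_conc = beta_proposal_conc,
                 learn_beta = isTRUE(learn_beta), seed = as.integer(seed)),
            class = "pmkl_control")
}

ldirichlet <- function(x, alpha) {
  sum((alpha - 1) * log(pmax(x, 1e-300))) + lgamma(sum(alpha)) -
    sum(lgamma(alpha))
}

#' Fit a probabilistic multiple-kernel multinomial-probit classifier
#'
#' The model places a multinomial probit likelihood on class labels given a
#' composite kernel representation of the subjects:
#' `P(Y_n = i | W, k_n) = E_u prod_{j != i} Phi(u + (w_i - w_j) . k_n)`,
#' with `u ~ N(0,1)`, `k_n` the subject's row of the beta-weighted combined
#' kernel (augmented with a constant bias element), and `W` the matrix of
#' per-class regression coefficients that weight the training subjects'
#' votes. Priors: `W ~ N(0, tau^-1 I)` with a Gamma hyperprior on `tau`, and
#' a Dirichlet prior on the simplex-constrained kernel weights `beta`.
#' Posterior means of `W` and `beta` are returned along with chain
#' diagnostics.
#'
#' @param x numeric matrix of (already standardized) training features,
#'   subjects in rows.
#' @param y class labels; binary cohorts use 0 = N-MCI, 1 = P-MCI. Two or
#'   more classes required.
#' @param kernels a [kernel_spec()] or list of them (default: one linear
#'   kernel over all features).
#' @param source_map optional named source vector, needed when specs subset
#'   by source name.
#' @param beta optional fixed simplex weights; supplying them implies
#'   `learn_beta = FALSE`.
#' @param control a [pmkl_control()].
#' @return an object of class `pmkl` with components `W` (posterior mean
#'   coefficients, classes x (n_train + 1), last column the bias), `beta`
#'   (posterior mean kernel weights), `kset` (fitted [kernel_set()]),
#'   `class_levels`, `diagnostics`, and the control used.
#' @export
pmkl <- function(x, y, kernels = kernel_spec("linear"), source_map = NULL,
                 beta = NULL, control = pmkl_control()) {
  x <- as.matrix(x)
  if (anyNA(x) || any(!is.finite(x))) stopf("non-finite values in x")
  class_levels <- sort(unique(y))
  C <- length(class_levels)
  if (C < 2) stopf("need at least 2 classes present; got %d", C)
  yi <- match(y, class_levels)
  n <- nrow(x)
  if (length(yi) != n) stopf("x and y lengths differ")

  kset <- kernel_set(x, kernels, source_map = source_map)
  M <- length(kset$K)
  if (!is.null(beta)) {
    if (length(beta) != M) stopf("beta must have one weight per kernel")
    if (any(beta < 0) || abs(sum(beta) - 1) > 1e-8)
      stopf("beta must lie on the probability simplex")
    control$learn_beta <- FALSE
  } else {
    beta <- rep(1 / M, M)
  }

  K_comb <- combine_kernels(kset$K, beta)
  ev <- eigen((K_comb + t(K_comb)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) < -1e-6)
    stopf("composite training kernel is not PSD (min eigenvalue %.3g)", min(ev))

  ctl <- control
  with_seed(ctl$seed, {
    A <- cbind(K_comb, 1)
    p1 <- n + 1L
    eg <- eigen(crossprod(A), symmetric = TRUE)
    V <- eg$vectors; dvals <- pmax(eg$values, 0)

    W <- matrix(0, C, p1)
    z <- matrix(-0.5, n, C); z[cbind(seq_len(n), yi)] <- 0.5
    tau <- 1
    true_pos <- cbind(seq_len(n), yi)

    W_sum <- matrix(0, C, p1); beta_sum <- rep(0, M)
    n_keep <- 0L; ll_trace <- numeric(ctl$n_iter); tau_trace <- numeric(ctl$n_iter)
    beta_prop <- 0L; beta_acc <- 0L

    for (it in seq_len(ctl$n_iter)) {
      Emean <- A %*% t(W)                      # n x C latent means

      # latent scores: non-observed classes truncated below the observed
      # class's score, then the observed class truncated above their max
      cur_true <- z[true_pos]
      for (cc in seq_len(C)) {
        idx <- which(yi != cc)
        if (length(idx))
          z[idx, cc] <- rtruncnorm1(Emean[idx, cc], cur_true[idx], lower = FALSE)
      }
      tmp <- z; tmp[true_pos] <- -Inf
      max_other <- do.call(pmax, as.data.frame(tmp))
      z[true_pos] <- rtruncnorm1(Emean[true_pos], max_other, lower = TRUE)

      # conjugate Gaussian update of each class's coefficient vector
      inv_d <- 1 / (dvals + tau)
      for (cc in seq_len(C)) {
        b <- crossprod(A, z[, cc])
        W[cc, ] <- V %*% (inv_d * crossprod(V, b) +
                            sqrt(inv_d) * rnorm(p1))
      }

      tau <- rgamma(1, shape = ctl$prior_shape + C * p1 / 2,
                    rate = ctl$prior_rate + sum(W^2) / 2)

      if (M > 1 && ctl$learn_beta && it %% ctl$beta_every == 0L) {
        beta_prop <- beta_prop + 1L
        alpha_fwd <- ctl$beta_proposal_conc * beta + 0.5
        beta_new <- rgamma(M, shape = alpha_fwd)
        beta_new <- beta_new / sum(beta_new)
        alpha_bwd <- ctl$beta_proposal_conc * beta_new + 0.5
        A_new <- cbind(combine_kernels(kset$K, beta_new), 1)
        ll_cur <- -0.5 * sum((z - A %*% t(W))^2)
        ll_new <- -0.5 * sum((z - A_new %*% t(W))^2)
        prior_conc <- rep(ctl$dirichlet_conc, M)
        logr <- (ll_new - ll_cur) +
          ldirichlet(beta_new, prior_conc) - ldirichlet(beta, prior_conc) +
          ldirichlet(beta, alpha_bwd) - ldirichlet(beta_new, alpha_fwd)
        if (is.finite(logr) && log(runif(1)) < logr) {
          beta_acc <- beta_acc + 1L
          beta <- beta_new; A <- A_new
          eg <- eigen(crossprod(A), symmetric = TRUE)
          V <- eg$vectors; dvals <- pmax(eg$values, 0)
        }
      }

      ll_trace[it] <- -0.5 * sum((z - A %*% t(W))^2)
      tau_trace[it] <- tau
      if (it > ctl$burn_in) {
        W_sum <- W_sum + W; beta_sum <- beta_sum + beta
        n_keep <- n_keep + 1L
      }
    }

    structure(list(
      W = W_sum / n_keep,
      beta = beta_sum / n_keep,
      kset = kset,
      class_levels = class_levels,
      n_train = n,
      training_ids = rownames(x) %||% as.character(seq_len(n)),
      diagnostics = list(loglik = ll_trace, tau = tau_trace,
                         beta_acceptance = if (beta_prop > 0)
                           beta_acc / beta_prop else NA_real_),
      control = ctl),
      class = "pmkl")
  })
}

#' Multinomial probit class probabilities from coefficients and kernel rows
#'
#' Monte-Carlo estimate of
#' `P(Y = i) = E_u prod_{j != i} Phi(u + (w_i - w_j) . k)`, `u ~ N(0,1)`,
#' using `n_mc` common-random-number draws shared across classes and
#' subjects, renormalized to sum to one. In the binary case this converges
#' to the closed form `Phi(a / sqrt(2))` where `a` is the coefficient-space
#' margin.
#'
#' @param W classes x (n_train + 1) coefficient matrix (last column bias).
#' @param k_rows a single kernel row (length `n_train + 1`, bias included)
#'   or a matrix of such rows.
#' @param n_mc number of standard-normal draws.
#' @param seed optional seed for the draws (deterministic estimates).
#' @return matrix of class probabilities, one row per subject.
#' @export
probit_class_probability <- function(W, k_rows, n_mc = 1000, seed = NULL) {
  if (is.null(dim(k_rows))) k_rows <- matrix(k_rows, nrow = 1)
  if (ncol(k_rows) != ncol(W))
    stopf("kernel rows have %d elements, coefficients expect %d",
          ncol(k_rows), ncol(W))
  if (anyNA(W) || any(!is.finite(W)) || any(!is.finite(k_rows)))
    stopf("non-finite inputs")
  S <- k_rows %*% t(W)                     # n x C class scores
  C <- ncol(S); n <- nrow(S)
  u <- with_seed(seed, rnorm(n_mc))
  P <- matrix(0, n, C)
  for (i in seq_len(C)) {
    acc <- matrix(1, n, n_mc)
    for (j in seq_len(C)) {
      if (j == i) next
      acc <- acc * pnorm(outer(S[, i] - S[, j], u, "+"))
    }
    P[, i] <- rowMeans(acc)
  }
  P / rowSums(P)
}

#' Predict progression probabilities for new subjects
#'
#' @param object a fitted [pmkl()] model.
#' @param newdata matrix of new feature rows on the same (standardized)
#'   scale and columns as the training data.
#' @param threshold binary decision threshold on the probability of the
#'   second class (the progressor class under 0/1 coding); a probability
#'   exactly at the threshold is called non-progressor and flagged as a tie
#'   (conservative: no "progressor" call at zero evidence).
#' @param n_mc,seed Monte-Carlo settings for the probit expectation;
#'   default to the fit's control.
#' @param ... unused.
#' @return object of class `pmkl_prediction`: list with `prob` (subjects x
#'   classes, columns named by class level), `label`, `confidence`
#'   (difference between the two largest class probabilities) and `tie`.
#' @export
predict.pmkl <- function(object, newdata, threshold = 0.5,
                         n_mc = NULL, seed = NULL, ...) {
  n_mc <- n_mc %||% object$control$n_mc_probit
  seed <- seed %||% child_seed(object$control$seed, 777L)
  cross <- kernel_rows(object$kset, newdata)
  Kc <- combine_kernels(cross, object$beta)
  k_rows <- cbind(Kc, 1)
  P <- probit_class_probability(object$W, k_rows, n_mc = n_mc, seed = seed)
  colnames(P) <- as.character(object$class_levels)
  classify_probabilities(P, object$class_levels, threshold)
}

# shared decision rule: binary thresholding / multiclass argmax + tie flag
classify_probabilities <- function(P, class_levels, threshold = 0.5) {
  C <- length(class_levels)
  if (C == 2) {
    p_pos <- P[, 2]
    label <- ifelse(p_pos > threshold, class_levels[2], class_levels[1])
    tie <- p_pos == threshold
  } else {
    which_best <- apply(P, 1, which.max)
    label <- class_levels[which_best]
    tie <- apply(P, 1, function(p) sum(p == max(p)) > 1)
  }
  conf <- apply(P, 1, function(p) {
    s <- sort(p, decreasing = TRUE)
    s[1] - s[2]
  })
  structure(list(prob = P, label = label, confidence = conf, tie = tie),
            class = "pmkl_prediction")
}

#' @export
print.pmkl_prediction <- function(x, ...) {
  cat(sprintf("<pmkl_prediction> %d subjects, %d classes\n",
              nrow(x$prob), ncol(x$prob)))
  cat(sprintf("  mean confidence %.3f; %d tie(s)\n",
              mean(x$confidence), sum(x$tie)))
  invisible(x)
}

#' @export
print.pmkl <- function(x, ...) {
  cat(sprintf("<pmkl> %d training subjects, %d classes, %d kernel(s)\n",
              x$n_train, length(x$class_levels), length(x$kset$K)))
  cat("  kernels:", paste(vapply(x$kset$specs, `[[`, "", "name"),
                          collapse = ", "), "\n")
  cat("  beta:", paste(sprintf("%.3f", x$beta), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.pmkl <- function(object, ...) {
  d <- object$diagnostics
  out <- list(
    n_train = object$n_train,
    classes = object$class_levels,
    kernel_names = vapply(object$kset$specs, `[[`, "", "name"),
    beta = object$beta,
    beta_acceptance = d$beta_acceptance,
    coef_norms = sqrt(rowSums(object$W^2)),
    loglik_last = utils::tail(d$loglik, 1),
    tau_mean = mean(d$tau[(object$control$burn_in + 1):length(d$tau)]))
  class(out) <- "summary.pmkl"
  out
}

#' @export
print.summary.pmkl <- function(x, ...) {
  cat(sprintf("pMKL fit: %d training subjects, classes {%s}\n", x$n_train,
              paste(x$classes, collapse = ", ")))
  cat("kernel weights (posterior mean):\n")
  print(stats::setNames(round(x$beta, 4), x$kernel_names))
  if (!is.na(x$beta_acceptance))
    cat(sprintf("beta MH acceptance: %.2f\n", x$beta_acceptance))
  cat(sprintf("posterior mean precision tau: %.4g\n", x$tau_mean))
  invisible(x)
}

#' @export
coef.pmkl <- function(object, ...) object$W

#' Serialize a fitted pMKL model to a JSON document
#'
#' Everything needed for exact reload and prediction is written: posterior
#' means `W` and `beta`, the resolved kernel specifications (including
#' resolved bandwidths and trace-normalization factors), the training
#' feature matrix, subject ids, class levels, and the control (seeds
#' included).
#'
#' @param model a [pmkl()] fit.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_pmkl <- function(model, path) {
  doc <- list(
    W = model$W,
    beta = model$beta,
    class_levels = model$class_levels,
    training_ids = model$training_ids,
    X_train = model$kset$X_train,
    feature_names = colnames(model$kset$X_train),
    scales = model$kset$scales,
    subsets = model$kset$subsets,
    specs = lapply(model$kset$specs, function(sp)
      list(kind = sp$kind, degree = sp$degree, offset = sp$offset,
           sigma = sp$sigma, name = sp$name)),
    control = unclass(model$control))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reload a serialized pMKL model
#'
#' @param path path written by [write_pmkl()].
#' @return a `pmkl` object whose predictions match the original exactly.
#' @export
read_pmkl <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  X <- as.matrix(doc$X_train)
  colnames(X) <- doc$feature_names
  specs <- lapply(seq_len(nrow(doc$specs)), function(i) {
    s <- doc$specs$sigma[i]
    if (!identical(s, "median_heuristic")) s <- as.numeric(s)
    kernel_spec(doc$specs$kind[i], degree = doc$specs$degree[i],
                offset = doc$specs$offset[i], sigma = s,
                name = doc$specs$name[i])
  })
  subsets <- doc$subsets
  if (is.matrix(subsets)) subsets <- lapply(seq_len(nrow(subsets)),
                                            function(i) subsets[i, ])
  if (!is.list(subsets)) subsets <- list(as.integer(subsets))
  Ks <- lapply(seq_along(specs), function(m) {
    idx <- as.integer(subsets[[m]])
    K <- compute_kernel(X[, idx, drop = FALSE], X[, idx, drop = FALSE],
                        specs[[m]])
    attr(K, "sigma") <- NULL
    K * doc$scales[m]
  })
  kset <- structure(list(K = Ks, specs = specs,
                         subsets = lapply(subsets, as.integer),
                         scales = doc$scales, X_train = X,
                         n_train = nrow(X)),
                    class = "kernel_set")
  ctl <- doc$control
  control <- pmkl_control(n_iter = ctl$n_iter, burn_in = ctl$burn_in,
                          n_mc_probit = ctl$n_mc_probit,
                          prior_shape = ctl$prior_shape,
                          prior_rate = ctl$prior_rate,
                          dirichlet_conc = ctl$dirichlet_conc,
                          beta_every = ctl$beta_every,
                          beta_proposal_conc = ctl$beta_proposal_conc,
                          learn_beta = ctl$learn_beta, seed = ctl$seed)
  structure(list(W = as.matrix(doc$W), beta = doc$beta, kset = kset,
                 class_levels = doc$class_levels, n_train = nrow(X),
                 training_ids = doc$training_ids,
                 diagnostics = list(loglik = NULL, tau = NULL,
                                    beta_acceptance = NA_real_),
                 control = control),
            class = "pmkl")
}
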