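#' Discretize a continuous feature for mutual-information estimation
#'
#' Mutual information is estimated with plug-in counts on discrete codes, so
#' continuous features are binned first. Intervals are left-closed /
#' right-open except the last (closed); a value falling exactly on an
#' interior edge goes to the lower bin.
#'
#' @param values numeric vector.
#' @param n_bins number of bins (>= 2).
#' @param strategy `"equal_frequency"` (quantile edges; default elsewhere in
#'   the package) or `"equal_width"`.
#' @return object of class `discretized_feature`: list with integer `codes`
#'   in `0..n_bins-1`, the interior `edges`, and `n_bins` actually realized.
#' @export
discretize <- function(values, n_bins = 10,
                       strategy = c("equal_frequency", "equal_width")) {
  strategy <- match.arg(strategy)
  if (n_bins < 2) stopf("n_bins must be >= 2")
  rng <- range(values)
  if (rng[1] == rng[2]) {
    warnf("constant vector: single bin")
    return(structure(list(codes = rep(0L, length(values)),
                          edges = numeric(0), n_bins = 1L),
                     class = "discretized_feature"))
  }
  edges <- if (strategy == "equal_width") {
    seq(rng[1], rng[2], length.out = n_bins + 1)[-c(1, n_bins + 1)]
  } else {
    unique(stats::quantile(values, probs = seq_len(n_bins - 1) / n_bins,
                           type = 7, names = FALSE))
  }
  edges <- edges[edges > rng[1] & edges < rng[2]]
  edges <- sort(unique(edges))
  # ties at an edge go to the lower bin: count edges strictly below the value
  codes <- findInterval(values, edges, left.open = TRUE)
  structure(list(codes = as.integer(codes), edges = edges,
                 n_bins = length(edges) + 1L),
            class = "discretized_feature")
}

# entropy (nats) of a count vector, 0*log0 := 0
entropy_counts <- function(counts) {
  n <- sum(counts)
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

as_codes <- function(x) {
  if (inherits(x, "discretized_feature")) list(codes = x$codes, k = x$n_bins)
  else {
    v <- as.integer(x)
    list(codes = v, k = max(v) + 1L)
  }
}

#' Plug-in mutual information between a discretized feature and a label
#'
#' `I(X;Y) = sum p(x,y) log[p(x,y) / (p(x) p(y))]` in nats, with the
#' convention `0 log 0 = 0`, estimated from the empirical joint counts.
#'
#' @param x a [discretize()]d feature (or integer codes starting at 0).
#' @param y binary (or small-alphabet integer) vector.
#' @return nonnegative mutual information in nats.
#' @export
mutual_information <- function(x, y) {
  cx <- as_codes(x); cy <- as_codes(y)
  if (length(cx$codes) != length(cy$codes)) stopf("length mismatch")
  joint <- tabulate(cx$codes * cy$k + cy$codes + 1L, nbins = cx$k * cy$k)
  hx <- entropy_counts(tabulate(cx$codes + 1L, nbins = cx$k))
  hy <- entropy_counts(tabulate(cy$codes + 1L, nbins = cy$k))
  hxy <- entropy_counts(joint)
  max(hx + hy - hxy, 0)
}

#' Joint mutual information of a feature pair with the label
#'
#' `I((Xk, Xj); Y)` computed by the plug-in estimator on the product
#' alphabet of the two discretized features. This is the building block of
#' the JMI selection criterion: it rewards candidates that are relevant and
#' complementary to already-selected features, and never falls below either
#' marginal relevance on exact counts.
#'
#' @param xk,xj [discretize()]d features (or integer codes).
#' @param y binary vector.
#' @return joint mutual information in nats.
#' @export
joint_mutual_information <- function(xk, xj, y) {
  ck <- as_codes(xk); cj <- as_codes(xj)
  if (length(ck$codes) != length(cj$codes)) stopf("length mismatch")
  pair <- ck$codes * cj$k + cj$codes
  mutual_information(structure(list(codes = as.integer(pair),
                                    n_bins = ck$k * cj$k,
                                    edges = numeric(0)),
                               class = "discretized_feature"), y)
}

#' Greedy JMI ranking of features against a binary outcome
#'
#' The "filter" stage of the filter-wrapper pipeline. The first feature
#' maximizes marginal relevance `I(X;Y)`; each subsequent feature maximizes
#' the JMI score `sum_{j in S} I((Xk, Xj); Y)` over candidates `k` not yet
#' selected, which favours features that are maximally relevant while
#' minimally redundant and maximally complementary with the selected set.
#' Ties break to the lowest feature index so rankings are reproducible.
#'
#' @param dataset a labelled [cohort_dataset()], or a numeric matrix (then
#'   `y` must be given).
#' @param y binary outcome; defaults to `dataset$labels`.
#' @param max_features number of features to rank (capped at the number of
#'   features, with a warning beyond it).
#' @param n_bins,strategy discretization settings (default equal-frequency,
#'   10 bins — robust to skewed clinical/proteomic marginals).
#' @return object of class `jmi_ranking`: list with `selected` (ordered
#'   feature indices), `scores` (criterion value at each step: marginal MI
#'   for the first, cumulative JMI for the rest), `feature_names`.
#' @export
jmi_rank <- function(dataset, y = NULL, max_features = 50,
                     n_bins = 10, strategy = "equal_frequency") {
  if (inherits(dataset, "cohort_dataset")) {
    X <- dataset$features
    y <- y %||% dataset$labels
    fn <- dataset$feature_names
  } else {
    X <- as.matrix(dataset)
    fn <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  }
  if (is.null(y)) stopf("jmi_rank requires a labelled dataset")
  if (max_features < 1) stopf("max_features must be >= 1")
  p <- ncol(X)
  if (max_features > p) {
    warnf("max_features (%d) exceeds n_features (%d); returning all",
          max_features, p)
    max_features <- p
  }
  y <- as.integer(y)
  ky <- max(y) + 1L
  n <- length(y)

  disc <- lapply(seq_len(p), function(j)
    suppressWarnings(discretize(X[, j], n_bins = n_bins, strategy = strategy)))
  codes <- lapply(disc, `[[`, "codes")
  kbin <- vapply(disc, `[[`, integer(1), "n_bins")
  hy <- entropy_counts(tabulate(y + 1L, nbins = ky))

  mi_with_y <- function(c1, k1) {
    joint <- tabulate(c1 * ky + y + 1L, nbins = k1 * ky)
    h1 <- entropy_counts(tabulate(c1 + 1L, nbins = k1))
    max(h1 + hy - entropy_counts(joint), 0)
  }
  jmi_pair <- function(j1, j2) {
    pair <- codes[[j1]] * kbin[j2] + codes[[j2]]
    mi_with_y(pair, kbin[j1] * kbin[j2])
  }

  rel <- vapply(seq_len(p), function(j) mi_with_y(codes[[j]], kbin[j]),
                numeric(1))
  selected <- which.max(rel)           # which.max ties -> lowest index
  scores <- rel[selected]
  cum <- rep(0, p)                     # cached JMI score sum per candidate
  remaining <- setdiff(seq_len(p), selected)
  while (length(selected) < max_features && length(remaining)) {
    last <- selected[length(selected)]
    for (kf in remaining) cum[kf] <- cum[kf] + jmi_pair(kf, last)
    best <- remaining[which.max(cum[remaining])]
    selected <- c(selected, best)
    scores <- c(scores, cum[best])
    remaining <- setdiff(remaining, best)
  }
  structure(list(selected = selected, scores = scores,
                 feature_names = fn[selected]),
            class = "jmi_ranking")
}

#' @export
print.jmi_ranking <- function(x, n = 10, ...) {
  cat(sprintf("<jmi_ranking> %d features ranked\n", length(x$selected)))
  k <- min(n, length(x$selected))
  print(data.frame(rank = seq_len(k),
                   feature = x$feature_names[seq_len(k)],
                   score = signif(x$scores[seq_len(k)], 4)))
  invisible(x)
}

#' Selection frequency across cross-validation trials
#'
#' Tallies how often each feature entered a final model across the `k * r`
#' trials of a repeated nested cross-validation run, the quantity reported
#' when asking which baseline predictors are selected consistently.
#'
#' @param selections list of integer vectors (selected feature indices per
#'   trial).
#' @param n_features total number of candidate features.
#' @return numeric vector of frequencies in `[0, 1]`, one per feature.
#' @export
selection_frequency <- function(selections, n_features) {
  counts <- tabulate(unlist(selections), nbins = n_features)
  counts / length(selections)
}
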