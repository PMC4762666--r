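# internal helpers shared across the package

SOURCES <- c("CRF", "CAM", "MRI", "PPM")
VISIT_GRID <- c(6, 12, 18, 24, 36)

#' Evaluate code under a local, restorable RNG state
#'
#' All randomness in the package flows through explicit integer seeds; this
#' helper seeds the RNG for the duration of `expr` and then restores the
#' caller's RNG state, so package functions never perturb user-level
#' reproducibility.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# derive a child seed from a base seed and an index, kept within 32-bit range
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 2654435761 + index * 40503) %% 2147483647L)
}

# one-sided truncated standard-deviation-1 normal draws, vectorised.
# lower = TRUE draws from (bound, Inf), else from (-Inf, bound), mean `mu`.
rtruncnorm1 <- function(mu, bound, lower) {
  p_bound <- pnorm(bound, mean = mu)
  u <- runif(length(mu))
  if (lower) {
    q <- p_bound + u * (1 - p_bound)
  } else {
    q <- u * p_bound
  }
  # clamp away from 0/1 so qnorm stays finite under extreme separation
  q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
  qnorm(q, mean = mu)
}

# sample-moment skewness (used to decide log1p pre-transform)
sample_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
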