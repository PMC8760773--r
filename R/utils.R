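# Numerical helpers shared across the variational kernels.

#' Log-sum-exp
#'
#' Numerically stable `log(sum(exp(x)))`.
#'
#' @param x Numeric vector (may contain `-Inf`).
#' @return A scalar.
#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

softplus <- function(x) {
  # log(1 + exp(x)) without overflow
  ifelse(x > 30, x, log1p(exp(x)))
}

#' Derive a reproducible sub-stream seed
#'
#' Expands one user-facing seed into per-stage seeds so that pipeline stages
#' (simulation, fold splitting, initialization, SMOTE) are independently
#' reproducible. Kept below 2^31 so it is always a valid R integer.
#'
#' @param seed Integer base seed.
#' @param tag Character stage tag.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 69069 + h * 1013) %% 2147483647L)
}

# Draw one Dirichlet vector.
rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) <= 0) x <- rep(1, length(alpha))
  x / sum(x)
}

assert_prob_rows <- function(m, what, tol = 1e-8) {
  if (any(!is.finite(m)) || any(m < 0)) {
    abort(sprintf("%s must be finite and nonnegative", what))
  }
  if (any(abs(rowSums(m) - 1) > tol)) {
    abort(sprintf("rows of %s must sum to 1", what))
  }
  invisible(m)
}
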