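#' Model parameters of the hierarchical supervised topic model
#'
#' Bundles the four parameter blocks of the model: the Dirichlet
#' hyperparameter `alpha` (length `K`), the topic-to-feature multinomials
#' `pi` (`K x F`, rows on the simplex), the topic-to-value multinomials
#' `beta` (`K x V`, normalized within each topic's feature block, so that
#' for every topic `k` and feature `f` the entries of `beta[k, ]` over
#' `f`'s values sum to 1), and the class coefficients `eta` (`C x K`).
#' `value_feature` gives each value's owning feature index and defines the
#' blocks.
#'
#' @param alpha Positive numeric vector of length `K`.
#' @param pi `K x F` matrix, rows summing to 1.
#' @param beta `K x V` matrix, block rows summing to 1 within each feature.
#' @param eta `C x K` numeric matrix.
#' @param value_feature Integer vector of length `V` mapping each value to
#'   its feature index in `1..F`.
#' @return A list of class `hslda_params`.
#' @export
hslda_params <- function(alpha, pi, beta, eta, value_feature) {
  alpha <- as.numeric(alpha)
  pi <- as.matrix(pi); beta <- as.matrix(beta); eta <- as.matrix(eta)
  value_feature <- as.integer(value_feature)
  K <- length(alpha)
  if (any(!is.finite(alpha)) || any(alpha <= 0)) abort("alpha must be positive")
  if (nrow(pi) != K || nrow(beta) != K || ncol(eta) != K) {
    abort("pi, beta, eta must have K rows / columns matching length(alpha)")
  }
  if (ncol(beta) != length(value_feature)) {
    abort("ncol(beta) must equal length(value_feature)")
  }
  if (max(value_feature) > ncol(pi) || min(value_feature) < 1) {
    abort("value_feature indices out of range")
  }
  assert_prob_rows(pi, "pi")
  for (f in seq_len(ncol(pi))) {
    block <- which(value_feature == f)
    bs <- rowSums(beta[, block, drop = FALSE])
    if (any(abs(bs - 1) > 1e-8)) {
      abort(sprintf("beta rows must sum to 1 within feature block %d", f))
    }
  }
  structure(list(alpha = alpha, pi = pi, beta = beta, eta = eta,
                 value_feature = value_feature),
            class = "hslda_params")
}

#' @export
print.hslda_params <- function(x, ...) {
  cat(sprintf("<hslda_params> K=%d topics, F=%d features, V=%d values, C=%d classes\n",
              length(x$alpha), ncol(x$pi), ncol(x$beta), nrow(x$eta)))
  invisible(x)
}
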