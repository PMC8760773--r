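# Per-document variational inference (mean-field coordinate ascent).
#
# Low-level kernels operate on plain vectors/matrices plus a "doc" triple
# list(f, v, w): 1-based feature indices, value indices and positive token
# weights, all of length N. `fit_hslda()`/`predict()` build these from an
# hslda_corpus; the kernels are exported so their coordinate updates can be
# checked directly against independent oracles.

as_doc <- function(f, v, w = rep(1, length(v))) {
  list(f = as.integer(f), v = as.integer(v), w = as.numeric(w))
}

#' Expected log topic proportions under the variational Dirichlet
#'
#' `E[log theta_i] = digamma(gamma_i) - digamma(sum(gamma))` for
#' `theta ~ Dirichlet(gamma)`.
#'
#' @param gamma Positive numeric vector.
#' @return Numeric vector of the same length; all entries are negative.
#' @examples
#' expected_log_theta(c(1, 1))  # both equal -1
#' @export
expected_log_theta <- function(gamma) {
  if (any(!is.finite(gamma)) || any(gamma <= 0)) {
    abort("gamma must be positive and finite")
  }
  digamma(gamma) - digamma(sum(gamma))
}

# log a[l, m] = log sum_i phi[m, i] exp(eta[l, i] * w_m / W), the per-token
# factors of the softmax log-partition bound. Returns a C x N matrix.
log_resp_factors <- function(phi, eta, weights, W = sum(weights)) {
  N <- nrow(phi); C <- nrow(eta)
  A <- matrix(0, C, N)
  for (m in seq_len(N)) {
    # C x K of eta scaled by this token's weight share
    Em <- eta * (weights[m] / W)
    Mx <- apply(Em, 1, max)
    A[, m] <- log(exp(Em - Mx) %*% phi[m, ]) + Mx
  }
  A
}

#' Linearization coefficients of the softmax log-partition
#'
#' The expected softmax normalizer `E_q[sum_l exp(eta_l' rbar)]` is linear
#' in any single token's responsibilities `phi_n`; this returns its
#' coefficient vector `h`, i.e.
#' `h_i = sum_l [prod_{m != n} sum_j phi_{m,j} exp(eta_{l,j} w_m/W)] *
#' exp(eta_{l,i} w_n/W)`. With all weights 1 (`W = N`) this is the
#' unweighted linearization used by multi-class sLDA. Computed in log space.
#'
#' @param phi `N x K` matrix of token responsibilities (rows on the simplex).
#' @param eta `C x K` class-coefficient matrix.
#' @param weights Positive token weights of length `N`.
#' @param n Token index in `1..N`.
#' @return Positive numeric vector of length `K`. With `eta = 0` this is
#'   exactly `rep(C, K)`.
#' @export
compute_h <- function(phi, eta, weights, n) {
  phi <- as.matrix(phi)
  N <- nrow(phi)
  if (n < 1 || n > N) abort("token index n out of range")
  exp(log_h(log_resp_factors(phi, eta, weights), eta, weights, n))
}

# log h for token n given precomputed factors A (C x N).
log_h <- function(A, eta, weights, n, W = sum(weights)) {
  s <- rowSums(A) - A[, n]                       # leave-one-out log products
  X <- s + eta * (weights[n] / W)                # C x K (recycles by column? no)
  # eta * scalar keeps C x K; adding s (length C) recycles down columns: ok
  Mx <- max(X)
  log(colSums(exp(X - Mx))) + Mx
}

#' Closed-form update of the variational Dirichlet parameter
#'
#' `gamma = alpha + sum_n w_n phi_n`; does not involve the class label.
#'
#' @param alpha Positive numeric vector of length `K`.
#' @param phi `N x K` responsibility matrix (may have zero rows).
#' @param weights Token weights of length `N`.
#' @return Numeric vector of length `K`, elementwise `>= alpha`.
#' @export
update_gamma <- function(alpha, phi, weights = rep(1, nrow(phi))) {
  phi <- as.matrix(phi)
  if (nrow(phi) == 0) return(alpha)
  alpha + as.numeric(crossprod(phi, weights))
}

#' Coordinate update of one token's topic responsibilities
#'
#' Maximizes the per-document evidence lower bound in `phi_n` holding
#' everything else fixed:
#' `phi_{n,i} proportional to pi[i, f_n] beta[i, v_n] exp(E[log theta_i] +
#' eta[y, i]/W - h_i / (w_n * h' phi_n_old))` when a label `y` is given
#' (with unit weights this is the textbook labeled update), and the same
#' expression without the two response-coupled terms when `label` is `NULL`
#' (test-time inference). Normalized with log-sum-exp.
#'
#' @param state List with elements `gamma` (length `K`) and `phi`
#'   (`N x K`).
#' @param params An [hslda_params].
#' @param doc A token triple `list(f, v, w)` of parallel vectors.
#' @param n Token index to update.
#' @param label Optional 1-based class index.
#' @return Numeric simplex vector of length `K`.
#' @export
update_phi <- function(state, params, doc, n, label = NULL) {
  N <- length(doc$v)
  if (n < 1 || n > N) abort("token index n out of range")
  elog <- expected_log_theta(state$gamma)
  lp <- log(params$pi[, doc$f[n]]) + log(params$beta[, doc$v[n]]) + elog
  if (!is.null(label)) {
    W <- sum(doc$w)
    A <- log_resp_factors(state$phi, params$eta, doc$w, W)
    lh <- log_h(A, params$eta, doc$w, n, W)
    log_hphi <- logsumexp(lh + log(state$phi[n, ]))
    lp <- lp + params$eta[label, ] / W - exp(lh - log_hphi) / doc$w[n]
  }
  p <- exp(lp - logsumexp(lp))
  p / sum(p)
}

# One full labeled sweep over tokens with cached leave-one-out factors;
# returns the updated phi together with the factor matrix A (C x N) so the
# caller can reuse it for the bound's response term. The loop lives in
# compiled code (src/kernels.cpp); this wrapper assembles its inputs.
sweep_phi_labeled <- function(phi, elog, params, doc, label) {
  base <- log(params$pi[, doc$f, drop = FALSE]) +
    log(params$beta[, doc$v, drop = FALSE]) + elog   # K x N
  cpp_sweep_phi_labeled(phi, base, params$eta, doc$w, sum(doc$w),
                        as.integer(label))
}

#' Per-document evidence lower bound
#'
#' The sum of the Dirichlet, topic-assignment, feature, value, response and
#' entropy terms of the variational bound. Token-level terms are scaled by
#' the token weights; the intractable expected softmax log-partition is
#' replaced by `log E_q[...]` (Jensen), so the returned value is a true
#' lower bound on the exact log evidence. With `label = NULL` the response
#' term is omitted.
#'
#' @inheritParams update_phi
#' @param state List with `gamma` and `phi`.
#' @return A scalar.
#' @export
elbo_doc <- function(doc, state, params, label = NULL) {
  alpha <- params$alpha
  gamma <- state$gamma
  K <- length(alpha)
  elog <- expected_log_theta(gamma)
  # Dirichlet prior term and variational Dirichlet entropy
  val <- lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * elog)
  val <- val - lgamma(sum(gamma)) + sum(lgamma(gamma)) -
    sum((gamma - 1) * elog)
  N <- length(doc$v)
  # empty document: rbar = 0 by convention, so the response is uniform
  if (N == 0) return(val - if (is.null(label)) 0 else log(nrow(params$eta)))
  phi <- as.matrix(state$phi)
  w <- doc$w
  lp_tok <- log(params$pi[, doc$f, drop = FALSE]) +
    log(params$beta[, doc$v, drop = FALSE])        # K x N
  val <- val + sum(w * colSums(t(phi) * (lp_tok + elog)))
  plp <- phi * log(phi)
  plp[phi == 0] <- 0
  val <- val - sum(w * rowSums(plp))
  if (!is.null(label)) {
    W <- sum(w)
    phi_bar <- as.numeric(crossprod(phi, w)) / W
    A <- log_resp_factors(phi, params$eta, w, W)
    val <- val + sum(params$eta[label, ] * phi_bar) - logsumexp(rowSums(A))
  }
  val
}

#' Variational inference for one document
#'
#' Alternates full responsibility sweeps and the Dirichlet update until the
#' per-document bound's relative change falls below `config$e_step$rel_tol`
#' or `config$e_step$max_iters` is reached. Initialization: uniform `phi`,
#' `gamma = alpha + W/K`.
#'
#' @inheritParams update_phi
#' @param config An [hslda_config].
#' @param init Optional warm start: a list with `gamma` and `phi` from a
#'   previous call (used by the EM loop so successive E-steps resume from
#'   the incumbent optimum).
#' @return A list with `gamma`, `phi`, `phi_bar` (weighted mean
#'   responsibility), `elbo`, `trace` (bound per iteration), `iterations`,
#'   `converged`, and `empty` (`TRUE` for zero-token documents).
#' @export
doc_e_step <- function(doc, params, label = NULL, config = hslda_config(),
                       init = NULL) {
  K <- length(params$alpha)
  N <- length(doc$v)
  if (N == 0) {
    return(list(gamma = params$alpha, phi = matrix(0, 0, K),
                phi_bar = rep(1 / K, K),
                elbo = elbo_doc(doc,
                  list(gamma = params$alpha, phi = matrix(0, 0, K)),
                  params, label = label),
                trace = numeric(0), iterations = 0L, converged = TRUE,
                empty = TRUE))
  }
  W <- sum(doc$w)
  if (is.null(init)) {
    phi <- matrix(1 / K, N, K)
    gamma <- params$alpha + W / K
  } else {
    phi <- init$phi
    gamma <- init$gamma
  }
  # constant and token-likelihood pieces of the bound
  alpha <- params$alpha
  lp_tok <- log(params$pi[, doc$f, drop = FALSE]) +
    log(params$beta[, doc$v, drop = FALSE])            # K x N
  const <- lgamma(sum(alpha)) - sum(lgamma(alpha))
  bound_at <- function(phi, gamma, A) {
    elog <- expected_log_theta(gamma)
    val <- const + sum((alpha - 1) * elog) -
      lgamma(sum(gamma)) + sum(lgamma(gamma)) - sum((gamma - 1) * elog)
    plp <- phi * log(phi)
    plp[phi == 0] <- 0
    val <- val + sum(doc$w * (colSums(t(phi) * (lp_tok + elog)) - rowSums(plp)))
    if (!is.null(label)) {
      phi_bar <- as.numeric(crossprod(phi, doc$w)) / W
      val <- val + sum(params$eta[label, ] * phi_bar) -
        logsumexp(rowSums(A))
    }
    val
  }
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(config$e_step$max_iters)) {
    elog <- expected_log_theta(gamma)
    A <- NULL
    if (is.null(label)) {
      lp <- lp_tok + elog
      mx <- apply(lp, 2, max)
      p <- exp(sweep(lp, 2, mx))
      phi <- t(p) / colSums(p)
    } else {
      sw <- sweep_phi_labeled(phi, elog, params, doc, label)
      phi <- sw$phi
      A <- sw$A
    }
    gamma <- update_gamma(params$alpha, phi, doc$w)
    cur <- bound_at(phi, gamma, A)
    trace <- c(trace, cur)
    if (is.finite(prev) && abs(cur - prev) <= config$e_step$rel_tol * abs(prev)) {
      converged <- TRUE
      break
    }
    prev <- cur
  }
  list(gamma = gamma, phi = phi,
       phi_bar = as.numeric(crossprod(phi, doc$w)) / W,
       elbo = trace[length(trace)], trace = trace,
       iterations = it, converged = converged, empty = FALSE)
}

#' Exact log evidence by enumeration (small instances)
#'
#' Computes `log p(f, v[, y])` exactly by summing over all `K^N` topic
#' assignments, using the Dirichlet-multinomial marginal over assignments:
#' `DirMult(c; alpha) = Gamma(sum a)/Gamma(sum a + N) * prod_i
#' Gamma(a_i + c_i)/Gamma(a_i)`. Serves as the independent upper-bound
#' oracle for [elbo_doc()]. Requires unit token weights and `K^N <= 1e6`.
#'
#' @inheritParams update_phi
#' @return The exact log evidence (a scalar).
#' @export
oracle_log_evidence <- function(doc, params, label = NULL) {
  K <- length(params$alpha)
  N <- length(doc$v)
  if (any(doc$w != 1)) abort("oracle requires unit token weights")
  if (K^N > 1e6) abort("instance too large for enumeration (K^N > 1e6)")
  alpha <- params$alpha
  if (N == 0) {
    if (is.null(label)) return(0)
    # rbar undefined for empty documents; response of an empty doc is
    # uniform over classes under the convention rbar = 0
    return(-log(nrow(params$eta)))
  }
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
  lp_tok <- log(params$pi[, doc$f, drop = FALSE]) +
    log(params$beta[, doc$v, drop = FALSE])          # K x N
  ll <- numeric(nrow(grid))
  for (n in seq_len(N)) ll <- ll + lp_tok[grid[, n], n]
  counts <- vapply(seq_len(K), function(k) rowSums(grid == k),
                   numeric(nrow(grid)))
  counts <- matrix(counts, nrow = nrow(grid))
  ldm <- lgamma(sum(alpha)) - lgamma(sum(alpha) + N) +
    rowSums(lgamma(sweep(counts, 2, alpha, "+"))) - sum(lgamma(alpha))
  ll <- ll + ldm
  if (!is.null(label)) {
    rbar <- counts / N
    sc <- rbar %*% t(params$eta)                      # M x C
    ll <- ll + sc[, label] - apply(sc, 1, logsumexp)
  }
  logsumexp(ll)
}
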