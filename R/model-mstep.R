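# Corpus-level parameter estimation (variational M-step).

#' Closed-form M-step for the topic-feature and topic-value multinomials
#'
#' `pi[k, f]` is proportional to `epsilon + sum_d sum_n w_n 1[f_n = f]
#' phi^d_{n,k}` (normalized over features); `beta[k, v]` is proportional to
#' the analogous value-indexed statistic, normalized within each
#' `(topic, feature-block)`. The smoothing floor keeps `log pi`, `log beta`
#' finite for pairs unseen under a topic.
#'
#' @param corpus An [hslda_corpus].
#' @param states List of per-document states from [doc_e_step()], one per
#'   document, in corpus order.
#' @param epsilon Nonnegative smoothing added to every count.
#' @return A list with matrices `pi` (`K x F`) and `beta` (`K x V`).
#' @export
m_step_pi_beta <- function(corpus, states, epsilon = 1e-10) {
  idx <- corpus_index(corpus)
  m_step_pi_beta_idx(idx, states, epsilon)
}

m_step_pi_beta_idx <- function(idx, states, epsilon) {
  K <- length(states[[1]]$gamma)
  Fq <- idx$F; V <- idx$V
  pi_stat <- matrix(0, K, Fq)
  beta_stat <- matrix(0, K, V)
  for (d in seq_along(idx$docs)) {
    doc <- idx$docs[[d]]
    if (length(doc$v) == 0) next
    wphi <- states[[d]]$phi * doc$w              # N x K
    for (k in seq_len(K)) {
      pi_stat[k, ] <- pi_stat[k, ] +
        as.numeric(rowsum_vec(wphi[, k], doc$f, Fq))
      beta_stat[k, ] <- beta_stat[k, ] +
        as.numeric(rowsum_vec(wphi[, k], doc$v, V))
    }
  }
  pi_stat <- pi_stat + epsilon
  beta_stat <- beta_stat + epsilon
  pi <- pi_stat / rowSums(pi_stat)
  beta <- beta_stat
  for (f in seq_len(Fq)) {
    block <- which(idx$vf == f)
    bs <- rowSums(beta_stat[, block, drop = FALSE])
    beta[, block] <- beta_stat[, block, drop = FALSE] / bs
  }
  list(pi = pi, beta = beta)
}

rowsum_vec <- function(x, group, n) {
  out <- numeric(n)
  agg <- rowsum(x, group)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# Precompute per-document pieces used by the eta objective.
eta_doc_data <- function(idx, states) {
  purrr::map(seq_along(idx$docs), function(d) {
    doc <- idx$docs[[d]]
    st <- states[[d]]
    list(phi = st$phi, w = doc$w, W = sum(doc$w), y = doc$label,
         phi_bar = st$phi_bar)
  })
}

# Penalized response objective and gradient for eta (C x K); the per-token
# accumulation is compiled (src/kernels.cpp).
eta_objective <- function(eta, docs, lambda) {
  cpp_eta_objective(eta, docs, lambda)
}

#' Conjugate-gradient M-step for the class coefficients
#'
#' Maximizes the response part of the corpus bound,
#' `sum_d [eta_{y_d}' phi_bar_d - log sum_l prod_n sum_i phi^d_{n,i}
#' exp(eta_{l,i} w_n / W_d)]`, minus an L2 penalty `lambda * ||eta||^2`
#' added because the softmax is invariant to shifting all class rows. Uses
#' Polak-Ribiere conjugate gradients (via [stats::optim()]) with the
#' analytic gradient, restarted until the gradient infinity-norm drops
#' below `config$cg$grad_tol` or the iteration cap is reached.
#'
#' @param corpus A fully labeled [hslda_corpus].
#' @param states Per-document states from [doc_e_step()].
#' @param eta_init `C x K` starting matrix.
#' @param config An [hslda_config] (fields `cg` and `lambda` are used).
#' @return The optimized `C x K` matrix. The penalized objective at the
#'   result is never below its value at `eta_init`.
#' @export
m_step_eta <- function(corpus, states, eta_init, config = hslda_config()) {
  idx <- corpus_index(corpus)
  if (any(vapply(idx$docs, function(d) is.na(d$label), logical(1)))) {
    abort("m_step_eta requires every document to be labeled")
  }
  m_step_eta_idx(idx, states, eta_init, config)
}

m_step_eta_idx <- function(idx, states, eta_init, config) {
  docs <- eta_doc_data(idx, states)
  C <- nrow(eta_init); K <- ncol(eta_init)
  lambda <- config$lambda
  cache <- new.env(parent = emptyenv())
  eval_at <- function(par) {
    if (!is.null(cache$par) && identical(cache$par, par)) return(cache$res)
    cache$par <- par
    cache$res <- eta_objective(matrix(par, C, K), docs, lambda)
    cache$res
  }
  fn <- function(par) -eval_at(par)$value
  gr <- function(par) -as.numeric(eval_at(par)$gradient)
  par <- as.numeric(eta_init)
  used <- 0L
  repeat {
    g <- gr(par)
    if (max(abs(g)) < config$cg$grad_tol || used >= config$cg$max_iters) break
    chunk <- min(50L, config$cg$max_iters - used)
    res <- optim(par, fn, gr, method = "CG",
                 control = list(maxit = chunk, type = 2, reltol = 1e-8))
    if (max(abs(par - res$par)) == 0) { par <- res$par; break }
    par <- res$par
    used <- used + chunk
  }
  eta_new <- matrix(par, C, K)
  # never accept a step that lowers the penalized objective
  if (eta_objective(eta_new, docs, lambda)$value <
      eta_objective(eta_init, docs, lambda)$value) {
    return(eta_init)
  }
  eta_new
}
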