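# Fixture builders and independent oracles. Everything here is written
# directly from the model's densities, without calling the package's
# inference kernels, so the tests compare two independent routes.

rdir <- function(a) {
  x <- rgamma(length(a), a, 1)
  x / sum(x)
}

# Random valid parameters: K topics, feature blocks of the given sizes.
rand_params <- function(K, blocks, C, seed = NULL, eta_sd = 1) {
  if (!is.null(seed)) set.seed(seed)
  Fq <- length(blocks)
  vf <- rep(seq_len(Fq), blocks)
  pi <- t(sapply(seq_len(K), function(k) rdir(rep(1, Fq))))
  pi <- matrix(pi, K, Fq)
  beta <- matrix(0, K, sum(blocks))
  for (f in seq_len(Fq)) {
    b <- which(vf == f)
    for (k in seq_len(K)) beta[k, b] <- rdir(rep(1, length(b)))
  }
  hslda_params(runif(K, 0.3, 1.5), pi, beta,
               matrix(rnorm(C * K, sd = eta_sd), C, K), vf)
}

# Random document consistent with params' vocabulary structure.
rand_doc <- function(N, params, weights = rep(1, N)) {
  vf <- params$value_feature
  v <- sample(seq_along(vf), N, replace = TRUE)
  list(f = vf[v], v = v, w = weights)
}

# Small labeled corpus from the generator, with a guaranteed label per class.
tiny_corpus <- function(seed = 1, D = 20) {
  corp <- sample_corpus(synthetic_spec(preset = "tiny", D = D, seed = seed))
  stopifnot(length(unique(corp$docs$label)) >= 2)
  corp
}

# Two-pass TF-IDF by explicit counting (independent of tfidf_weight()).
tfidf_oracle <- function(corpus, floor = 1e-8) {
  D <- n_docs(corpus)
  toks <- as.data.frame(corpus$tokens)
  key <- paste(toks$doc_id, toks$value, sep = "\r")
  df <- tapply(toks$doc_id, toks$value, function(x) length(unique(x)))
  tf <- table(key)
  w <- numeric(nrow(toks))
  for (i in seq_len(nrow(toks))) {
    wi <- tf[[key[i]]] * log(D / df[[toks$value[i]]])
    w[i] <- if (wi <= 0) floor else wi
  }
  w
}

# Independent three-layer (no feature level) sLDA per-document bound,
# written term by term from the densities.
slda_elbo_oracle <- function(doc, gamma, phi, alpha, beta, eta, label = NULL) {
  K <- length(alpha)
  elog <- digamma(gamma) - digamma(sum(gamma))
  val <- lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * elog) -
    lgamma(sum(gamma)) + sum(lgamma(gamma)) - sum((gamma - 1) * elog)
  N <- length(doc$v)
  if (N == 0) return(val)
  for (n in seq_len(N)) {
    for (i in seq_len(K)) {
      p <- phi[n, i]
      if (p > 0) {
        val <- val + doc$w[n] * p *
          (elog[i] + log(beta[i, doc$v[n]]) - log(p))
      }
    }
  }
  if (!is.null(label)) {
    W <- sum(doc$w)
    phi_bar <- colSums(doc$w * phi) / W
    val <- val + sum(eta[label, ] * phi_bar)
    # log E_q[sum_l prod_n sum_i phi exp(eta w/W)]
    C <- nrow(eta)
    tot <- numeric(C)
    for (l in seq_len(C)) {
      s <- 0
      for (n in seq_len(N)) {
        s <- s + log(sum(phi[n, ] * exp(eta[l, ] * doc$w[n] / W)))
      }
      tot[l] <- s
    }
    m <- max(tot)
    val <- val - (m + log(sum(exp(tot - m))))
  }
  val
}

# Independent unlabeled three-layer sLDA E-step (coordinate ascent written
# from the closed forms, no shared code with the package kernels).
slda_estep_oracle <- function(doc, alpha, beta, iters = 200, tol = 1e-6) {
  K <- length(alpha)
  N <- length(doc$v)
  phi <- matrix(1 / K, N, K)
  gamma <- alpha + sum(doc$w) / K
  prev <- -Inf
  for (it in seq_len(iters)) {
    elog <- digamma(gamma) - digamma(sum(gamma))
    for (n in seq_len(N)) {
      lp <- elog + log(beta[, doc$v[n]])
      p <- exp(lp - max(lp))
      phi[n, ] <- p / sum(p)
    }
    gamma <- alpha + colSums(doc$w * phi)
    cur <- slda_elbo_oracle(doc, gamma, phi, alpha, beta, eta = NULL)
    if (is.finite(prev) && abs(cur - prev) <= tol * abs(prev)) break
    prev <- cur
  }
  list(gamma = gamma, phi = phi,
       phi_bar = colSums(doc$w * phi) / sum(doc$w))
}

# Direct evaluation of the softmax-normalizer expectation
# E_q[sum_l prod_n sum_i phi_{n,i} exp(eta_{l,i} w_n / W)].
direct_resp_normalizer <- function(phi, eta, w) {
  W <- sum(w)
  tot <- 0
  for (l in seq_len(nrow(eta))) {
    pr <- 1
    for (n in seq_len(nrow(phi))) {
      pr <- pr * sum(phi[n, ] * exp(eta[l, ] * w[n] / W))
    }
    tot <- tot + pr
  }
  tot
}

expect_nondecreasing <- function(x, rel_slack = 1e-6) {
  if (length(x) < 2) return(invisible(TRUE))
  ok <- diff(x) >= -rel_slack * abs(x[-length(x)])
  expect_true(all(ok),
              label = sprintf("trace non-decreasing (worst drop %.3g)",
                              suppressWarnings(min(diff(x)))))
}
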