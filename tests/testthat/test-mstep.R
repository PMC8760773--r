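test_that("closed-form topic multinomials equal normalized co-occurrence counts", {
  # hard assignments: phi rows one-hot -> pi/beta are plain count tables
  corp <- tiny_corpus(seed = 13, D = 15)
  idx <- hslda:::corpus_index(corp)
  K <- 2
  set.seed(2)
  states <- lapply(idx$docs, function(d) {
    N <- length(d$v)
    phi <- matrix(0, N, K)
    phi[cbind(seq_len(N), sample.int(K, N, TRUE))] <- 1
    list(gamma = rep(1, K), phi = phi,
         phi_bar = colSums(phi) / max(N, 1))
  })
  mb <- m_step_pi_beta(corp, states, epsilon = 0)
  pi_count <- matrix(0, K, idx$F)
  beta_count <- matrix(0, K, idx$V)
  for (d in seq_along(idx$docs)) {
    doc <- idx$docs[[d]]
    k <- apply(states[[d]]$phi, 1, which.max)
    for (n in seq_along(doc$v)) {
      pi_count[k[n], doc$f[n]] <- pi_count[k[n], doc$f[n]] + 1
      beta_count[k[n], doc$v[n]] <- beta_count[k[n], doc$v[n]] + 1
    }
  }
  expect_equal(mb$pi, pi_count / rowSums(pi_count), tolerance = 1e-12)
  for (f in seq_len(idx$F)) {
    b <- which(idx$vf == f)
    blk <- beta_count[, b] / rowSums(beta_count[, b])
    expect_equal(mb$beta[, b], blk, tolerance = 1e-12)
  }
})

test_that("single point-mass token concentrates its feature and value", {
  voc <- hslda_vocabulary(c("a-x", "a-y", "b-z"), c("a", "a", "b"))
  corp <- hslda_corpus(tibble::tibble(doc_id = "d1", feature = "a",
                                      value = "a-x"),
                       docs = tibble::tibble(doc_id = "d1", label = "A"),
                       vocabulary = voc, class_names = "A")
  states <- list(list(gamma = c(1, 1), phi = matrix(c(1, 0), 1, 2),
                      phi_bar = c(1, 0)))
  mb <- m_step_pi_beta(corp, states, epsilon = 1e-10)
  expect_gt(mb$pi[1, 1], 1 - 1e-8)      # feature "a" under topic 1
  expect_lt(mb$pi[2, 1], 0.51)          # topic 2 saw nothing: uniform-ish
  expect_gt(mb$beta[1, 1], 1 - 1e-8)    # value "a-x" within block "a"
})

test_that("closed forms are stationary points of the bound's pi/beta terms", {
  # random perturbations on the simplex never improve the weighted
  # log-likelihood terms by more than numerical noise
  set.seed(51)
  for (fix in 1:20) {
    corp <- sample_corpus(synthetic_spec(
      preset = "tiny", D = 8, seed = 100 + fix))
    idx <- hslda:::corpus_index(corp)
    K <- 2
    states <- lapply(idx$docs, function(d) {
      phi <- matrix(rgamma(length(d$v) * K, 1), ncol = K)
      phi <- phi / rowSums(phi)
      list(gamma = rep(1, K), phi = phi)
    })
    mb <- m_step_pi_beta(corp, states, epsilon = 1e-10)
    term <- function(pi, beta) {
      tot <- 0
      for (d in seq_along(idx$docs)) {
        doc <- idx$docs[[d]]
        phi <- states[[d]]$phi
        for (n in seq_along(doc$v)) {
          tot <- tot + doc$w[n] * sum(phi[n, ] *
            (log(pi[, doc$f[n]]) + log(beta[, doc$v[n]])))
        }
      }
      tot
    }
    base <- term(mb$pi, mb$beta)
    for (trial in 1:20) {
      eps <- runif(1, 1e-4, 0.05)
      pi2 <- mb$pi; beta2 <- mb$beta
      k <- sample.int(K, 1)
      if (trial %% 2 == 0) {
        j <- sample.int(idx$F, 2)
        move <- min(eps, pi2[k, j[1]] * 0.9)
        pi2[k, j[1]] <- pi2[k, j[1]] - move
        pi2[k, j[2]] <- pi2[k, j[2]] + move
      } else {
        f <- sample.int(idx$F, 1)
        b <- which(idx$vf == f)
        j <- sample(b, 2)
        move <- min(eps, beta2[k, j[1]] * 0.9)
        beta2[k, j[1]] <- beta2[k, j[1]] - move
        beta2[k, j[2]] <- beta2[k, j[2]] + move
      }
      expect_lt(term(pi2, beta2) - base, 1e-7)
    }
  }
})

test_that("class-coefficient gradient matches central finite differences", {
  corp <- tiny_corpus(seed = 19, D = 10)
  idx <- hslda:::corpus_index(corp)
  cfg <- hslda_config(K = 3)
  params <- hslda:::init_params(cfg, idx)
  states <- lapply(idx$docs, function(d)
    doc_e_step(d, params, label = d$label, config = cfg))
  docs <- hslda:::eta_doc_data(idx, states)
  set.seed(6)
  for (lambda in c(0, 0.01)) {
    eta <- matrix(rnorm(idx$C * 3), idx$C, 3)
    ob <- hslda:::eta_objective(eta, docs, lambda)
    h <- 1e-5
    for (i in seq_len(idx$C)) {
      for (j in 1:3) {
        ep <- eta; ep[i, j] <- ep[i, j] + h
        em <- eta; em[i, j] <- em[i, j] - h
        fd <- (hslda:::eta_objective(ep, docs, lambda)$value -
               hslda:::eta_objective(em, docs, lambda)$value) / (2 * h)
        expect_equal(ob$gradient[i, j], fd, tolerance = 1e-5)
      }
    }
  }
})

test_that("symmetric responsibilities give equal class-coefficient rows", {
  # balanced labels with identical topic mixtures: no class is
  # distinguishable, so optimized rows agree (the L2 pull is shared)
  voc <- hslda_vocabulary(c("a-x", "a-y"), c("a", "a"))
  toks <- tibble::tibble(doc_id = rep(c("d1", "d2"), each = 2),
                         feature = "a", value = rep(c("a-x", "a-y"), 2))
  corp <- hslda_corpus(toks,
                       docs = tibble::tibble(doc_id = c("d1", "d2"),
                                             label = c("A", "B")),
                       vocabulary = voc, class_names = c("A", "B"))
  phi <- matrix(0.5, 2, 2)
  states <- list(list(gamma = c(1, 1), phi = phi, phi_bar = c(0.5, 0.5)),
                 list(gamma = c(1, 1), phi = phi, phi_bar = c(0.5, 0.5)))
  eta <- m_step_eta(corp, states, matrix(0, 2, 2), hslda_config(K = 2))
  expect_equal(eta[1, ], eta[2, ], tolerance = 1e-6)
})

test_that("orthogonal one-hot mixtures are separated after optimization", {
  voc <- hslda_vocabulary(c("a-x", "a-y", "a-z"), rep("a", 3))
  toks <- tibble::tibble(doc_id = c("d1", "d2", "d3"), feature = "a",
                         value = c("a-x", "a-y", "a-z"))
  corp <- hslda_corpus(toks,
                       docs = tibble::tibble(doc_id = c("d1", "d2", "d3"),
                                             label = c("A", "B", "C")),
                       vocabulary = voc, class_names = c("A", "B", "C"))
  states <- lapply(1:3, function(d) {
    phi <- matrix(0, 1, 3); phi[1, d] <- 1
    list(gamma = rep(1, 3), phi = phi, phi_bar = phi[1, ])
  })
  eta <- m_step_eta(corp, states, matrix(0, 3, 3), hslda_config(K = 3))
  for (d in 1:3) {
    scores <- eta %*% states[[d]]$phi_bar
    expect_equal(which.max(scores), d)
  }
  # optimization never lowers the penalized objective
  idx <- hslda:::corpus_index(corp)
  docs <- hslda:::eta_doc_data(idx, states)
  expect_gte(hslda:::eta_objective(eta, docs, 0.01)$value,
             hslda:::eta_objective(matrix(0, 3, 3), docs, 0.01)$value)
})
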