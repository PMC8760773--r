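test_that("expected log topic proportions match digamma identities and quadrature", {
  expect_equal(expected_log_theta(c(1, 1)), c(-1, -1))
  g <- rep(2.7, 4)
  expect_true(all(expected_log_theta(g) == expected_log_theta(g)[1]))
  expect_true(all(expected_log_theta(c(0.2, 5, 1)) < 0))
  expect_error(expected_log_theta(c(1, 0)), "positive")
  # quadrature: E[log theta_1] under Dirichlet(0.5, 1.5) via the Beta marginal
  q <- integrate(function(x) log(x) * dbeta(x, 0.5, 1.5), 0, 1)$value
  expect_equal(expected_log_theta(c(0.5, 1.5))[1], q, tolerance = 1e-6)
})

test_that("h linearization agrees with direct evaluation of the normalizer", {
  # eta = 0 -> every exponential is 1 -> h = C for each topic
  phi <- matrix(c(0.2, 0.8, 0.5, 0.5, 1, 0), 3, 2, byrow = TRUE)
  expect_equal(compute_h(phi, matrix(0, 4, 2), rep(1, 3), 2), rep(4, 2))
  # C = 1, N = 1: empty leave-one-out product -> h_i = exp(eta_{1,i})
  eta1 <- matrix(c(0.3, -1.2), 1, 2)
  expect_equal(compute_h(matrix(0.5, 1, 2), eta1, 1, 1),
               as.numeric(exp(eta1)))
  # random instance: h' phi_n must equal the direct normalizer expectation
  set.seed(4)
  for (rep in 1:20) {
    N <- 3; K <- 2; C <- 3
    phi <- t(sapply(seq_len(N), function(i) rdir(rep(1, K))))
    eta <- matrix(rnorm(C * K), C, K)
    w <- rep(1, N)
    for (n in seq_len(N)) {
      h <- compute_h(phi, eta, w, n)
      expect_equal(sum(h * phi[n, ]), direct_resp_normalizer(phi, eta, w),
                   tolerance = 1e-10)
    }
  }
  expect_error(compute_h(phi, eta1, rep(1, 3), 9), "out of range")
})

test_that("gamma update adds weighted responsibilities to alpha", {
  a <- c(0.5, 0.5)
  expect_equal(update_gamma(a, matrix(0, 0, 2)), a)
  phi <- rbind(c(1, 0), c(0, 1))
  expect_equal(update_gamma(a, phi, c(1, 1)), c(1.5, 1.5))
  set.seed(8)
  phi <- matrix(runif(12), 4, 3); phi <- phi / rowSums(phi)
  w <- runif(4, 0.5, 2)
  brute <- c(0.3, 1, 2)
  for (n in 1:4) brute <- brute + w[n] * phi[n, ]
  expect_equal(update_gamma(c(0.3, 1, 2), phi, w), brute)
})

test_that("token update is uniform under symmetric inputs and trivial for K=1", {
  p1 <- hslda_params(1, matrix(1, 1, 1), matrix(c(0.4, 0.6), 1, 2),
                     matrix(0, 2, 1), c(1L, 1L))
  doc <- list(f = 1L, v = 2L, w = 1)
  st <- list(gamma = 2, phi = matrix(1, 1, 1))
  expect_equal(update_phi(st, p1, doc, 1), 1)
  # fully symmetric parameters, no label -> uniform responsibilities
  K <- 3
  psym <- hslda_params(rep(0.7, K), matrix(1 / 2, K, 2),
                       matrix(1 / 2, K, 4), matrix(0, 2, K),
                       c(1L, 1L, 2L, 2L))
  doc2 <- list(f = c(1L, 2L), v = c(1L, 3L), w = c(1, 1))
  st2 <- list(gamma = rep(1.2, K), phi = matrix(1 / K, 2, K))
  expect_equal(update_phi(st2, psym, doc2, 1), rep(1 / K, K))
})

test_that("iterated token update reaches the grid maximum of the restricted bound", {
  # N = 2, K = 2, labeled: iterate the MM update on token 1 to its fixed
  # point, then compare against a 10^4-point sweep of phi_1 in the exact
  # restricted bound (gamma and the other token held fixed).
  set.seed(12)
  params <- rand_params(K = 2, blocks = c(2, 2), C = 2, eta_sd = 1.5)
  doc <- list(f = c(1L, 2L), v = c(2L, 3L), w = c(1, 1))
  phi <- rbind(c(0.3, 0.7), c(0.6, 0.4))
  st <- list(gamma = c(1.1, 0.9), phi = phi)
  for (i in 1:200) {
    newp <- update_phi(st, params, doc, 1, label = 1L)
    if (max(abs(newp - st$phi[1, ])) < 1e-13) break
    st$phi[1, ] <- newp
  }
  grid <- seq(0, 1, length.out = 1e4)
  vals <- vapply(grid, function(t) {
    st2 <- st; st2$phi[1, ] <- c(t, 1 - t)
    elbo_doc(doc, st2, params, label = 1L)
  }, numeric(1))
  at_update <- elbo_doc(doc, st, params, label = 1L)
  expect_gte(at_update, max(vals) - 1e-6)
})

test_that("doc inference handles empty documents and matches a hand-rolled first sweep", {
  params <- rand_params(K = 2, blocks = c(2, 2), C = 2, seed = 3)
  empty <- list(f = integer(0), v = integer(0), w = numeric(0))
  st <- doc_e_step(empty, params)
  expect_equal(st$gamma, params$alpha)
  expect_equal(st$iterations, 0L)
  expect_true(st$empty)
  expect_equal(st$phi_bar, rep(0.5, 2))

  # two-token fixture: reproduce the first sweep by hand (sequential token
  # updates from uniform phi, gamma = alpha + W/K, then the gamma update)
  doc <- list(f = c(1L, 2L), v = c(1L, 4L), w = c(1, 1))
  label <- 2L
  K <- 2; W <- 2
  phi <- matrix(1 / K, 2, K)
  gamma0 <- params$alpha + W / K
  elog <- digamma(gamma0) - digamma(sum(gamma0))
  for (n in 1:2) {
    h <- compute_h(phi, params$eta, doc$w, n)
    lp <- log(params$pi[, doc$f[n]]) + log(params$beta[, doc$v[n]]) + elog +
      params$eta[label, ] / W - h / (sum(h * phi[n, ]) * doc$w[n])
    p <- exp(lp - max(lp))
    phi[n, ] <- p / sum(p)
  }
  gamma1 <- params$alpha + colSums(phi)
  st1 <- doc_e_step(doc, params, label = label,
                    config = hslda_config(K = 2, e_step_max_iters = 1))
  expect_equal(st1$phi, phi, tolerance = 1e-12)
  expect_equal(st1$gamma, gamma1, tolerance = 1e-12)
})

test_that("per-document bound traces are non-decreasing (property)", {
  set.seed(77)
  for (i in 1:60) {
    K <- sample(2:3, 1); C <- sample(2:3, 1)
    params <- rand_params(K, blocks = sample(2:3, 2, TRUE), C, eta_sd = 1.5)
    N <- sample(1:5, 1)
    doc <- rand_doc(N, params)
    label <- if (i %% 2 == 0) sample.int(C, 1) else NULL
    st <- doc_e_step(doc, params, label = label, config = hslda_config(K = K))
    expect_nondecreasing(st$trace, rel_slack = 1e-8)
    # simplex invariants after convergence
    expect_equal(rowSums(st$phi), rep(1, N), tolerance = 1e-10)
    expect_true(all(st$gamma >= params$alpha - 1e-12))
  }
})

test_that("degenerate single-topic bounds have closed forms", {
  # K = 1, C = 1, unit weights: bound reduces to sum of log pi + log beta
  vf <- c(1L, 1L, 2L)
  p <- hslda_params(1, matrix(c(0.3, 0.7), 1, 2),
                    matrix(c(0.2, 0.8, 1), 1, 3), matrix(0.4, 1, 1), vf)
  doc <- list(f = c(1L, 2L), v = c(2L, 3L), w = c(1, 1))
  st <- list(gamma = 3, phi = matrix(1, 2, 1))
  manual <- log(0.3) + log(0.8) + log(0.7) + log(1)
  expect_equal(elbo_doc(doc, st, p), manual)
  # Dirichlet term at alpha = gamma = (1,1) is exactly 0
  p2 <- rand_params(2, c(2, 2), 2, seed = 5)
  p2$alpha <- c(1, 1)
  st2 <- list(gamma = c(1, 1), phi = matrix(0, 0, 2))
  edoc <- list(f = integer(0), v = integer(0), w = numeric(0))
  expect_equal(elbo_doc(edoc, st2, p2), 0)
})

test_that("enumeration oracle matches closed forms and Monte Carlo", {
  # N = 1, uniform pi and beta: evidence is 1/F * 1/|block(f)|
  K <- 2
  p <- hslda_params(c(1, 1), matrix(1 / 2, K, 2), matrix(1 / 2, K, 4),
                    matrix(0, 2, K), c(1L, 1L, 2L, 2L))
  doc1 <- list(f = 1L, v = 2L, w = 1)
  expect_equal(oracle_log_evidence(doc1, p), log(1 / 2 * 1 / 2))
  # N = 2 fixture vs 1e6-draw Monte Carlo estimate of the evidence
  set.seed(41)
  params <- rand_params(2, c(2, 2), 2, eta_sd = 1)
  doc <- list(f = c(1L, 2L), v = c(1L, 3L), w = c(1, 1))
  label <- 1L
  M <- 1e6
  th <- matrix(rgamma(M * 2, rep(params$alpha, each = M)), M, 2)
  th <- th / rowSums(th)
  r1 <- 1L + (runif(M) > th[, 1]); r2 <- 1L + (runif(M) > th[, 1])
  lik <- params$pi[cbind(r1, 1)] * params$beta[cbind(r1, 1)] *
    params$pi[cbind(r2, 2)] * params$beta[cbind(r2, 3)]
  rbar1 <- ((r1 == 1) + (r2 == 1)) / 2
  sc <- cbind(params$eta[1, 1] * rbar1 + params$eta[1, 2] * (1 - rbar1),
              params$eta[2, 1] * rbar1 + params$eta[2, 2] * (1 - rbar1))
  py <- exp(sc[, label]) / (exp(sc[, 1]) + exp(sc[, 2]))
  est <- lik * py
  se <- sd(est) / sqrt(M)
  expect_lt(abs(exp(oracle_log_evidence(doc, params, label)) - mean(est)),
            3 * se)
  expect_error(oracle_log_evidence(list(f = rep(1L, 40), v = rep(1L, 40),
                                        w = rep(1, 40)), params),
               "too large")
})
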