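#' Training configuration
#'
#' Collects every tunable of the variational EM fit. The Dirichlet
#' hyperparameter is set by policy and never re-estimated: either a fixed
#' symmetric value, or the logistic-in-K schedule of [alpha_curve()].
#'
#' @param K Number of topics.
#' @param alpha Either a single positive number (fixed symmetric
#'   hyperparameter) or the string `"curve"` to use
#'   `alpha_curve(K, V, c1, c2)` with the vocabulary size of the training
#'   corpus.
#' @param c1,c2 Constants of the alpha schedule (defaults 0.3 and 0.25).
#' @param epsilon Smoothing floor added to M-step counts (default 1e-10).
#' @param lambda L2 penalty on the class coefficients (default 0.01; 0 is
#'   supported).
#' @param e_step_max_iters,e_step_rel_tol Per-document coordinate-ascent
#'   caps (defaults 100 and 1e-6 relative bound change).
#' @param em_max_iters,em_rel_tol Corpus-level EM caps (defaults 100 and
#'   1e-4).
#' @param cg_max_iters,cg_grad_tol Conjugate-gradient caps for the class
#'   coefficients (defaults 500 and 1e-5 on the gradient infinity-norm).
#' @param n_init Number of seeded EM restarts; the fit with the best final
#'   bound is kept (default 1). The bound is multi-modal in the topic
#'   multinomials, so restarts trade compute for optimum quality exactly as
#'   in other mixture fitters.
#' @param seed Integer seed controlling initialization (restart seeds are
#'   derived from it).
#' @return A list of class `hslda_config`.
#' @export
hslda_config <- function(K = 10, alpha = "curve", c1 = 0.3, c2 = 0.25,
                         epsilon = 1e-10, lambda = 0.01,
                         e_step_max_iters = 100, e_step_rel_tol = 1e-6,
                         em_max_iters = 100, em_rel_tol = 1e-4,
                         cg_max_iters = 500, cg_grad_tol = 1e-5,
                         n_init = 1L, seed = 1L) {
  stopifnot(K >= 1, e_step_max_iters >= 1, em_max_iters >= 1,
            cg_max_iters >= 1, e_step_rel_tol > 0, em_rel_tol > 0,
            cg_grad_tol > 0, epsilon >= 0, lambda >= 0, n_init >= 1)
  if (is.numeric(alpha) && (length(alpha) != 1 || alpha <= 0)) {
    abort("fixed alpha must be a single positive number")
  }
  if (is.character(alpha) && !identical(alpha, "curve")) {
    abort('alpha must be a positive number or "curve"')
  }
  structure(list(
    K = as.integer(K), alpha = alpha, c1 = c1, c2 = c2,
    epsilon = epsilon, lambda = lambda,
    e_step = list(max_iters = as.integer(e_step_max_iters),
                  rel_tol = e_step_rel_tol),
    em = list(max_iters = as.integer(em_max_iters), rel_tol = em_rel_tol),
    cg = list(max_iters = as.integer(cg_max_iters), grad_tol = cg_grad_tol),
    n_init = as.integer(n_init), seed = as.integer(seed)),
    class = "hslda_config")
}

#' Logistic schedule for the Dirichlet hyperparameter
#'
#' `alpha(K) = c1 + 1 / (1 + exp(c2 * (K - V/2)))`: close to `c1 + 1` for
#' few topics, decaying monotonically (for `c2 > 0`) towards `c1` as the
#' topic count passes half the value-vocabulary size.
#'
#' @param K Topic count (`>= 1`).
#' @param V Number of feature-value pairs in the vocabulary (`>= 1`).
#' @param c1,c2 Curve constants; defaults 0.3 and 0.25.
#' @return A positive scalar.
#' @examples
#' alpha_curve(70, 79)          # near c1 for K well past V/2
#' alpha_curve(39.5, 79)        # exactly c1 + 0.5 at the midpoint
#' @export
alpha_curve <- function(K, V, c1 = 0.3, c2 = 0.25) {
  stopifnot(K >= 1, V >= 1)
  c1 + 1 / (1 + exp(c2 * (K - V / 2)))
}

resolve_alpha <- function(config, V) {
  if (identical(config$alpha, "curve")) {
    rep(alpha_curve(config$K, V, config$c1, config$c2), config$K)
  } else {
    rep(as.numeric(config$alpha), config$K)
  }
}

init_params <- function(config, idx, restart = 1L) {
  K <- config$K
  withr::with_seed(derive_seed(config$seed, paste0("init", restart)), {
    pi <- t(vapply(seq_len(K), function(k) rdirichlet1(rep(1, idx$F)),
                   numeric(idx$F)))
    pi <- matrix(pi, K, idx$F)
    beta <- matrix(0, K, idx$V)
    for (f in seq_len(idx$F)) {
      block <- which(idx$vf == f)
      for (k in seq_len(K)) beta[k, block] <- rdirichlet1(rep(1, length(block)))
    }
    hslda_params(resolve_alpha(config, idx$V), pi, beta,
                 matrix(0, idx$C, K), idx$vf)
  })
}

#' Fit the hierarchical supervised topic model
#'
#' Variational Bayes EM: per-document mean-field inference (E-step)
#' alternated with closed-form updates of the topic-feature and topic-value
#' multinomials and a conjugate-gradient update of the class coefficients
#' (M-step), until the corpus bound's relative change falls below
#' `config$em$rel_tol`. The topic-feature/topic-value multinomials are
#' initialized from flat Dirichlet draws (seeded), the class coefficients
#' at zero, and the Dirichlet hyperparameter from the configured policy
#' (never re-estimated).
#'
#' @param corpus A fully labeled [hslda_corpus] with at least as many
#'   documents as classes.
#' @param K Number of topics (overrides `config$K` when given).
#' @param config An [hslda_config].
#' @param baseline One of `"hierarchical"` (default) or `"mslda"`; the
#'   latter flattens the vocabulary to a single feature before fitting (see
#'   [flatten_corpus()]), which makes the fit a multi-class sLDA.
#' @return An object of class `hslda_model`: list with `params`
#'   ([hslda_params]), `vocabulary`, `class_names`, `elbo_trace` (corpus
#'   bound after each E-step), `config`, `variant`, `iterations`,
#'   `converged`, `n_train`.
#' @examples
#' \donttest{
#' corp <- sample_corpus(synthetic_spec(preset = "tiny", seed = 1))
#' fit <- fit_hslda(corp, K = 3, config = hslda_config(em_max_iters = 10))
#' glance(fit)
#' }
#' @export
fit_hslda <- function(corpus, K = NULL, config = hslda_config(),
                      baseline = c("hierarchical", "mslda")) {
  baseline <- match.arg(baseline)
  if (baseline == "mslda") corpus <- flatten_corpus(corpus)
  validate_corpus(corpus)
  if (!is.null(K)) config$K <- as.integer(K)
  idx <- corpus_index(corpus)
  unlab <- vapply(idx$docs, function(d) is.na(d$label), logical(1))
  if (any(unlab)) {
    abort(sprintf("fit requires labeled documents; unlabeled: %s",
                  paste(head(corpus$docs$doc_id[unlab], 5), collapse = ", ")))
  }
  D <- length(idx$docs)
  if (D < idx$C) abort("need at least as many documents as classes")
  winner <- 1L
  if (config$n_init > 1) {
    # short pilot runs; the restart with the best bound is run to
    # convergence (emEM-style initialization selection)
    pilot_cfg <- config
    pilot_cfg$em$max_iters <- min(8L, config$em$max_iters)
    pilot <- vapply(seq_len(config$n_init), function(r)
      tail(fit_em_once(idx, pilot_cfg, r)$trace, 1), numeric(1))
    winner <- which.max(pilot)
  }
  best <- fit_em_once(idx, config, winner)
  if (!best$converged) {
    warn(sprintf("EM did not converge in %d iterations", config$em$max_iters))
  }
  structure(list(params = best$params, vocabulary = corpus$vocabulary,
                 class_names = corpus$class_names, elbo_trace = best$trace,
                 config = config, variant = baseline,
                 iterations = best$iterations, converged = best$converged,
                 n_train = D),
            class = "hslda_model")
}

fit_em_once <- function(idx, config, restart) {
  params <- init_params(config, idx, restart)
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  it <- 0L
  states <- NULL
  for (it in seq_len(config$em$max_iters)) {
    states <- purrr::map(seq_along(idx$docs), function(d)
      doc_e_step(idx$docs[[d]], params, label = idx$docs[[d]]$label,
                 config = config,
                 init = if (it > 1) states[[d]][c("gamma", "phi")]))
    cur <- sum(vapply(states, function(s) s$elbo, numeric(1)))
    trace <- c(trace, cur)
    if (is.finite(prev) && abs(cur - prev) <= config$em$rel_tol * abs(prev)) {
      converged <- TRUE
      break
    }
    prev <- cur
    pb <- m_step_pi_beta_idx(idx, states, config$epsilon)
    eta <- m_step_eta_idx(idx, states, params$eta, config)
    params <- hslda_params(params$alpha, pb$pi, pb$beta, eta, idx$vf)
  }
  list(params = params, trace = trace, iterations = it,
       converged = converged)
}

#' @export
print.hslda_model <- function(x, ...) {
  cat(sprintf(
    "<hslda_model> %s variant: K=%d topics, F=%d, V=%d, C=%d; D=%d docs, %d EM iterations (%s)\n",
    x$variant, x$config$K, ncol(x$params$pi), ncol(x$params$beta),
    nrow(x$params$eta), x$n_train, x$iterations,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Predict diagnosis classes for new documents
#'
#' Runs label-free variational inference per document and scores each class
#' by `eta_c' phi_bar` (the variational expectation of the softmax score);
#' the predicted class is the argmax, ties broken toward the lowest class
#' index. Zero-token documents get a uniform topic mixture and are flagged.
#'
#' @param object An `hslda_model`.
#' @param corpus An [hslda_corpus] over the same vocabulary (labels, if
#'   any, are ignored).
#' @param ... Unused.
#' @return A tibble with one row per document: `doc_id`, `.pred_class`,
#'   one `.score_<class>` column per class, `.empty`, and a `.topics`
#'   list-column holding each document's topic mixture `phi_bar`.
#' @export
predict.hslda_model <- function(object, corpus, ...) {
  validate_corpus(corpus)
  if (!identical(corpus$vocabulary$value, object$vocabulary$value)) {
    abort("corpus vocabulary does not match the model's vocabulary")
  }
  idx <- corpus_index(corpus)
  states <- purrr::map(idx$docs, function(doc)
    doc_e_step(doc, object$params, label = NULL, config = object$config))
  scores <- t(vapply(states, function(s)
    as.numeric(object$params$eta %*% s$phi_bar),
    numeric(nrow(object$params$eta))))
  scores <- matrix(scores, nrow = length(states))
  pred <- apply(scores, 1, which.max)   # which.max ties -> lowest index
  out <- tibble::tibble(
    doc_id = corpus$docs$doc_id,
    .pred_class = object$class_names[pred],
    .empty = vapply(states, function(s) isTRUE(s$empty), logical(1)))
  sc <- tibble::as_tibble(as.data.frame(scores))
  names(sc) <- paste0(".score_", object$class_names)
  out <- dplyr::bind_cols(out, sc)
  out$.topics <- purrr::map(states, "phi_bar")
  out
}

# ---- serialization -----------------------------------------------------

#' Save / load a fitted model as JSON
#'
#' One JSON document holding the configuration, class names, vocabulary
#' (plus a hash of it for integrity checks) and the dense parameter
#' matrices at 17 significant digits, so a write/read round trip is
#' bit-stable.
#'
#' @param model An `hslda_model`.
#' @param path Output path.
#' @return `read_model()` returns the restored `hslda_model`.
#' @export
write_model <- function(model, path) {
  voc <- model$vocabulary
  payload <- list(
    package = "hslda", variant = model$variant,
    config = unclass(model$config),
    class_names = model$class_names,
    vocabulary = list(value = voc$value, feature = voc$feature,
                      features = vocab_features(voc)),
    vocabulary_hash = vocab_hash(voc),
    alpha = model$params$alpha,
    pi = model$params$pi, beta = model$params$beta, eta = model$params$eta,
    value_feature = model$params$value_feature,
    elbo_trace = model$elbo_trace, iterations = model$iterations,
    converged = model$converged, n_train = model$n_train)
  jsonlite::write_json(payload, path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(model)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  voc <- hslda_vocabulary(p$vocabulary$value, p$vocabulary$feature,
                          feature_levels = p$vocabulary$features)
  if (!identical(vocab_hash(voc), p$vocabulary_hash)) {
    warn("vocabulary hash mismatch in model file")
  }
  cfg <- do.call(hslda_config, c(
    p$config[c("K", "alpha", "c1", "c2", "epsilon", "lambda", "seed")],
    list(e_step_max_iters = p$config$e_step$max_iters,
         e_step_rel_tol = p$config$e_step$rel_tol,
         em_max_iters = p$config$em$max_iters,
         em_rel_tol = p$config$em$rel_tol,
         cg_max_iters = p$config$cg$max_iters,
         cg_grad_tol = p$config$cg$grad_tol)))
  params <- hslda_params(p$alpha, matrix(unlist(p$pi), nrow = length(p$alpha)),
                         matrix(unlist(p$beta), nrow = length(p$alpha)),
                         matrix(unlist(p$eta), ncol = length(p$alpha)),
                         p$value_feature)
  structure(list(params = params, vocabulary = voc,
                 class_names = p$class_names, elbo_trace = p$elbo_trace,
                 config = cfg, variant = p$variant,
                 iterations = p$iterations, converged = p$converged,
                 n_train = p$n_train),
            class = "hslda_model")
}

vocab_hash <- function(voc) {
  s <- paste(voc$value, voc$feature, sep = "\r", collapse = "\n")
  x <- utf8ToInt(s)
  h <- 5381
  for (chunk in split(x, ceiling(seq_along(x) / 512))) {
    h <- sum((h * 33 + chunk) * seq_along(chunk)) %% 2147483647
  }
  sprintf("%d:%d", length(x), as.integer(h))
}

# ---- broom-style methods ----------------------------------------------

#' Tidy a fitted model's parameter matrices
#'
#' @param x An `hslda_model`.
#' @param matrix Which parameter block to return: `"beta"` (topic-value,
#'   default), `"pi"` (topic-feature) or `"eta"` (class coefficients).
#' @param ... Unused.
#' @return A long tibble: for `"beta"`, columns `topic`, `feature`,
#'   `value`, `beta`; for `"pi"`, columns `topic`, `feature`, `pi`; for
#'   `"eta"`, columns `class`, `topic`, `eta`.
#' @export
tidy.hslda_model <- function(x, matrix = c("beta", "pi", "eta"), ...) {
  matrix <- match.arg(matrix)
  K <- x$config$K
  voc <- x$vocabulary
  switch(matrix,
    beta = tibble::tibble(
      topic = rep(seq_len(K), times = nrow(voc)),
      feature = rep(voc$feature, each = K),
      value = rep(voc$value, each = K),
      beta = as.numeric(x$params$beta)),
    pi = tibble::tibble(
      topic = rep(seq_len(K), times = ncol(x$params$pi)),
      feature = rep(vocab_features(voc), each = K),
      pi = as.numeric(x$params$pi)),
    eta = tibble::tibble(
      class = rep(x$class_names, times = K),
      topic = rep(seq_len(K), each = length(x$class_names)),
      eta = as.numeric(x$params$eta)))
}

#' One-row fit summary
#'
#' @param x An `hslda_model`.
#' @param ... Unused.
#' @return A tibble with `K`, `F`, `V`, `C`, `n_train`, `elbo`,
#'   `iterations`, `converged`, `variant`.
#' @export
glance.hslda_model <- function(x, ...) {
  tibble::tibble(
    K = x$config$K, F = ncol(x$params$pi), V = ncol(x$params$beta),
    C = nrow(x$params$eta), n_train = x$n_train,
    elbo = x$elbo_trace[length(x$elbo_trace)],
    iterations = x$iterations, converged = x$converged, variant = x$variant)
}
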