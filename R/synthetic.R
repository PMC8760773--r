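#' Specification of a synthetic corpus
#'
#' Describes a draw from the model's own generative process, used to test
#' every pipeline stage without real data. Two presets mirror common
#' shapes: `"tiny"` (fast unit-test scale), `"separable"` (well-separated
#' classes: strong orthogonal class coefficients) and `"chd-like"`, which
#' mirrors the shape of a coronary-heart-disease discharge-record corpus:
#' 420 documents, 34 features owning 79 values (blocks of 2-3), 4 classes
#' with prior (0.631, 0.233, 0.029, 0.107), 25-34 tokens per document.
#'
#' @param K Topic count.
#' @param F Feature count (ignored when `values_per_feature` is given with
#'   names).
#' @param values_per_feature Integer vector of block sizes (length `F`).
#' @param D Number of documents.
#' @param tokens_per_doc Length-2 integer range (min, max) of tokens per
#'   document, drawn uniformly.
#' @param C Number of classes.
#' @param alpha Symmetric Dirichlet hyperparameter for topic proportions.
#' @param concentration_pi,concentration_beta Dirichlet concentrations for
#'   sampling the topic-feature and topic-value multinomials (small values
#'   give peaky, well-identified topics).
#' @param eta_scale Class-separation multiplier on the orthogonalized class
#'   coefficient rows (0 gives label noise independent of topics).
#' @param class_prior Length-`C` simplex added as a log offset to the
#'   softmax scores, so imbalanced cohorts are reproducible; uniform by
#'   default.
#' @param seed Integer seed.
#' @param preset Optional shortcut: `"tiny"`, `"separable"`, `"chd-like"`.
#'   Explicit arguments override preset fields.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(K = 3, F = 4, values_per_feature = c(3, 2, 3, 2),
                           D = 60, tokens_per_doc = c(5, 10), C = 3,
                           alpha = 0.5, concentration_pi = 0.3,
                           concentration_beta = 0.3, eta_scale = 8,
                           class_prior = NULL, seed = 1L, preset = NULL) {
  spec <- list(K = K, F = F, values_per_feature = values_per_feature, D = D,
               tokens_per_doc = tokens_per_doc, C = C, alpha = alpha,
               concentration_pi = concentration_pi,
               concentration_beta = concentration_beta,
               eta_scale = eta_scale, class_prior = class_prior, seed = seed)
  if (!is.null(preset)) {
    pre <- switch(preset,
      "tiny" = list(),
      "separable" = list(K = 3, F = 5, values_per_feature = rep(3, 5),
                         D = 300, tokens_per_doc = c(20, 40), C = 3,
                         alpha = 0.5, concentration_pi = 0.2,
                         concentration_beta = 0.2, eta_scale = 30),
      "chd-like" = list(K = 10, F = 34,
                        values_per_feature = rep(c(3L, 2L), c(11, 23)),
                        D = 420, tokens_per_doc = c(25, 34), C = 4,
                        alpha = 0.5, concentration_pi = 0.3,
                        concentration_beta = 0.3, eta_scale = 5,
                        class_prior = c(0.631, 0.233, 0.029, 0.107)),
      abort(sprintf("unknown preset '%s'", preset)))
    supplied <- names(match.call())[-1]
    for (nm in setdiff(names(pre), supplied)) spec[[nm]] <- pre[[nm]]
  }
  spec$F <- length(spec$values_per_feature)
  spec$class_prior <- spec$class_prior %||% rep(1 / spec$C, spec$C)
  stopifnot(spec$K >= 1, spec$D >= 1, spec$C >= 1, spec$alpha > 0,
            all(spec$values_per_feature >= 1),
            length(spec$tokens_per_doc) == 2,
            spec$tokens_per_doc[1] >= 1,
            spec$tokens_per_doc[2] >= spec$tokens_per_doc[1],
            length(spec$class_prior) == spec$C,
            abs(sum(spec$class_prior) - 1) < 1e-8)
  structure(spec, class = "synthetic_spec")
}

#' Sample ground-truth model parameters
#'
#' Topic-feature rows are Dirichlet draws with concentration
#' `concentration_pi`; each `(topic, feature)` block of the topic-value
#' matrix is a Dirichlet draw with concentration `concentration_beta`;
#' class-coefficient rows are random Gaussian vectors orthogonalized
#' against each other (when `C <= K`) and scaled by `eta_scale`.
#' Deterministic under `spec$seed`.
#'
#' @param spec A [synthetic_spec].
#' @return An [hslda_params].
#' @export
sample_params <- function(spec) {
  K <- spec$K; Fq <- spec$F; C <- spec$C
  vf <- rep(seq_len(Fq), spec$values_per_feature)
  V <- length(vf)
  withr::with_seed(derive_seed(spec$seed, "params"), {
    pi <- t(vapply(seq_len(K), function(k)
      rdirichlet1(rep(spec$concentration_pi, Fq)), numeric(Fq)))
    pi <- matrix(pi, K, Fq)
    beta <- matrix(0, K, V)
    for (f in seq_len(Fq)) {
      block <- which(vf == f)
      for (k in seq_len(K)) {
        beta[k, block] <- rdirichlet1(rep(spec$concentration_beta,
                                          length(block)))
      }
    }
    eta <- matrix(stats::rnorm(C * K, sd = 0.3), C, K)
    if (spec$eta_scale == 0) {
      eta <- matrix(0, C, K)
    } else {
      if (C <= K) {
        # anchor class c on topic c before orthogonalizing, so every class
        # owns a region of the topic simplex
        eta <- eta + 3 * diag(1, C, K)
        q <- qr.Q(qr(t(eta)))          # K x C, orthonormal columns
        eta <- t(q) * sign(diag(q)[seq_len(C)])
      } else {
        eta <- eta / sqrt(rowSums(eta^2))
      }
      eta <- eta * spec$eta_scale
    }
    hslda_params(rep(spec$alpha, K), pi, beta, eta, vf)
  })
}

#' Sample a labeled corpus from the generative process
#'
#' Per document: topic proportions `theta ~ Dirichlet(alpha)`; per token:
#' topic `r_n ~ Mult(theta)`, feature `f_n ~ Mult(pi[r_n, ])`, value
#' `v_n ~ Mult(beta[r_n, block(f_n)])`; the class label is drawn from
#' `softmax(eta %*% rbar + log(class_prior))` where `rbar` is the empirical
#' mean of the realized one-hot topic assignments (with a uniform
#' `class_prior` this is exactly the model's softmax GLM). Tokens have unit
#' weight. The ground truth (`params`, `theta`, `r`, `rbar`, class
#' probabilities) is attached as `attr(corpus, "truth")`.
#'
#' @param spec A [synthetic_spec].
#' @param params Optional [hslda_params] (defaults to
#'   `sample_params(spec)`).
#' @return An [hslda_corpus] with a `truth` attribute.
#' @examples
#' corp <- sample_corpus(synthetic_spec(preset = "tiny", seed = 7))
#' n_docs(corp)
#' @export
sample_corpus <- function(spec, params = NULL) {
  params <- params %||% sample_params(spec)
  K <- spec$K; C <- spec$C
  vf <- params$value_feature
  feat_names <- sprintf("f%02d", seq_len(spec$F))
  val_names <- sprintf("%s-v%d", feat_names[vf],
                       unlist(lapply(spec$values_per_feature, seq_len)))
  voc <- hslda_vocabulary(val_names, feat_names[vf],
                          feature_levels = feat_names)
  class_names <- sprintf("C%d", seq_len(C))
  blocks <- split(seq_along(vf), vf)
  withr::with_seed(derive_seed(spec$seed, "corpus"), {
    theta <- matrix(0, spec$D, K)
    rbar <- matrix(0, spec$D, K)
    labels <- character(spec$D)
    r_list <- vector("list", spec$D)
    tok_rows <- vector("list", spec$D)
    doc_ids <- sprintf("doc%04d", seq_len(spec$D))
    for (d in seq_len(spec$D)) {
      th <- rdirichlet1(rep(spec$alpha, K))
      N <- sample(seq(spec$tokens_per_doc[1], spec$tokens_per_doc[2]), 1)
      r <- sample.int(K, N, replace = TRUE, prob = th)
      f <- vapply(r, function(k)
        sample.int(spec$F, 1, prob = params$pi[k, ]), integer(1))
      v <- vapply(seq_len(N), function(n) {
        b <- blocks[[f[n]]]
        b[sample.int(length(b), 1, prob = params$beta[r[n], b])]
      }, integer(1))
      rb <- tabulate(r, K) / N
      sc <- as.numeric(params$eta %*% rb) + log(spec$class_prior)
      p <- exp(sc - logsumexp(sc))
      y <- sample.int(C, 1, prob = p)
      theta[d, ] <- th; rbar[d, ] <- rb; r_list[[d]] <- r
      labels[d] <- class_names[y]
      tok_rows[[d]] <- tibble::tibble(doc_id = doc_ids[d],
                                      feature = feat_names[f],
                                      value = val_names[v], weight = 1)
    }
  })
  corpus <- hslda_corpus(dplyr::bind_rows(tok_rows),
                         docs = tibble::tibble(doc_id = doc_ids,
                                               label = labels),
                         vocabulary = voc, class_names = class_names)
  attr(corpus, "truth") <- list(params = params, theta = theta, rbar = rbar,
                                r = r_list, spec = spec)
  corpus
}
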