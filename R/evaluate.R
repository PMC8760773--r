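# Cross-validated classification metrics and risk stratification.

#' Stratified k-fold split
#'
#' Partitions document indices into `folds` test folds, stratified by class
#' so per-class fold sizes differ by at most one; deterministic under
#' `seed`.
#'
#' @param corpus A fully labeled [hslda_corpus].
#' @param folds Number of folds (`>= 2`); every class must have at least
#'   `folds` documents.
#' @param seed Integer seed.
#' @return A list of `folds` elements, each `list(train, test)` of
#'   document indices; test folds are disjoint and exhaustive.
#' @export
stratified_kfold <- function(corpus, folds = 5, seed = 1L) {
  stopifnot(folds >= 2)
  lab <- corpus$docs$label
  if (anyNA(lab)) abort("stratified_kfold requires labeled documents")
  counts <- table(factor(lab, levels = corpus$class_names))
  small <- counts < folds
  if (any(small)) {
    abort(sprintf("class '%s' has %d < %d documents",
                  names(counts)[small][1], counts[small][1], folds))
  }
  assign <- integer(length(lab))
  withr::with_seed(derive_seed(seed, "folds"), {
    for (cl in corpus$class_names) {
      ids <- sample(which(lab == cl))
      assign[ids] <- rep_len(seq_len(folds), length(ids))
    }
  })
  purrr::map(seq_len(folds), function(f)
    list(train = which(assign != f), test = which(assign == f)))
}

subset_corpus <- function(corpus, ids) {
  keep_docs <- corpus$docs[ids, , drop = FALSE]
  toks <- corpus$tokens[corpus$tokens$doc_id %in% keep_docs$doc_id, , drop = FALSE]
  structure(list(tokens = toks, docs = keep_docs,
                 vocabulary = corpus$vocabulary,
                 class_names = corpus$class_names),
            class = "hslda_corpus")
}

#' Macro-averaged classification metrics
#'
#' Accuracy plus unweighted class-wise means of precision, recall and F1
#' (macro-F1 is the mean of per-class F1 scores, not the F1 of the macro
#' precision/recall; `0/0` is defined as 0). All metrics are on the
#' percentage scale at full precision.
#'
#' @param truth,predicted Character vectors of class names (equal length).
#' @param class_names Ordered class names defining the confusion matrix
#'   layout (rows = truth, columns = predicted).
#' @return A list of class `hslda_metrics`: `metrics` (one-row tibble with
#'   `accuracy`, `macro_precision`, `macro_recall`, `macro_f1`),
#'   `per_class` (tibble with per-class `precision`, `recall`, `f1`,
#'   `support`), and `confusion` (integer matrix).
#' @examples
#' macro_metrics(c("a", "a", "b", "b"), c("a", "b", "b", "b"), c("a", "b"))
#' @export
macro_metrics <- function(truth, predicted, class_names) {
  if (length(truth) != length(predicted) || length(truth) == 0) {
    abort("truth and predicted must be non-empty and of equal length")
  }
  tf <- factor(truth, levels = class_names)
  pf <- factor(predicted, levels = class_names)
  if (anyNA(tf) || anyNA(pf)) abort("labels outside class_names")
  cm <- table(truth = tf, predicted = pf)
  cm <- matrix(as.integer(cm), nrow = length(class_names),
               dimnames = list(truth = class_names, predicted = class_names))
  tp <- diag(cm)
  prec <- unname(ifelse(colSums(cm) > 0, tp / colSums(cm), 0))
  rec <- unname(ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0))
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(
    metrics = tibble::tibble(
      accuracy = 100 * sum(tp) / sum(cm),
      macro_precision = 100 * mean(prec),
      macro_recall = 100 * mean(rec),
      macro_f1 = 100 * mean(f1)),
    per_class = tibble::tibble(class = class_names,
                               precision = 100 * prec, recall = 100 * rec,
                               f1 = 100 * f1, support = rowSums(cm)),
    confusion = cm), class = "hslda_metrics")
}

#' @export
print.hslda_metrics <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("accuracy %.2f | macro-P %.2f | macro-R %.2f | macro-F1 %.2f\n",
              m$accuracy, m$macro_precision, m$macro_recall, m$macro_f1))
  print(x$confusion)
  invisible(x)
}

#' Cross-validated training and evaluation
#'
#' Stratified k-fold protocol: per fold, optionally SMOTE-balance the
#' training fold only (`smote_in_fold = TRUE`, the leakage-safe default) or
#' balance the whole corpus before splitting (`smote_in_fold = FALSE`,
#' reproducing protocols that report balanced totals), fit the model on
#' the training documents, predict the test fold, and compute
#' [macro_metrics()]. Metrics are averaged across folds; confusion
#' matrices are summed.
#'
#' @param corpus A fully labeled [hslda_corpus].
#' @param config An [hslda_config].
#' @param folds Number of folds (default 5).
#' @param seed Integer seed (drives the split and, offset per fold, the
#'   fits).
#' @param smote Apply SMOTE balancing (default `FALSE`).
#' @param smote_k SMOTE neighborhood size.
#' @param smote_in_fold Balance inside the training fold only (default
#'   `TRUE`).
#' @param baseline Passed to [fit_hslda()].
#' @return A list of class `hslda_cv`: `fold_metrics` (one row per fold),
#'   `mean_metrics` (across-fold means), `confusion` (summed), `folds`,
#'   `predictions` (per-document tibble with fold, truth, prediction).
#' @export
cross_validate <- function(corpus, config = hslda_config(), folds = 5,
                           seed = 1L, smote = FALSE, smote_k = 5,
                           smote_in_fold = TRUE,
                           baseline = c("hierarchical", "mslda")) {
  baseline <- match.arg(baseline)
  validate_corpus(corpus)
  if (smote && !smote_in_fold) {
    corpus <- smote_oversample(corpus, k_neighbors = smote_k,
                               seed = derive_seed(seed, "smote-pre"))
  }
  split <- stratified_kfold(corpus, folds = folds, seed = seed)
  fold_rows <- vector("list", folds)
  pred_rows <- vector("list", folds)
  cm_total <- NULL
  for (f in seq_along(split)) {
    train <- subset_corpus(corpus, split[[f]]$train)
    test <- subset_corpus(corpus, split[[f]]$test)
    if (smote && smote_in_fold) {
      train <- smote_oversample(train, k_neighbors = smote_k,
                                seed = derive_seed(seed, paste0("smote", f)))
    }
    cfg <- config
    cfg$seed <- derive_seed(seed, paste0("fold", f))
    fit <- fit_hslda(train, config = cfg, baseline = baseline)
    preds <- predict(fit, test)
    mm <- macro_metrics(test$docs$label, preds$.pred_class,
                        corpus$class_names)
    fold_rows[[f]] <- dplyr::bind_cols(tibble::tibble(fold = f), mm$metrics)
    pred_rows[[f]] <- tibble::tibble(fold = f, doc_id = test$docs$doc_id,
                                     truth = test$docs$label,
                                     predicted = preds$.pred_class)
    cm_total <- if (is.null(cm_total)) mm$confusion else cm_total + mm$confusion
  }
  fold_metrics <- dplyr::bind_rows(fold_rows)
  structure(list(
    fold_metrics = fold_metrics,
    mean_metrics = dplyr::summarise(fold_metrics, dplyr::across(
      c("accuracy", "macro_precision", "macro_recall", "macro_f1"), mean)),
    confusion = cm_total, folds = split,
    predictions = dplyr::bind_rows(pred_rows)), class = "hslda_cv")
}

#' @export
print.hslda_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, across-fold means:\n",
              nrow(x$fold_metrics)))
  print(x$mean_metrics)
  invisible(x)
}

#' @param x An `hslda_cv`.
#' @param ... Unused.
#' @describeIn cross_validate per-fold metric rows as a tibble.
#' @export
tidy.hslda_cv <- function(x, ...) x$fold_metrics

#' @describeIn cross_validate one-row across-fold summary.
#' @export
glance.hslda_cv <- function(x, ...) x$mean_metrics

#' Topic-based risk stratification table
#'
#' For each class, topics are ranked by their class coefficient; the top
#' `top_topics` form the high-risk tier and the bottom `top_topics` the
#' low-risk tier. Within a tier, feature-value pairs are scored by the
#' tier topics' generative mass on them,
#' `sum_k w_k * beta[k, v] * pi[k, feature(v)]` with softplus-normalized
#' topic weights `w_k`, and the `top_pairs` best-scoring names are
#' reported. This tier construction is a reconstruction: it is one
#' defensible reading of "top risk factors per tier", not a canonical
#' definition.
#'
#' @param model An `hslda_model`.
#' @param top_topics Tier size in topics (`2 * top_topics <= K`).
#' @param top_pairs Number of feature-value pairs reported per tier.
#' @return A tibble of class `hslda_risk`: columns `class`, `tier`
#'   (`"high"`/`"low"`), `rank`, `value`, `feature`, `topic` (the tier
#'   topic contributing most to the pair), `score`.
#' @export
risk_factor_table <- function(model, top_topics = 1, top_pairs = 5) {
  K <- model$config$K
  if (2 * top_topics > K) abort("2 * top_topics must not exceed K")
  voc <- model$vocabulary
  vf <- model$params$value_feature
  gen_mass <- model$params$beta *
    model$params$pi[, vf, drop = FALSE]           # K x V
  rows <- list()
  for (ci in seq_along(model$class_names)) {
    etac <- model$params$eta[ci, ]
    ord <- order(etac, decreasing = TRUE)
    tiers <- list(high = ord[seq_len(top_topics)],
                  low = rev(ord)[seq_len(top_topics)])
    for (tier in names(tiers)) {
      ks <- tiers[[tier]]
      w <- softplus(etac[ks])
      w <- (w + 1e-12) / sum(w + 1e-12)
      sc <- as.numeric(w %*% gen_mass[ks, , drop = FALSE])
      top <- order(sc, decreasing = TRUE)[seq_len(min(top_pairs, length(sc)))]
      contrib <- (w * gen_mass[ks, top, drop = FALSE])
      best_k <- ks[apply(matrix(contrib, nrow = length(ks)), 2, which.max)]
      rows[[length(rows) + 1]] <- tibble::tibble(
        class = model$class_names[ci], tier = tier,
        rank = seq_along(top), value = voc$value[top],
        feature = voc$feature[top], topic = best_k, score = sc[top])
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("hslda_risk", class(out))
  out
}

#' Permutation-aligned topic recovery error
#'
#' Compares two parameter sets over the same vocabulary by searching all
#' topic permutations for the one minimizing the mean row-wise total
#' variation (TV) distance, averaged over the topic-feature rows and every
#' `(topic, feature-block)` row of the topic-value matrix. Used to measure
#' how well a fit recovers known generating parameters.
#'
#' @param truth,fitted [hslda_params] objects with equal dimensions.
#' @return A list with `tv_pi`, `tv_beta`, `tv_mean` (aligned means) and
#'   `permutation` (fitted topic order matched to truth).
#' @export
recovery_error <- function(truth, fitted) {
  K <- length(truth$alpha)
  stopifnot(length(fitted$alpha) == K,
            identical(dim(truth$beta), dim(fitted$beta)))
  vf <- truth$value_feature
  blocks <- split(seq_along(vf), vf)
  perms <- permutations_of(K)
  best <- NULL
  for (p in perms) {
    tv_pi <- mean(0.5 * rowSums(abs(truth$pi - fitted$pi[p, , drop = FALSE])))
    tv_b <- mean(vapply(blocks, function(b)
      mean(0.5 * rowSums(abs(truth$beta[, b, drop = FALSE] -
                             fitted$beta[p, b, drop = FALSE]))),
      numeric(1)))
    m <- (tv_pi + tv_b) / 2
    if (is.null(best) || m < best$tv_mean) {
      best <- list(tv_pi = tv_pi, tv_beta = tv_b, tv_mean = m,
                   permutation = p)
    }
  }
  best
}

permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in permutations_of(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- as.integer(append(p, n, after = pos - 1L))
    }
  }
  out
}
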