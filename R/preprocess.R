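# Raw tabular patient data -> weighted feature-value corpus.

#' Guideline-driven binning specification
#'
#' Declares, per raw feature, either a categorical pass-through with its
#' admissible levels or an ordered set of half-open numeric bins
#' `[lo, hi)` with value labels (e.g. `"norm."` / `"Abn."`), the way
#' clinical lab-test guidelines discretize measurements.
#'
#' @param features A named list; each element is a list with `type`
#'   (`"categorical"` or `"numeric"`) and either `levels` (character) or
#'   `bins` (list of `list(label, lo, hi)` with strictly increasing,
#'   non-overlapping intervals).
#' @return A list of class `binning_spec`.
#' @examples
#' binning_spec(list(
#'   heart_rate = list(type = "numeric",
#'                     bins = list(list(label = "norm.", lo = 60, hi = 100),
#'                                 list(label = "Abn.", lo = 100, hi = 300))),
#'   sex = list(type = "categorical", levels = c("Male", "Female"))
#' ))
#' @export
binning_spec <- function(features) {
  stopifnot(is.list(features), length(features) >= 1,
            !is.null(names(features)), all(nzchar(names(features))))
  for (nm in names(features)) {
    f <- features[[nm]]
    if (identical(f$type, "categorical")) {
      if (length(f$levels) < 1) abort(sprintf("feature '%s': categorical needs levels", nm))
      if (anyDuplicated(f$levels)) abort(sprintf("feature '%s': duplicate levels", nm))
    } else if (identical(f$type, "numeric")) {
      if (length(f$bins) < 1) abort(sprintf("feature '%s': numeric needs bins", nm))
      lo <- vapply(f$bins, function(b) as.numeric(b$lo), numeric(1))
      hi <- vapply(f$bins, function(b) as.numeric(b$hi), numeric(1))
      if (any(hi <= lo)) abort(sprintf("feature '%s': bins must have lo < hi", nm))
      if (is.unsorted(lo, strictly = TRUE) || any(lo[-1] < hi[-length(hi)])) {
        abort(sprintf("feature '%s': bins must be increasing and disjoint", nm))
      }
      labs <- vapply(f$bins, function(b) as.character(b$label), character(1))
      if (anyDuplicated(labs)) abort(sprintf("feature '%s': duplicate bin labels", nm))
    } else {
      abort(sprintf("feature '%s': type must be categorical or numeric", nm))
    }
  }
  structure(list(features = features), class = "binning_spec")
}

#' @rdname binning_spec
#' @param path A YAML file with a top-level `features` mapping.
#' @export
read_binning_spec <- function(path) {
  y <- yaml::read_yaml(path)
  binning_spec(y$features %||% y)
}

spec_value_labels <- function(f) {
  if (identical(f$type, "categorical")) f$levels
  else vapply(f$bins, function(b) as.character(b$label), character(1))
}

#' Discretize a raw patient table into a feature-value corpus
#'
#' Each row becomes one document with exactly one token per specified
#' feature; numeric columns are mapped to the guideline bin containing the
#' value, categorical columns are passed through. Value names are composed
#' as `<feature>-<label>` and the vocabulary follows the specification
#' order, so the mapping is deterministic. Missing cells are rejected:
#' imputation (e.g. random-forest) is a pluggable upstream hook.
#'
#' @param raw_table A data frame, one row per patient record. An optional
#'   `doc_id` column names documents, an optional `label` column carries
#'   the class.
#' @param spec A [binning_spec].
#' @param impute Optional function applied to `raw_table` before
#'   discretization (takes and returns the raw table).
#' @param class_names Optional ordered class names.
#' @return An [hslda_corpus] with unit token weights.
#' @export
discretize <- function(raw_table, spec, impute = NULL, class_names = NULL) {
  stopifnot(inherits(spec, "binning_spec"))
  raw_table <- tibble::as_tibble(raw_table)
  if (!is.null(impute)) raw_table <- tibble::as_tibble(impute(raw_table))
  feats <- names(spec$features)
  missing_cols <- setdiff(feats, names(raw_table))
  if (length(missing_cols) > 0) {
    abort(sprintf("raw table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  doc_id <- if ("doc_id" %in% names(raw_table)) as.character(raw_table$doc_id)
            else sprintf("doc%04d", seq_len(nrow(raw_table)))
  label <- if ("label" %in% names(raw_table)) as.character(raw_table$label)
           else NA_character_
  vocab_vals <- character(0); vocab_feats <- character(0)
  for (nm in feats) {
    labs <- spec_value_labels(spec$features[[nm]])
    vocab_vals <- c(vocab_vals, paste(nm, labs, sep = "-"))
    vocab_feats <- c(vocab_feats, rep(nm, length(labs)))
  }
  voc <- hslda_vocabulary(vocab_vals, vocab_feats, feature_levels = feats)
  tok_rows <- vector("list", length(feats))
  for (j in seq_along(feats)) {
    nm <- feats[j]
    f <- spec$features[[nm]]
    col <- raw_table[[nm]]
    if (anyNA(col)) {
      abort(sprintf(
        "missing value in column '%s' (row %d): impute upstream via the `impute` hook",
        nm, which(is.na(col))[1]))
    }
    if (identical(f$type, "categorical")) {
      bad <- !(as.character(col) %in% f$levels)
      if (any(bad)) {
        abort(sprintf("row %d, column '%s': level '%s' not in spec",
                      which(bad)[1], nm, as.character(col)[bad][1]))
      }
      lab <- as.character(col)
    } else {
      x <- as.numeric(col)
      lo <- vapply(f$bins, function(b) as.numeric(b$lo), numeric(1))
      hi <- vapply(f$bins, function(b) as.numeric(b$hi), numeric(1))
      bin <- rep(NA_integer_, length(x))
      for (b in seq_along(lo)) bin[x >= lo[b] & x < hi[b]] <- b
      if (anyNA(bin)) {
        i <- which(is.na(bin))[1]
        abort(sprintf("row %d, column '%s': value %g outside all bins",
                      i, nm, x[i]))
      }
      lab <- spec_value_labels(f)[bin]
    }
    tok_rows[[j]] <- tibble::tibble(doc_id = doc_id, feature = nm,
                                    value = paste(nm, lab, sep = "-"),
                                    weight = 1)
  }
  tokens <- dplyr::bind_rows(tok_rows)
  tokens <- tokens[order(match(tokens$doc_id, doc_id)), ]
  hslda_corpus(tokens,
               docs = tibble::tibble(doc_id = doc_id, label = label),
               vocabulary = voc, class_names = class_names)
}

#' TF-IDF token weighting
#'
#' Replaces each token's weight by `tf * ln(D / df)`, where `tf` is the
#' within-document count of that `(feature, value)` pair and `df` the
#' number of documents containing it. Weights that come out non-positive
#' (pairs present in every document have `idf = 0`) are floored at `1e-8`
#' so the weighted likelihood stays defined. The support (pattern of
#' positive weights) is unchanged, which makes the operation idempotent on
#' it. The input corpus is not modified.
#'
#' @param corpus An [hslda_corpus] with `D > 0`.
#' @param floor Replacement for non-positive weights (default `1e-8`).
#' @return A new [hslda_corpus] with reweighted tokens.
#' @export
tfidf_weight <- function(corpus, floor = 1e-8) {
  validate_corpus(corpus)
  D <- n_docs(corpus)
  if (D == 0) abort("tfidf_weight needs a non-empty corpus")
  toks <- corpus$tokens
  df_tab <- toks |>
    dplyr::distinct(.data$doc_id, .data$value) |>
    dplyr::count(.data$value, name = "df")
  tf_tab <- toks |>
    dplyr::count(.data$doc_id, .data$value, name = "tf")
  toks <- toks |>
    dplyr::left_join(df_tab, by = "value") |>
    dplyr::left_join(tf_tab, by = c("doc_id", "value")) |>
    dplyr::mutate(weight = .data$tf * log(D / .data$df),
                  weight = ifelse(.data$weight <= 0, floor, .data$weight)) |>
    dplyr::select("doc_id", "feature", "value", "weight")
  hslda_corpus(toks, docs = corpus$docs, vocabulary = corpus$vocabulary,
               class_names = corpus$class_names)
}

#' SMOTE minority-class oversampling
#'
#' Balances every class up to the majority-class count with synthetic
#' documents interpolated in the dense per-document weight space over the
#' `V` values: a synthetic point is `x + u * (x_nn - x)` with
#' `u ~ Uniform(0, 1)` and `x_nn` one of the `k` nearest same-class
#' neighbors of a randomly chosen parent `x` (Euclidean distance;
#' `k = min(k_neighbors, class size - 1)`, and a singleton class is
#' duplicated). Positive coordinates of the synthetic vector become tokens.
#' Original documents are never altered; the output has exactly
#' `C * max(class count)` documents. Deterministic under `seed`.
#'
#' @param corpus A fully labeled [hslda_corpus]; every class must have at
#'   least one document.
#' @param k_neighbors Neighborhood size (default 5).
#' @param seed Integer seed.
#' @return An [hslda_corpus] with the original documents followed by the
#'   synthetic ones (doc ids `smote_<class>_<i>`).
#' @examples
#' \donttest{
#' corp <- sample_corpus(synthetic_spec(preset = "tiny", seed = 1))
#' bal <- smote_oversample(corp, seed = 1)
#' table(bal$docs$label)
#' }
#' @export
smote_oversample <- function(corpus, k_neighbors = 5, seed = 1L) {
  validate_corpus(corpus)
  stopifnot(k_neighbors >= 1)
  if (anyNA(corpus$docs$label)) abort("SMOTE requires every document to be labeled")
  counts <- table(factor(corpus$docs$label, levels = corpus$class_names))
  if (any(counts == 0)) {
    abort(sprintf("empty class: %s", names(counts)[counts == 0][1]))
  }
  target <- max(counts)
  if (all(counts == target)) return(corpus)
  voc <- corpus$vocabulary
  X <- doc_weight_matrix(corpus)
  vf_name <- voc$feature
  new_rows <- list()
  new_docs <- list()
  withr::with_seed(derive_seed(seed, "smote"), {
    for (cl in corpus$class_names) {
      need <- target - counts[[cl]]
      if (need == 0) next
      members <- which(corpus$docs$label == cl)
      Xc <- X[members, , drop = FALSE]
      k <- min(k_neighbors, length(members) - 1)
      nn_idx <- NULL
      if (k >= 1) {
        dm <- as.matrix(dist(Xc))
        nn_idx <- apply(dm, 1, function(r) order(r)[2:(k + 1)])
        nn_idx <- matrix(nn_idx, ncol = length(members))
      }
      for (i in seq_len(need)) {
        p <- sample.int(length(members), 1)
        if (k >= 1) {
          nb <- nn_idx[sample.int(k, 1), p]
          u <- runif(1)
          xs <- Xc[p, ] + u * (Xc[nb, ] - Xc[p, ])
        } else {
          xs <- Xc[p, ]
        }
        keep <- which(xs > 0)
        id <- sprintf("smote_%s_%d", cl, i)
        new_rows[[length(new_rows) + 1]] <- tibble::tibble(
          doc_id = id, feature = vf_name[keep], value = voc$value[keep],
          weight = xs[keep])
        new_docs[[length(new_docs) + 1]] <- tibble::tibble(doc_id = id,
                                                           label = cl)
      }
    }
  })
  hslda_corpus(dplyr::bind_rows(c(list(corpus$tokens), new_rows)),
               docs = dplyr::bind_rows(c(list(corpus$docs), new_docs)),
               vocabulary = voc, class_names = corpus$class_names)
}

#' Dense document-by-value weight matrix
#'
#' Sums token weights per `(document, value)`; the vector space used by
#' [smote_oversample()].
#'
#' @param corpus An [hslda_corpus].
#' @return A `D x V` numeric matrix with documents in corpus order.
#' @export
doc_weight_matrix <- function(corpus) {
  voc <- corpus$vocabulary
  toks <- corpus$tokens
  X <- matrix(0, n_docs(corpus), nrow(voc),
              dimnames = list(corpus$docs$doc_id, voc$value))
  if (nrow(toks) > 0) {
    i <- match(toks$doc_id, corpus$docs$doc_id)
    j <- match(toks$value, voc$value)
    for (t in seq_along(i)) X[i[t], j[t]] <- X[i[t], j[t]] + toks$weight[t]
  }
  X
}
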