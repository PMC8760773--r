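#' Labeled feature-value corpus
#'
#' A corpus holds one document per patient record: a weighted bag of
#' feature-value tokens plus an optional diagnosis class label. Tokens live
#' in a tidy tibble (one row per token), documents in a second tibble so
#' that zero-token documents are representable, and the hierarchical
#' vocabulary rides along.
#'
#' Duplicate `(feature, value)` tokens within one document are legal and are
#' kept distinct; the model sums their sufficient statistics, which is
#' equivalent to merging their weights.
#'
#' @param tokens Tibble with columns `doc_id`, `feature`, `value` and
#'   optionally `weight` (default 1).
#' @param docs Optional tibble with columns `doc_id` and `label` (`NA` for
#'   unlabeled documents). Defaults to the distinct `doc_id`s of `tokens`,
#'   unlabeled, plus a `label` column of `tokens` if present.
#' @param vocabulary Optional [hslda_vocabulary]; inferred from the observed
#'   pairs (order of appearance) when omitted.
#' @param class_names Optional ordered class names; defaults to the sorted
#'   unique non-missing labels.
#' @return A list of class `hslda_corpus` with elements `tokens`, `docs`,
#'   `vocabulary`, `class_names`.
#' @examples
#' toks <- tibble::tibble(
#'   doc_id = c("p1", "p1", "p2"),
#'   feature = c("rhythm", "sex", "rhythm"),
#'   value = c("rhythm-sinus", "sex-male", "rhythm-afib")
#' )
#' docs <- tibble::tibble(doc_id = c("p1", "p2"), label = c("SAP", "UAP"))
#' hslda_corpus(toks, docs)
#' @export
hslda_corpus <- function(tokens, docs = NULL, vocabulary = NULL,
                         class_names = NULL) {
  tokens <- tibble::as_tibble(tokens)
  if (!all(c("doc_id", "feature", "value") %in% names(tokens))) {
    abort("`tokens` needs columns doc_id, feature, value")
  }
  if (is.null(tokens[["weight"]])) tokens$weight <- 1
  if (is.null(docs)) {
    if (!is.null(tokens[["label"]])) {
      docs <- dplyr::distinct(tokens, .data$doc_id, .data$label)
    } else {
      docs <- tibble::tibble(doc_id = unique(tokens$doc_id),
                             label = NA_character_)
    }
  }
  docs <- tibble::as_tibble(docs)
  if (is.null(docs[["label"]])) docs$label <- NA_character_
  tokens <- tokens[c("doc_id", "feature", "value", "weight")]
  docs <- docs[c("doc_id", "label")]
  if (is.null(vocabulary)) {
    pairs <- dplyr::distinct(tokens, .data$feature, .data$value)
    if (nrow(pairs) == 0) abort("cannot infer a vocabulary from an empty token table")
    vocabulary <- hslda_vocabulary(pairs$value, pairs$feature)
  }
  class_names <- class_names %||% sort(unique(docs$label[!is.na(docs$label)]))
  out <- structure(
    list(tokens = tokens, docs = docs, vocabulary = vocabulary,
         class_names = as.character(class_names)),
    class = "hslda_corpus"
  )
  validate_corpus(out)
}

#' Validate a corpus against its type invariants
#'
#' Checks vocabulary membership and feature/value pairing of every token,
#' weight positivity, label membership in `class_names`, and document-table
#' consistency. Called by the constructor and by readers; exported because
#' property tests mutate corpora and expect every violation to be rejected.
#'
#' @param corpus An `hslda_corpus`.
#' @return The corpus, invisibly usable (returned unchanged) on success.
#' @export
validate_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "hslda_corpus"))
  toks <- corpus$tokens
  voc <- corpus$vocabulary
  if (anyDuplicated(corpus$docs$doc_id)) abort("duplicate doc_id in document table")
  if (!all(toks$doc_id %in% corpus$docs$doc_id)) {
    abort("tokens reference doc_ids absent from the document table")
  }
  vi <- match(toks$value, voc$value)
  if (anyNA(vi)) {
    bad <- unique(toks$value[is.na(vi)])
    abort(sprintf("unknown value name(s): %s", paste(head(bad, 5), collapse = ", ")))
  }
  owner <- voc$feature[vi]
  mism <- owner != toks$feature
  if (any(mism)) {
    i <- which(mism)[1]
    abort(sprintf("token value '%s' belongs to feature '%s', not '%s'",
                  toks$value[i], owner[i], toks$feature[i]))
  }
  if (any(!is.finite(toks$weight)) || any(toks$weight <= 0)) {
    abort("token weights must be finite and > 0")
  }
  lab <- corpus$docs$label
  if (!all(lab[!is.na(lab)] %in% corpus$class_names)) {
    abort("document labels must be among class_names")
  }
  corpus
}

#' @export
print.hslda_corpus <- function(x, ...) {
  cat(sprintf(
    "<hslda_corpus> D=%d documents, %d tokens, F=%d features, V=%d values, C=%d classes\n",
    nrow(x$docs), nrow(x$tokens), length(vocab_features(x$vocabulary)),
    nrow(x$vocabulary), length(x$class_names)))
  invisible(x)
}

#' Number of documents in a corpus
#' @param corpus An `hslda_corpus`.
#' @export
n_docs <- function(corpus) nrow(corpus$docs)

# ---- indexed view used by the numerical kernels ------------------------

# Convert the tidy corpus to 0-based-free integer indices: a list of
# documents, each list(id, f, v, w, label) with f,v 1-based indices into the
# vocabulary and label a 1-based class index or NA.
corpus_index <- function(corpus) {
  voc <- corpus$vocabulary
  vf <- value_feature_map(voc)
  toks <- corpus$tokens
  vi <- match(toks$value, voc$value)
  fi <- vf[vi]
  li <- match(corpus$docs$label, corpus$class_names)
  split_idx <- split(seq_len(nrow(toks)), factor(toks$doc_id, levels = corpus$docs$doc_id))
  docs <- purrr::map(seq_len(nrow(corpus$docs)), function(d) {
    j <- split_idx[[d]]
    list(id = corpus$docs$doc_id[d], f = fi[j], v = vi[j],
         w = toks$weight[j], label = li[d])
  })
  list(docs = docs, vf = vf,
       F = length(vocab_features(voc)), V = nrow(voc),
       C = length(corpus$class_names))
}

# ---- readers / writers -------------------------------------------------

fmt_num <- function(x) {
  # 17 significant digits round-trip a double; %g never pads
  sprintf("%.17g", x)
}

#' Read and write the corpus TSV format
#'
#' The corpus file is UTF-8 TSV with one document per line:
#' `doc_id<TAB>label<TAB>feature=value:weight feature=value ...`, tokens
#' space-separated, `:weight` omitted when the weight is 1, and label `-`
#' for unlabeled documents. The vocabulary lives in a companion TSV (see
#' [read_vocabulary()]). Writing then reading reproduces the corpus exactly,
#' including weights at full double precision.
#'
#' @param path Corpus file path.
#' @param vocab_path Vocabulary file path (parsed first).
#' @param class_names Optional ordered class names; defaults to sorted
#'   unique labels found in the file.
#' @return `read_corpus()` returns an [hslda_corpus].
#' @export
read_corpus <- function(path, vocab_path, class_names = NULL) {
  vocabulary <- read_vocabulary(vocab_path)
  if (!file.exists(path)) abort(sprintf("corpus file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  doc_ids <- character(0); labels <- character(0)
  tok_rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) {
      abort(sprintf("%s line %d: expected at least doc_id<TAB>label", path, i))
    }
    doc_ids[i] <- parts[1]
    labels[i] <- if (parts[2] == "-") NA_character_ else parts[2]
    toks <- if (length(parts) >= 3 && nzchar(parts[3])) {
      strsplit(parts[3], " ", fixed = TRUE)[[1]]
    } else character(0)
    if (length(toks) == 0) { tok_rows[[i]] <- NULL; next }
    m <- regmatches(toks, regexec("^([^=]+)=([^:]+)(:(.*))?$", toks))
    bad <- vapply(m, length, integer(1)) == 0
    if (any(bad)) {
      abort(sprintf("%s line %d: malformed token '%s'", path, i, toks[bad][1]))
    }
    feature <- vapply(m, `[`, character(1), 2)
    value <- vapply(m, `[`, character(1), 3)
    wtxt <- vapply(m, `[`, character(1), 5)
    weight <- rep(1, length(toks))
    has_w <- nzchar(wtxt)
    if (any(has_w)) {
      wv <- suppressWarnings(as.numeric(wtxt[has_w]))
      if (anyNA(wv)) {
        abort(sprintf("%s line %d: malformed weight '%s'", path, i,
                      wtxt[has_w][is.na(wv)][1]))
      }
      weight[has_w] <- wv
    }
    vi <- match(value, vocabulary$value)
    if (anyNA(vi)) {
      abort(sprintf("%s line %d: value '%s' not in vocabulary", path, i,
                    value[is.na(vi)][1]))
    }
    mism <- vocabulary$feature[vi] != feature
    if (any(mism)) {
      abort(sprintf("%s line %d: value '%s' paired with wrong feature '%s'",
                    path, i, value[mism][1], feature[mism][1]))
    }
    tok_rows[[i]] <- tibble::tibble(doc_id = parts[1], feature = feature,
                                    value = value, weight = weight)
  }
  tokens <- dplyr::bind_rows(tok_rows)
  if (nrow(tokens) == 0) {
    tokens <- tibble::tibble(doc_id = character(0), feature = character(0),
                             value = character(0), weight = numeric(0))
  }
  hslda_corpus(tokens,
               docs = tibble::tibble(doc_id = doc_ids, label = labels),
               vocabulary = vocabulary, class_names = class_names)
}

#' @rdname read_corpus
#' @param corpus An [hslda_corpus] to write.
#' @export
write_corpus <- function(corpus, path, vocab_path) {
  validate_corpus(corpus)
  write_vocabulary(corpus$vocabulary, vocab_path)
  toks <- corpus$tokens
  tok_str <- paste0(toks$feature, "=", toks$value,
                    ifelse(toks$weight == 1, "", paste0(":", fmt_num(toks$weight))))
  by_doc <- split(tok_str, factor(toks$doc_id, levels = corpus$docs$doc_id))
  body <- vapply(by_doc, paste, character(1), collapse = " ")
  lab <- ifelse(is.na(corpus$docs$label), "-", corpus$docs$label)
  writeLines(paste(corpus$docs$doc_id, lab, body, sep = "\t"), path,
             useBytes = TRUE)
  invisible(corpus)
}

#' Read a wide patient-by-pair CSV matrix as a corpus
#'
#' One row per document; every column whose header parses as
#' `feature=value` holds that pair's weight (0 = absent); a `label` column
#' holds the class name (empty/NA = unlabeled); an optional `doc_id` column
#' names documents (defaults to `doc<row>`).
#'
#' @param path CSV path.
#' @param class_names Optional ordered class names.
#' @return An [hslda_corpus].
#' @export
read_corpus_matrix <- function(path, class_names = NULL) {
  tab <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  pair_cols <- grep("^[^=]+=[^=]+$", names(tab), value = TRUE)
  if (length(pair_cols) == 0) abort("no columns with `feature=value` headers found")
  doc_id <- if ("doc_id" %in% names(tab)) as.character(tab$doc_id) else
    paste0("doc", seq_len(nrow(tab)))
  label <- if ("label" %in% names(tab)) as.character(tab$label) else
    NA_character_
  split_hdr <- strsplit(pair_cols, "=", fixed = TRUE)
  feats <- vapply(split_hdr, `[`, character(1), 1)
  vals <- pair_cols
  long <- tidyr::pivot_longer(
    dplyr::mutate(tab[pair_cols], doc_id = doc_id),
    cols = dplyr::all_of(pair_cols),
    names_to = "value", values_to = "weight")
  long <- dplyr::filter(long, .data$weight > 0)
  long$feature <- feats[match(long$value, vals)]
  hslda_corpus(long[c("doc_id", "feature", "value", "weight")],
               docs = tibble::tibble(doc_id = doc_id,
                                     label = dplyr::na_if(label, "")),
               vocabulary = hslda_vocabulary(vals, feats),
               class_names = class_names)
}

# ---- summaries ---------------------------------------------------------

#' Corpus summary statistics
#'
#' Per feature-value pair: document frequency (number of documents
#' containing the pair at least once) and its percentage of `D`, rounded to
#' 2 decimals; per class: count and percentage; plus the corpus dimensions.
#'
#' @param corpus An `hslda_corpus` with at least one document.
#' @return A list of class `hslda_summary` with tibbles `pairs` (columns
#'   `feature`, `value`, `frequency`, `ratio`), `classes` (`class`, `count`,
#'   `ratio`) and `dims` (`D`, `F`, `V`).
#' @examples
#' corp <- sample_corpus(synthetic_spec(preset = "tiny", seed = 1))
#' summarize_corpus(corp)$dims
#' @export
summarize_corpus <- function(corpus) {
  validate_corpus(corpus)
  D <- n_docs(corpus)
  if (D == 0) abort("cannot summarize an empty corpus")
  pairs <- corpus$tokens |>
    dplyr::distinct(.data$doc_id, .data$feature, .data$value) |>
    dplyr::count(.data$feature, .data$value, name = "frequency") |>
    dplyr::mutate(ratio = round(100 * .data$frequency / D, 2)) |>
    dplyr::arrange(dplyr::desc(.data$frequency))
  classes <- corpus$docs |>
    dplyr::filter(!is.na(.data$label)) |>
    dplyr::count(class = .data$label, name = "count") |>
    dplyr::mutate(ratio = round(100 * .data$count / D, 2))
  classes <- classes[order(match(classes$class, corpus$class_names)), ]
  structure(
    list(pairs = pairs, classes = classes,
         dims = tibble::tibble(D = D,
                               F = length(vocab_features(corpus$vocabulary)),
                               V = nrow(corpus$vocabulary))),
    class = "hslda_summary")
}

#' @export
print.hslda_summary <- function(x, ...) {
  d <- x$dims
  cat(sprintf("Corpus: D=%d documents, F=%d features, V=%d feature-value pairs\n",
              d$D, d$F, d$V))
  cat("Top feature-value pairs by document frequency:\n")
  print(head(x$pairs, 10))
  cat("Classes:\n")
  print(x$classes)
  invisible(x)
}
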