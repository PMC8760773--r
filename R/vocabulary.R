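#' Hierarchical feature/value vocabulary
#'
#' A vocabulary maps every feature-value pair name (a "value") to the
#' clinical feature that owns it, partitioning the `V` values into `F`
#' feature blocks. It is stored as a tibble with one row per value and
#' columns `value` and `feature`; the ordered feature list is kept as an
#' attribute so feature indices are stable even when a feature's values are
#' not contiguous.
#'
#' @param values Character vector of value names (length `V`, unique).
#' @param features Character vector of the same length giving the owning
#'   feature of each value.
#' @param feature_levels Optional ordered character vector of feature names;
#'   defaults to order of first appearance in `features`.
#' @return A tibble of class `hslda_vocabulary` with columns `value`,
#'   `feature`.
#' @examples
#' hslda_vocabulary(
#'   values   = c("rhythm-sinus", "rhythm-afib", "sex-male", "sex-female"),
#'   features = c("rhythm", "rhythm", "sex", "sex")
#' )
#' @export
hslda_vocabulary <- function(values, features, feature_levels = NULL) {
  stopifnot(is.character(values), is.character(features),
            length(values) == length(features), length(values) >= 1)
  if (anyNA(values) || anyNA(features)) {
    abort("vocabulary names must not be missing")
  }
  if (anyDuplicated(values)) {
    abort(sprintf("duplicate value names in vocabulary: %s",
                  paste(unique(values[duplicated(values)]), collapse = ", ")))
  }
  feature_levels <- feature_levels %||% unique(features)
  if (anyDuplicated(feature_levels)) abort("duplicate feature names")
  if (!all(features %in% feature_levels)) {
    abort("every value's feature must appear in `feature_levels`")
  }
  if (!all(feature_levels %in% features)) {
    abort("every feature must own at least one value")
  }
  out <- tibble::tibble(value = values, feature = features)
  attr(out, "features") <- feature_levels
  class(out) <- c("hslda_vocabulary", class(out))
  out
}

#' @rdname hslda_vocabulary
#' @param x An `hslda_vocabulary`.
#' @export
vocab_features <- function(x) attr(x, "features")

#' @rdname hslda_vocabulary
#' @export
vocab_values <- function(x) x$value

# Integer map value-index -> feature-index (total by construction).
value_feature_map <- function(x) {
  match(x$feature, vocab_features(x))
}

#' @export
print.hslda_vocabulary <- function(x, ...) {
  cat(sprintf("<hslda_vocabulary> %d values in %d feature blocks\n",
              nrow(x), length(vocab_features(x))))
  NextMethod()
}

#' Read / write a vocabulary TSV
#'
#' The file is UTF-8 TSV with a required header row and columns
#' `value_name` and `feature_name`, one row per value; feature order is the
#' order of first appearance.
#'
#' @param path File path.
#' @return `read_vocabulary()` returns an [hslda_vocabulary]; the writer
#'   returns its input invisibly.
#' @export
read_vocabulary <- function(path) {
  if (!file.exists(path)) abort(sprintf("vocabulary file not found: %s", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("value_name", "feature_name") %in% names(tab))) {
    abort(sprintf("vocabulary file %s must have header columns value_name, feature_name", path))
  }
  hslda_vocabulary(tab$value_name, tab$feature_name)
}

#' @rdname read_vocabulary
#' @param vocabulary An [hslda_vocabulary] to write.
#' @export
write_vocabulary <- function(vocabulary, path) {
  lines <- c("value_name\tfeature_name",
             paste(vocabulary$value, vocabulary$feature, sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(vocabulary)
}
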