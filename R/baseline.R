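#' Flatten the hierarchical vocabulary to a single feature
#'
#' Re-parents every value under one pseudo-feature, which reduces the
#' four-layer model to plain multi-class sLDA: with `F = 1` the
#' topic-feature multinomials are identically 1 and contribute nothing to
#' the likelihood, so the same inference code run on the flattened corpus
#' isolates exactly the effect of the hierarchy. Value names, documents,
#' weights and labels are preserved; the operation is idempotent.
#'
#' @param corpus An [hslda_corpus].
#' @param feature_name Name of the pseudo-feature (default `"*"`).
#' @return An [hslda_corpus] whose vocabulary has one feature owning all
#'   `V` values.
#' @examples
#' corp <- sample_corpus(synthetic_spec(preset = "tiny", seed = 1))
#' flat <- flatten_corpus(corp)
#' length(vocab_features(flat$vocabulary))  # 1
#' @export
flatten_corpus <- function(corpus, feature_name = "*") {
  validate_corpus(corpus)
  voc <- corpus$vocabulary
  flat_voc <- hslda_vocabulary(voc$value, rep(feature_name, nrow(voc)))
  toks <- corpus$tokens
  toks$feature <- feature_name
  hslda_corpus(toks, docs = corpus$docs, vocabulary = flat_voc,
               class_names = corpus$class_names)
}
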