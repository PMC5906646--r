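#' Vendored English stop-word list
#'
#' The stop-word list is pinned inside the package rather than taken from an
#' external resource, so that tokenization is reproducible: the search index,
#' the fingerprints and the difference statistics are all defined relative to
#' this exact list. It is the classic English function-word inventory used by
#' general-purpose text analyzers (determiners, pronouns, auxiliaries,
#' prepositions, conjunctions) plus the single-letter residues left behind
#' when contractions such as "don't" are split at the apostrophe during
#' tokenization.
#'
#' @return character vector of lower-case stop words.
#' @examples
#' "the" %in% english_stopwords()
#' @export
english_stopwords <- function() .citance_stopwords

.citance_stopwords <- c(
  "i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you",
  "your", "yours", "yourself", "yourselves", "he", "him", "his", "himself",
  "she", "her", "hers", "herself", "it", "its", "itself", "they", "them",
  "their", "theirs", "themselves", "what", "which", "who", "whom", "this",
  "that", "these", "those", "am", "is", "are", "was", "were", "be", "been",
  "being", "have", "has", "had", "having", "do", "does", "did", "doing",
  "a", "an", "the", "and", "but", "if", "or", "because", "as", "until",
  "while", "of", "at", "by", "for", "with", "about", "against", "between",
  "into", "through", "during", "before", "after", "above", "below", "to",
  "from", "up", "down", "in", "out", "on", "off", "over", "under", "again",
  "further", "then", "once", "here", "there", "when", "where", "why", "how",
  "all", "any", "both", "each", "few", "more", "most", "other", "some",
  "such", "no", "nor", "not", "only", "own", "same", "so", "than", "too",
  "very", "s", "t", "can", "will", "just", "don", "should", "now", "d",
  "ll", "m", "o", "re", "ve", "y", "ain", "aren", "couldn", "didn",
  "doesn", "hadn", "hasn", "haven", "isn", "ma", "mightn", "mustn",
  "needn", "shan", "shouldn", "wasn", "weren", "won", "wouldn"
)
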