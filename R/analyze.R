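#' Tokenize text into normalized word tokens
#'
#' Splits text on any character that is neither a letter nor a digit (so
#' hyphens split compounds: "α-helix" gives two tokens) and case-folds the
#' result. Letters of any script are kept — Greek symbols common in
#' biomedical prose ("α", "κB") survive — as do digits, so tokens such as
#' "p53" or "2019" are preserved intact. Punctuation never survives because
#' it is consumed by the split itself.
#'
#' @param text character scalar (or vector; elements are concatenated).
#' @return character vector of lower-case tokens, possibly empty.
#' @export
tokenize_words <- function(text) {
  if (length(text) == 0L) return(character(0))
  text <- paste(text, collapse = " ")
  if (!nzchar(trimws(text))) return(character(0))
  text <- stringi::stri_trans_nfc(text)
  toks <- stringi::stri_split_regex(text, "[^\\p{L}\\p{N}]+",
                                    omit_empty = TRUE)[[1]]
  stringi::stri_trans_tolower(toks)
}

#' Analyze text for indexing and querying
#'
#' The standard English analysis chain applied identically to every indexed
#' statement and every query: tokenize, case-fold, drop stop words
#' ([english_stopwords()]), then stem with the Porter algorithm
#' ([porter_stem()]). Search relevance and the text fingerprints are both
#' defined on top of this one analyzer, so a fingerprint genuinely reflects
#' how the retrieval side sees a text.
#'
#' @param text character scalar to analyze.
#' @return character vector of stemmed tokens in text order (duplicates
#'   retained; use [make_fingerprint()] for the deduplicated set view).
#' @examples
#' analyze("Binding Proteins")   # "bind" "protein"
#' analyze("the of and")         # character(0)
#' @export
analyze <- function(text) {
  toks <- tokenize_words(text)
  toks <- toks[!toks %in% .citance_stopwords]
  porter_stem(toks)
}
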