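#' @keywords internal
"_PACKAGE"

# Periods inside these short-hands never end a sentence. The list is pinned:
# segmentation output must be stable across releases of anything external.
.protected_abbreviations <- c(
  "et al.", "ca.", "e.g.", "i.e.", "Fig.", "Figs.", "vs.", "Dr.", "cf.",
  "approx.", "Eq.", "No."
)

# marker tokens produced by parse_jats(): <bibr:RID> or <nbib:RID>
.marker_regex <- "<(bibr|nbib):([^>]+)>"

# citation cluster that may trail a terminal period and still belong to the
# sentence before it: markers (optionally bracket-wrapped or space-separated)
# and closing brackets flush against the period
.post_period_cluster <- "(?:\\s*\\[?<(?:bibr|nbib):[^>]+>\\]?|[\\)\\]])*"

#' Split a paragraph into sentences
#'
#' Sentence boundaries are terminal periods, with two protections tuned to
#' scientific prose: periods inside a fixed list of short-hands ("et al.",
#' "ca.", "e.g.", "Fig.", ...) never split, and neither does the period of an
#' abbreviated genus name ("H. pylori" — a single capital letter followed by
#' a period and a lower-case word). Citation markers that trail a terminal
#' period (up to the first character of the next sentence) stay with the
#' sentence they follow, so post-period citations can later be attached to
#' the statement they support.
#'
#' The split is lossless: re-joining the returned sentences reproduces the
#' input up to inter-sentence whitespace.
#'
#' @param text paragraph string, possibly carrying inline citation markers
#'   of the form `<bibr:RID>` / `<nbib:RID>` as produced by [parse_jats()].
#' @return character vector of sentences, markers preserved; empty input
#'   gives `character(0)`.
#' @examples
#' segment_sentences("Smith et al. <bibr:B1> showed X. We confirm this.")
#' segment_sentences("H. pylori infects the stomach. It is common.")
#' @export
segment_sentences <- function(text) {
  if (length(text) != 1L || is.na(text)) stop("text must be a single string")
  if (!nzchar(trimws(text))) return(character(0))
  text <- stringi::stri_trans_nfc(text)

  sentinel <- "\x01"
  masked <- text
  for (ab in .protected_abbreviations) {
    pat <- paste0("(?<![\\p{L}\\p{N}])",
                  gsub(".", "\\.", ab, fixed = TRUE))
    rep <- gsub(".", sentinel, ab, fixed = TRUE)
    masked <- stringi::stri_replace_all_regex(masked, pat, rep)
  }
  # genus short-hand: lone capital + period + lower-case word ("H. pylori")
  masked <- stringi::stri_replace_all_regex(
    masked, "(?<![\\p{L}\\p{N}])(\\p{Lu})\\.(?=\\s+\\p{Ll})",
    paste0("$1", sentinel))

  # a boundary is a surviving period plus its trailing citation cluster,
  # provided something follows
  bound <- stringi::stri_locate_all_regex(
    masked, paste0("\\.", .post_period_cluster, "(?=\\s)"))[[1]]
  cuts <- if (all(is.na(bound))) integer(0) else bound[, 2L]

  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, nchar(masked))
  pieces <- stringi::stri_sub(masked, starts, ends)
  pieces <- gsub(sentinel, ".", pieces, fixed = TRUE)
  pieces <- trimws(pieces)
  pieces[nzchar(pieces)]
}

#' Remove citation markers from a sentence
#'
#' Strips the typed `<bibr:...>`/`<nbib:...>` markers (and any brackets that
#' immediately enclosed them), collapses the whitespace left behind, and
#' trims. The stored text of a Cited Statement is the statement itself, not
#' its reference numerals.
#'
#' @param sentence sentence string with markers.
#' @return plain sentence text.
#' @export
strip_markers <- function(sentence) {
  out <- gsub(paste0("\\[", .marker_regex, "\\]"), "", sentence, perl = TRUE)
  out <- gsub(.marker_regex, "", out, perl = TRUE)
  out <- gsub("\\s+", " ", out)
  out <- gsub(" +([.,;:)\\]])", "\\1", out, perl = TRUE)
  trimws(out)
}

# parse markers out of a sentence: data.frame of type ("bibr"/"nbib") and rid
sentence_markers <- function(sentence) {
  m <- stringi::stri_match_all_regex(sentence, .marker_regex)[[1]]
  if (all(is.na(m))) {
    return(data.frame(type = character(0), rid = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(type = m[, 2L], rid = m[, 3L], stringsAsFactors = FALSE)
}
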