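#' Construct a cited statement
#'
#' @param text plain sentence text (no markers, no markup).
#' @param cited list of [cited_work()] objects; must be non-empty.
#' @param source_article_id,source_article_title,source_journal_title
#'   metadata of the citing article.
#' @return object of class `cited_statement`.
#' @export
cited_statement <- function(text, cited, source_article_id = "",
                            source_article_title = "",
                            source_journal_title = "") {
  stopifnot(is.character(text), length(text) == 1L)
  if (length(cited) == 0L) {
    stop("a cited statement must cite at least one work")
  }
  structure(list(
    text = text,
    cited = cited,
    source_article_id = source_article_id,
    source_article_title = source_article_title,
    source_journal_title = source_journal_title
  ), class = "cited_statement")
}

#' Extract cited statements from a parsed article
#'
#' Segments every body paragraph into sentences ([segment_sentences()]), and
#' turns each sentence that carries at least one bibliographic marker into a
#' [cited_statement()]. Citation markers trailing a sentence's terminal
#' period were already attached to that sentence during segmentation, so
#' post-period citations land on the statement they support.
#' Non-bibliographic markers (figures, tables) never create a statement and
#' never contribute a cited work. Markers are stripped from the stored text;
#' cited works are deduplicated by [work_key()] (PMID, then DOI, then raw
#' rid). A bibliographic marker whose rid has no reference-list entry still
#' yields a cited work carrying only the raw rid, with a warning.
#'
#' @param article an `article_record` from [parse_jats()].
#' @return list of `cited_statement` objects, in document order.
#' @export
extract_cited_statements <- function(article) {
  stopifnot(inherits(article, "article_record"))
  out <- list()
  for (para in article$paragraphs) {
    for (sent in segment_sentences(para)) {
      mk <- sentence_markers(sent)
      rids <- unique(mk$rid[mk$type == "bibr"])
      if (length(rids) == 0L) next
      works <- lapply(rids, function(r) {
        w <- article$references[[r]]
        if (is.null(w)) {
          warning("unresolved bibliographic rid '", r, "' in article ",
                  article$article_id, call. = FALSE)
          w <- cited_work(raw_key = r)
        }
        w
      })
      keys <- vapply(works, work_key, character(1))
      works <- works[!duplicated(keys)]
      out[[length(out) + 1L]] <- cited_statement(
        text = strip_markers(sent),
        cited = works,
        source_article_id = article$article_id,
        source_article_title = article$article_title,
        source_journal_title = article$journal_title)
    }
  }
  out
}

#' Write cited statements as JSON lines
#'
#' One UTF-8 JSON object per line per statement, with a stable key order:
#' `text`, `cited` (array of objects with `pmid`, `doi`, `raw_key`),
#' `source_article_id`, `source_article_title`, `source_journal_title`.
#' This is the bulk-data interchange format of the pipeline.
#'
#' @param cs_list list of `cited_statement` objects.
#' @param destination file path.
#' @return number of records written, invisibly.
#' @export
write_cs_json <- function(cs_list, destination) {
  lines <- vapply(cs_list, function(cs) {
    jsonlite::toJSON(list(
      text = cs$text,
      cited = lapply(cs$cited, function(w) list(
        pmid = if (is.null(w$pmid)) NA_character_ else w$pmid,
        doi = if (is.null(w$doi)) NA_character_ else w$doi,
        raw_key = w$raw_key)),
      source_article_id = cs$source_article_id,
      source_article_title = cs$source_article_title,
      source_journal_title = cs$source_journal_title
    ), auto_unbox = TRUE, na = "null")
  }, character(1))
  con <- file(destination, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(length(lines))
}

#' Read cited statements from JSON lines
#'
#' Inverse of [write_cs_json()]: reloading is the identity on statement
#' lists.
#'
#' @param path JSON-lines file.
#' @return list of `cited_statement` objects.
#' @export
read_cs_json <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    cited_statement(
      text = rec$text,
      cited = lapply(rec$cited, function(w) cited_work(
        raw_key = w$raw_key,
        pmid = if (is.null(w$pmid)) NULL else w$pmid,
        doi = if (is.null(w$doi)) NULL else w$doi)),
      source_article_id = rec$source_article_id,
      source_article_title = rec$source_article_title,
      source_journal_title = rec$source_journal_title)
  })
}

#' @export
print.cited_statement <- function(x, ...) {
  cat("<cited_statement> \"", x$text, "\"\n  cites: ",
      paste(vapply(x$cited, work_key, character(1)), collapse = ", "),
      "\n  from:  ", x$source_article_id, " (", x$source_article_title,
      ")\n", sep = "")
  invisible(x)
}
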