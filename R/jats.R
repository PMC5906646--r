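#' Construct a cited-work record
#'
#' A cited work is what a bibliographic `<xref>` ultimately points at: the
#' back-matter reference entry, reduced to its machine identifiers. At least
#' the raw JATS `rid` is always present; PMID and DOI are carried when the
#' reference list supplies them.
#'
#' @param raw_key the JATS `rid` of the reference entry.
#' @param pmid,doi optional identifier strings.
#' @return object of class `cited_work`.
#' @export
cited_work <- function(raw_key, pmid = NULL, doi = NULL) {
  stopifnot(is.character(raw_key), length(raw_key) == 1L, nzchar(raw_key))
  structure(list(pmid = pmid, doi = doi, raw_key = raw_key),
            class = "cited_work")
}

#' Canonical identity key of a cited work
#'
#' PMID is preferred, then DOI, then the raw JATS rid. This one identity
#' rule is used everywhere a cited work must be compared: deduplication
#' within a statement and shared-citation counting during ranking.
#'
#' @param work a `cited_work`.
#' @return single string, e.g. `"pmid:123"`.
#' @export
work_key <- function(work) {
  if (!is.null(work$pmid)) return(paste0("pmid:", work$pmid))
  if (!is.null(work$doi)) return(paste0("doi:", work$doi))
  paste0("raw:", work$raw_key)
}

#' Parse a JATS article into an article record
#'
#' Reads one JATS (NLM/PMC) full-text XML document and returns the pieces
#' the citation-statement pipeline needs: article and journal titles, an
#' article identifier (PMCID preferred, then PMID, then DOI), the body
#' paragraphs with inline `<xref>` elements replaced by typed markers, and
#' the back-matter reference list resolved to [cited_work()] entries.
#'
#' An `<xref>` is treated as bibliographic when `ref-type="bibr"`, or when it
#' has no `ref-type` but its `rid` resolves into the reference list; all
#' other xrefs (figures, tables, ...) become non-bibliographic markers.
#' Multi-target xrefs (`rid="B1 B2"`) expand into one marker per target.
#' Text is normalized to NFC.
#'
#' @param xml_document JATS XML as a string, or a file path.
#' @return object of class `article_record` with fields `article_id`,
#'   `article_title`, `journal_title`, `paragraphs` (character vector with
#'   `<bibr:RID>`/`<nbib:RID>` markers) and `references` (named list of
#'   `cited_work`, keyed by rid).
#' @export
parse_jats <- function(xml_document) {
  doc <- tryCatch(
    xml2::read_xml(xml_document),
    error = function(e) {
      stop("malformed XML: ", conditionMessage(e), call. = FALSE)
    })

  body <- xml2::xml_find_first(doc, ".//body")
  if (inherits(body, "xml_missing")) stop("no body", call. = FALSE)

  refs <- list()
  ref_nodes <- xml2::xml_find_all(doc, ".//back//ref-list/ref")
  if (length(ref_nodes) == 0L) {
    warning("article has no reference list", call. = FALSE)
  }
  for (rn in ref_nodes) {
    rid <- xml2::xml_attr(rn, "id")
    if (is.na(rid)) next
    pmid <- xml2::xml_text(
      xml2::xml_find_first(rn, ".//pub-id[@pub-id-type='pmid']"))
    doi <- xml2::xml_text(
      xml2::xml_find_first(rn, ".//pub-id[@pub-id-type='doi']"))
    refs[[rid]] <- cited_work(
      raw_key = rid,
      pmid = if (is.na(pmid)) NULL else pmid,
      doi = if (is.na(doi)) NULL else doi)
  }

  paras <- xml2::xml_find_all(
    body, ".//p[not(ancestor::fig) and not(ancestor::table-wrap)]")
  para_text <- vapply(paras, flatten_jats_node, character(1),
                      ref_keys = names(refs))
  para_text <- stringi::stri_trans_nfc(para_text)

  title <- xml2::xml_text(xml2::xml_find_first(
    doc, ".//front//article-meta//article-title"))
  journal <- xml2::xml_text(xml2::xml_find_first(
    doc, ".//front//journal-meta//journal-title"))

  aid <- NA_character_
  for (typ in c("pmcid", "pmc", "pmid", "doi")) {
    aid <- xml2::xml_text(xml2::xml_find_first(
      doc, sprintf(".//front//article-meta/article-id[@pub-id-type='%s']",
                   typ)))
    if (!is.na(aid)) break
  }
  if (is.na(aid)) {
    aid <- xml2::xml_text(
      xml2::xml_find_first(doc, ".//front//article-meta/article-id"))
  }

  structure(list(
    article_id = if (is.na(aid)) "" else stringi::stri_trans_nfc(aid),
    article_title = if (is.na(title)) "" else stringi::stri_trans_nfc(title),
    journal_title = if (is.na(journal)) "" else
      stringi::stri_trans_nfc(journal),
    paragraphs = para_text,
    references = refs
  ), class = "article_record")
}

# flatten a paragraph node to text, replacing xref elements by typed markers
flatten_jats_node <- function(node, ref_keys) {
  out <- character(0)
  for (child in xml2::xml_contents(node)) {
    nm <- xml2::xml_name(child)
    if (nm == "text" || nm == "cdata") {
      out <- c(out, xml2::xml_text(child))
    } else if (nm == "xref") {
      rt <- xml2::xml_attr(child, "ref-type")
      rids <- strsplit(trimws(xml2::xml_attr(child, "rid")), "\\s+")[[1]]
      if (length(rids) == 0L || all(is.na(rids))) next
      bib <- if (is.na(rt)) all(rids %in% ref_keys) else identical(rt, "bibr")
      tag <- if (bib) "bibr" else "nbib"
      out <- c(out, paste0("<", tag, ":", rids, ">", collapse = ""))
    } else {
      out <- c(out, flatten_jats_node(child, ref_keys))
    }
  }
  paste(out, collapse = "")
}

#' @export
print.article_record <- function(x, ...) {
  cat("<article_record> ", x$article_id, "\n",
      "  title:   ", x$article_title, "\n",
      "  journal: ", x$journal_title, "\n",
      "  ", length(x$paragraphs), " paragraph(s), ",
      length(x$references), " reference(s)\n", sep = "")
  invisible(x)
}
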