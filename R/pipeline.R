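#' Write a synthetic corpus to disk
#'
#' Materializes [generate_corpus()]: one JATS XML file per article plus a
#' `ground_truth.json` manifest recording every citing sentence, the total
#' citing-sentence count, planted difference levels and the planted
#' reference texts.
#'
#' @param spec a [corpus_spec()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, the generated corpus object.
#' @export
run_simulate <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  corpus <- generate_corpus(spec)
  for (i in seq_along(corpus$articles)) {
    writeLines(corpus$articles[i],
               file.path(out_dir, sprintf("article_%04d.xml", i)),
               useBytes = TRUE)
  }
  manifest <- list(
    n_articles = spec$n_articles,
    n_cs = corpus$ground_truth$n_cs,
    articles = corpus$ground_truth$articles,
    planted = corpus$ground_truth$planted,
    pr_texts = corpus$pr_texts)
  jsonlite::write_json(manifest, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(corpus)
}

#' Extract cited statements from a directory of JATS files
#'
#' Parses every `*.xml` file, extracts cited statements, and writes them as
#' JSON lines. Files that fail to parse are logged and skipped; the run
#' fails only if nothing at all could be processed when input files were
#' present.
#'
#' @param xml_dir directory of JATS XML files.
#' @param out_jsonl output JSON-lines path.
#' @return number of statements written, invisibly.
#' @export
run_extract <- function(xml_dir, out_jsonl) {
  files <- list.files(xml_dir, pattern = "\\.xml$", full.names = TRUE)
  if (length(files) == 0L) {
    warning("no XML files found in ", xml_dir, call. = FALSE)
  }
  all_cs <- list()
  failed <- 0L
  for (f in files) {
    cs <- tryCatch(
      extract_cited_statements(parse_jats(f)),
      error = function(e) {
        message("skipping ", basename(f), ": ", conditionMessage(e))
        NULL
      })
    if (is.null(cs)) failed <- failed + 1L else all_cs <- c(all_cs, cs)
  }
  if (length(files) > 0L && failed == length(files)) {
    stop("all ", failed, " input file(s) failed to parse")
  }
  n <- write_cs_json(all_cs, out_jsonl)
  invisible(n)
}

#' Build and persist a search index
#'
#' @param jsonl JSON-lines file of cited statements.
#' @param index_path destination path for the serialized index.
#' @return the index, invisibly.
#' @export
run_index <- function(jsonl, index_path) {
  idx <- build_index(read_cs_json(jsonl))
  saveRDS(idx, index_path)
  invisible(idx)
}

#' Search a persisted index
#'
#' Results carry the triple a reader needs: the statement itself, the title
#' of the article it appears in, and the identifiers of the works it cites.
#'
#' @param index_path path written by [run_index()], or a live `cs_index`.
#' @param keywords query string.
#' @param top_k maximum results.
#' @param as_json if `TRUE`, return a JSON string instead of a data.frame.
#' @return data.frame from [search_index()], or its JSON rendering.
#' @export
run_search <- function(index_path, keywords, top_k = 10L, as_json = FALSE) {
  idx <- if (inherits(index_path, "cs_index")) index_path else
    readRDS(index_path)
  res <- search_index(idx, keywords, top_k = top_k)
  if (!as_json) return(res)
  jsonlite::toJSON(lapply(seq_len(nrow(res)), function(i) list(
    source_article_title = res$source_article_title[i],
    statement = res$text[i],
    cited = res$cited[[i]],
    rounded_score = res$rounded_score[i],
    shared_citations = res$shared_citations[i])),
    auto_unbox = TRUE, pretty = TRUE)
}

#' Compare cited statements against the documents they cite
#'
#' Groups statements by cited document id, computes the per-document
#' maximum fingerprint difference ([max_difference_per_pr()]) against the
#' supplied reference texts, and summarizes the distribution. Documents
#' with no usable statement are excluded with a message.
#'
#' @param cs_list list of `cited_statement` objects (or a JSON-lines path).
#' @param pr_texts named list: document id -> `list(title_abstract,
#'   fulltext)`.
#' @param bin_width histogram bin width for the summary.
#' @return list with `records` (data.frame: one row per comparable
#'   document) and `distribution` (see [difference_distribution()]).
#' @export
run_diff <- function(cs_list, pr_texts, bin_width = 5) {
  if (is.character(cs_list)) cs_list <- read_cs_json(cs_list)
  records <- list()
  for (pr_id in names(pr_texts)) {
    texts <- character(0)
    for (cs in cs_list) {
      ids <- unlist(lapply(cs$cited, function(w)
        c(w$pmid, w$doi, w$raw_key)))
      if (pr_id %in% ids) texts <- c(texts, cs$text)
    }
    if (length(texts) == 0L) {
      message("no citing statement found for document ", pr_id)
      next
    }
    rec <- tryCatch(
      max_difference_per_pr(pr_texts[[pr_id]], texts, pr_id = pr_id),
      error = function(e) {
        message("excluding document ", pr_id, ": ", conditionMessage(e))
        NULL
      })
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  if (length(records) == 0L) stop("no comparable document")
  df <- data.frame(
    pr_id = vapply(records, `[[`, character(1), "pr_id"),
    max_diff_vs_title_abstract = vapply(records, `[[`, numeric(1),
                                        "max_diff_vs_title_abstract"),
    max_diff_vs_fulltext = vapply(records, `[[`, numeric(1),
                                  "max_diff_vs_fulltext"),
    n_cs = vapply(records, `[[`, integer(1), "n_cs"),
    stringsAsFactors = FALSE)
  list(records = df,
       distribution = difference_distribution(records, bin_width))
}
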