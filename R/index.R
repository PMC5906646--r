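#' Build a searchable index over cited statements
#'
#' Creates an inverted index over the *text of the statements only* —
#' article and journal titles are deliberately never searchable, so results
#' are driven by what the statement itself says, not by metadata of the
#' article it came from. Tokens are produced by [analyze()]; relevance is
#' Okapi BM25 with constants `k1` and `b` stored in the index.
#'
#' @param cs_list non-empty list of `cited_statement` objects.
#' @param k1,b BM25 constants: `k1` saturates the term-frequency
#'   contribution (default 1.2), `b` scales document-length normalization
#'   (default 0.75). The defaults are the textbook values for short
#'   documents.
#' @return object of class `cs_index`.
#' @export
build_index <- function(cs_list, k1 = 1.2, b = 0.75) {
  if (length(cs_list) == 0L) stop("empty corpus")
  stopifnot(all(vapply(cs_list, inherits, logical(1), "cited_statement")))

  toks <- lapply(cs_list, function(cs) analyze(cs$text))
  doc_lengths <- lengths(toks)
  long_tok <- unlist(toks, use.names = FALSE)
  long_doc <- rep.int(seq_along(toks), doc_lengths)

  postings <- lapply(split(long_doc, long_tok), function(docs) {
    tab <- table(docs)
    stats::setNames(as.integer(tab), names(tab))
  })

  structure(list(
    postings = postings,
    doc_lengths = doc_lengths,
    n_docs = length(cs_list),
    avg_dl = mean(doc_lengths),
    k1 = k1,
    b = b,
    store = cs_list,
    cited_keys = lapply(cs_list, function(cs)
      unique(vapply(cs$cited, work_key, character(1))))
  ), class = "cs_index")
}

#' BM25 relevance of one statement for an analyzed query
#'
#' The score is the Okapi BM25 sum over the *distinct* analyzed query terms:
#'
#'   score = sum_t idf(t) * tf * (k1 + 1) / (tf + k1 * (1 - b + b * dl/avgdl))
#'
#' with the smoothed inverse document frequency
#'
#'   idf(t) = ln(1 + (N - df + 0.5) / (df + 0.5)),
#'
#' where `tf` is the term's frequency in the statement, `dl` the statement's
#' analyzed token count, `avgdl` the corpus mean length, `N` the number of
#' indexed statements and `df` the number containing the term. The idf
#' smoothing keeps every term's contribution non-negative, so a statement
#' containing no query term always scores exactly 0.
#'
#' @param index a `cs_index`.
#' @param query analyzed query, i.e. a character vector of tokens from
#'   [analyze()].
#' @param cs_id integer id of the statement (its position in the indexed
#'   list).
#' @return non-negative numeric scalar.
#' @export
bm25_score <- function(index, query, cs_id) {
  stopifnot(inherits(index, "cs_index"))
  if (length(cs_id) != 1L || is.na(cs_id) || cs_id < 1L ||
      cs_id > index$n_docs) {
    stop("unknown cs_id: ", cs_id)
  }
  terms <- unique(query)
  if (length(terms) == 0L) return(0)
  dl <- index$doc_lengths[[cs_id]]
  norm <- index$k1 * (1 - index$b + index$b * dl / index$avg_dl)
  s <- 0
  for (t in terms) {
    plist <- index$postings[[t]]
    if (is.null(plist)) next
    tf <- unname(plist[as.character(cs_id)])
    if (is.na(tf)) next
    df <- length(plist)
    idf <- log(1 + (index$n_docs - df + 0.5) / (df + 0.5))
    s <- s + idf * tf * (index$k1 + 1) / (tf + norm)
  }
  s
}

#' Shared-citation counts within a retrieved set
#'
#' For each retrieved statement, counts how many *other* statements in the
#' same retrieved set cite at least one common work (works compared by
#' [work_key()]). This is the ranking tie-breaker: among statements whose
#' rounded relevance ties, those commenting on heavily co-cited work rank
#' first.
#'
#' @param cited_sets list of character vectors of cited-work keys, one per
#'   retrieved statement.
#' @return integer vector of counts, same length as `cited_sets`.
#' @export
shared_citation_counts <- function(cited_sets) {
  n <- length(cited_sets)
  if (n == 0L) return(integer(0))
  docs_by_key <- split(rep.int(seq_len(n), lengths(cited_sets)),
                       unlist(cited_sets, use.names = FALSE))
  vapply(seq_len(n), function(i) {
    others <- unique(unlist(docs_by_key[cited_sets[[i]]], use.names = FALSE))
    length(setdiff(others, i))
  }, integer(1))
}

#' Round a relevance score to one decimal
#'
#' Half-away-from-zero rounding (2.35 becomes 2.4), applied to the raw BM25
#' score before ranking so that near-equal relevance collapses into ties
#' that the shared-citation count can break.
#'
#' @param x numeric vector.
#' @return numeric vector rounded to one decimal place.
#' @export
round_score <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10

#' Search the index
#'
#' Two-tier ranking over statements matching at least one query term:
#' descending rounded relevance ([round_score()] of the BM25 score), ties
#' broken by descending shared-citation count, remaining ties by ascending
#' statement id so the ordering is fully deterministic. Shared-citation
#' counts are computed over the whole candidate pool (all positive-score
#' statements, capped at `pool_size` by raw score) *before* truncation to
#' `top_k`, so the reported counts do not depend on how many results are
#' displayed.
#'
#' @param index a `cs_index`.
#' @param keywords free-text query string.
#' @param top_k maximum number of results (default 10).
#' @param pool_size cap on the tie-breaking candidate pool (default 1000).
#' @return `data.frame` with columns `cs_id`, `text`,
#'   `source_article_title`, `source_article_id`, `raw_score`,
#'   `rounded_score`, `shared_citations` and list-column `cited` of
#'   cited-work keys; zero rows when no statement matches. An empty query
#'   (nothing survives analysis) returns zero rows with a message.
#' @export
search_index <- function(index, keywords, top_k = 10L, pool_size = 1000L) {
  stopifnot(inherits(index, "cs_index"), top_k >= 1L)
  empty <- data.frame(
    cs_id = integer(0), text = character(0),
    source_article_title = character(0), source_article_id = character(0),
    raw_score = numeric(0), rounded_score = numeric(0),
    shared_citations = integer(0), stringsAsFactors = FALSE)
  empty$cited <- list()

  q <- unique(analyze(keywords))
  if (length(q) == 0L) {
    message("query contained no searchable terms")
    return(empty)
  }

  raw <- numeric(index$n_docs)
  for (t in q) {
    plist <- index$postings[[t]]
    if (is.null(plist)) next
    ids <- as.integer(names(plist))
    tf <- as.numeric(plist)
    df <- length(plist)
    idf <- log(1 + (index$n_docs - df + 0.5) / (df + 0.5))
    norm <- index$k1 *
      (1 - index$b + index$b * index$doc_lengths[ids] / index$avg_dl)
    raw[ids] <- raw[ids] + idf * tf * (index$k1 + 1) / (tf + norm)
  }

  cand <- which(raw > 0)
  if (length(cand) == 0L) return(empty)
  cand <- cand[order(-raw[cand], cand)]
  if (length(cand) > pool_size) cand <- cand[seq_len(pool_size)]

  rounded <- round_score(raw[cand])
  shared <- shared_citation_counts(index$cited_keys[cand])
  ord <- order(-rounded, -shared, cand)
  keep <- ord[seq_len(min(top_k, length(ord)))]

  ids <- cand[keep]
  res <- data.frame(
    cs_id = ids,
    text = vapply(index$store[ids], `[[`, character(1), "text"),
    source_article_title = vapply(index$store[ids], `[[`, character(1),
                                  "source_article_title"),
    source_article_id = vapply(index$store[ids], `[[`, character(1),
                               "source_article_id"),
    raw_score = raw[ids],
    rounded_score = rounded[keep],
    shared_citations = shared[keep],
    stringsAsFactors = FALSE)
  res$cited <- index$cited_keys[ids]
  rownames(res) <- NULL
  res
}

#' @export
print.cs_index <- function(x, ...) {
  cat("<cs_index> ", x$n_docs, " statements, ",
      length(x$postings), " terms, mean length ",
      round(x$avg_dl, 2), " tokens (BM25 k1=", x$k1, ", b=", x$b, ")\n",
      sep = "")
  invisible(x)
}
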