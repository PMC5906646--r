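# Shared fixtures built in code.

# minimal JATS article; paragraphs and refs are spliced in as raw XML
jats_article <- function(paragraphs,
                         refs = '<ref id="B1"><element-citation><pub-id pub-id-type="pmid">123</pub-id></element-citation></ref>',
                         title = "T", journal = "J",
                         with_body = TRUE, with_reflist = TRUE) {
  body <- if (with_body) {
    paste0("<body><sec>",
           paste0("<p>", paragraphs, "</p>", collapse = ""),
           "</sec></body>")
  } else ""
  back <- if (with_reflist) {
    paste0("<back><ref-list>", refs, "</ref-list></back>")
  } else "<back></back>"
  paste0('<?xml version="1.0" encoding="UTF-8"?>',
         "<article><front>",
         "<journal-meta><journal-title-group><journal-title>", journal,
         "</journal-title></journal-title-group></journal-meta>",
         "<article-meta>",
         '<article-id pub-id-type="pmid">999</article-id>',
         "<title-group><article-title>", title,
         "</article-title></title-group>",
         "</article-meta></front>", body, back, "</article>")
}

# ground-truth citing sentences of a generated corpus as (text, sorted ids)
gt_cs_table <- function(ground_truth) {
  rows <- list()
  for (art in ground_truth$articles) {
    for (s in art$sentences) {
      if (length(s$cited) == 0L) next
      rows[[length(rows) + 1L]] <-
        paste(s$text, paste(sort(unlist(s$cited)), collapse = ","),
              sep = "\t")
    }
  }
  sort(unlist(rows))
}

# extracted statements in the same comparable form (identifiers only)
extracted_cs_table <- function(cs_list) {
  rows <- vapply(cs_list, function(cs) {
    ids <- vapply(cs$cited, function(w) {
      if (!is.null(w$pmid)) w$pmid else if (!is.null(w$doi)) w$doi else
        w$raw_key
    }, character(1))
    paste(cs$text, paste(sort(ids), collapse = ","), sep = "\t")
  }, character(1))
  sort(rows)
}

# statements with controlled text/citations for retrieval tests
make_cs <- function(text, pmids = "1", id = "PMC1", title = "Title") {
  cited_statement(
    text = text,
    cited = lapply(as.character(pmids), function(p)
      cited_work(raw_key = paste0("B", p), pmid = p)),
    source_article_id = id,
    source_article_title = title,
    source_journal_title = "J")
}

# independent BM25 evaluation, written directly from the documented formula;
# `toks` is the corpus analyzed once (list of token vectors)
oracle_bm25 <- function(toks, query_tokens, doc, k1 = 1.2, b = 0.75) {
  n <- length(toks)
  dl <- lengths(toks)
  avgdl <- mean(dl)
  s <- 0
  for (t in unique(query_tokens)) {
    tf <- sum(toks[[doc]] == t)
    if (tf == 0) next
    df <- sum(vapply(toks, function(x) t %in% x, logical(1)))
    idf <- log(1 + (n - df + 0.5) / (df + 0.5))
    s <- s + idf * tf * (k1 + 1) / (tf + k1 * (1 - b + b * dl[doc] / avgdl))
  }
  s
}

# brute-force O(n^2) shared-citation oracle
oracle_shared <- function(cited_sets) {
  n <- length(cited_sets)
  vapply(seq_len(n), function(i) {
    sum(vapply(seq_len(n), function(j) {
      j != i && length(intersect(cited_sets[[i]], cited_sets[[j]])) > 0
    }, logical(1)))
  }, integer(1))
}

# brute-force ranking: score every statement, round, count shared citations
# over the positive-score set, sort by the documented key
oracle_ranking <- function(cs_list, keywords, top_k = 10L,
                           toks = lapply(cs_list,
                                         function(cs) analyze(cs$text))) {
  q <- unique(analyze(keywords))
  raw <- vapply(seq_along(cs_list), function(i)
    oracle_bm25(toks, q, i), numeric(1))
  cand <- which(raw > 0)
  if (length(cand) == 0L) return(integer(0))
  keys <- lapply(cs_list[cand], function(cs)
    unique(vapply(cs$cited, work_key, character(1))))
  shared <- oracle_shared(keys)
  rounded <- sign(raw[cand]) * floor(abs(raw[cand]) * 10 + 0.5) / 10
  ord <- order(-rounded, -shared, cand)
  cand[ord][seq_len(min(top_k, length(ord)))]
}
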