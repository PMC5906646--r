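test_that("the analyzer case-folds, drops stop words and stems", {
  expect_identical(analyze("Binding Proteins"), c("bind", "protein"))
  expect_identical(analyze("the of and"), character(0))
  expect_identical(analyze(""), character(0))
  # punctuation is consumed by tokenization; Greek letters survive
  expect_identical(analyze("α-helix unwinds!"), c("α", "helix", "unwind"))
  expect_false(any(analyze("The Quick Brown Foxes") %in%
                     english_stopwords()))
})

test_that("index construction reflects the analyzed statements", {
  expect_error(build_index(list()), "empty corpus")
  idx <- build_index(list(make_cs("protein binds DNA")))
  expect_setequal(names(idx$postings), c("protein", "bind", "dna"))
  expect_identical(idx$n_docs, 1L)

  # two identical texts share every posting list
  idx2 <- build_index(list(make_cs("kinase assay"), make_cs("kinase assay")))
  for (t in names(idx2$postings)) {
    expect_setequal(names(idx2$postings[[t]]), c("1", "2"))
  }

  # corpus statistics agree with a recount from the analyzer
  cs <- lapply(1:50, function(i)
    make_cs(paste(sample(.corpus_vocab, 6), collapse = " ")))
  idx3 <- build_index(cs)
  lens <- lengths(lapply(cs, function(x) analyze(x$text)))
  expect_identical(idx3$doc_lengths, lens)
  expect_equal(idx3$avg_dl, mean(lens))
  expect_identical(sum(lengths(idx3$postings)),
                   length(unique(unlist(lapply(seq_along(cs), function(i)
                     paste(i, unique(analyze(cs[[i]]$text))))))))
})

test_that("BM25 scores equal direct evaluation of the documented formula", {
  withr::local_seed(31)
  texts <- vapply(1:50, function(i)
    paste(sample(.corpus_vocab, sample(4:9, 1)), collapse = " "),
    character(1))
  cs <- lapply(texts, make_cs)
  idx <- build_index(cs)
  toks <- lapply(texts, analyze)
  for (rep in 1:20) {
    q <- analyze(paste(sample(.corpus_vocab, sample(1:3, 1)), collapse = " "))
    for (doc in sample(50, 5)) {
      expect_equal(bm25_score(idx, q, doc), oracle_bm25(toks, q, doc),
                   tolerance = 1e-12)
    }
  }
  # no query term in the statement -> exactly zero
  expect_identical(bm25_score(idx, analyze("zebrafish"), 1L), 0)
  expect_error(bm25_score(idx, "protein", 51L), "unknown cs_id")
})

test_that("duplicate statements score identically", {
  idx <- build_index(list(make_cs("kinase binds substrate"),
                          make_cs("kinase binds substrate"),
                          make_cs("unrelated fern text")))
  q <- analyze("kinase substrate")
  expect_identical(bm25_score(idx, q, 1L), bm25_score(idx, q, 2L))
})

test_that("shared-citation counts match the pairwise oracle", {
  same <- replicate(3, c("pmid:7"), simplify = FALSE)
  expect_identical(shared_citation_counts(same), c(2L, 2L, 2L))
  disjoint <- list("pmid:1", "pmid:2", "pmid:3")
  expect_identical(shared_citation_counts(disjoint), c(0L, 0L, 0L))
  mixed <- list(c("pmid:1", "pmid:2"), c("pmid:2", "pmid:3"),
                c("pmid:4"), c("pmid:3", "pmid:4"), c("pmid:5"))
  expect_identical(shared_citation_counts(mixed), oracle_shared(mixed))
  withr::local_seed(8)
  for (i in 1:20) {
    sets <- lapply(1:12, function(j)
      paste0("pmid:", sample(6, sample(1:3, 1))))
    expect_identical(shared_citation_counts(sets), oracle_shared(sets))
  }
})

test_that("score rounding is half-away-from-zero to one decimal", {
  expect_identical(round_score(c(2.35, 2.34999, 0.05, 0)),
                   c(2.4, 2.3, 0.1, 0))
})

test_that("search ranks by rounded score, shared citations, then id", {
  # single match
  idx <- build_index(list(make_cs("zebrafish model", pmids = "5"),
                          make_cs("kinase assay", pmids = "6")))
  res <- search_index(idx, "zebrafish")
  expect_identical(res$cs_id, 1L)

  # engineered tie: identical text (equal score), different citation overlap
  cs <- list(
    make_cs("conserved kinase motif", pmids = "1"),
    make_cs("conserved kinase motif", pmids = "9"),
    make_cs("kinase motif conserved", pmids = c("1", "2")),
    make_cs("distant filler sentence", pmids = "3"),
    make_cs("another kinase statement here", pmids = "1"))
  idx2 <- build_index(cs)
  res2 <- search_index(idx2, "conserved kinase motif")
  # statements 1 and 3 share pmid:1 (and 5 in pool); 2 shares none
  expect_true(which(res2$cs_id == 2L) > which(res2$cs_id == 1L))
  expect_identical(res2$cs_id[res2$shared_citations == 0 &
                                res2$rounded_score ==
                                max(res2$rounded_score)],
                   2L)
})

test_that("search ordering equals the brute-force oracle on a random corpus", {
  withr::local_seed(99)
  # narrow vocabulary + duplicated texts force plenty of rounded-score ties
  vocab <- .corpus_vocab[1:12]
  cs <- lapply(1:100, function(i) {
    txt <- paste(sample(vocab, sample(3:5, 1), replace = TRUE),
                 collapse = " ")
    make_cs(txt, pmids = as.character(sample(8, sample(1:2, 1))))
  })
  idx <- build_index(cs)
  toks <- lapply(cs, function(x) analyze(x$text))
  for (rep in 1:20) {
    q <- paste(sample(vocab, sample(1:2, 1)), collapse = " ")
    expect_identical(search_index(idx, q, top_k = 100L)$cs_id,
                     oracle_ranking(cs, q, top_k = 100L, toks = toks))
  }
})

test_that("only statement text is searchable, never article metadata", {
  cs <- list(make_cs("kinase phosphorylates substrate",
                     title = "Landmark zebrafish paper"))
  idx <- build_index(cs)
  expect_identical(nrow(search_index(idx, "zebrafish paper")), 0L)
  expect_identical(nrow(search_index(idx, "kinase")), 1L)
})

test_that("empty queries message and return nothing", {
  idx <- build_index(list(make_cs("kinase assay")))
  expect_message(res <- search_index(idx, "the of"), "no searchable terms")
  expect_identical(nrow(res), 0L)
})

test_that("top_k results are a prefix of the full ranking", {
  withr::local_seed(4)
  cs <- lapply(1:40, function(i)
    make_cs(paste(sample(.corpus_vocab[1:10], 4), collapse = " "),
            pmids = as.character(sample(5, 1))))
  idx <- build_index(cs)
  full <- search_index(idx, "protein kinase receptor", top_k = 40L)
  for (k in c(1L, 3L, 10L)) {
    expect_identical(search_index(idx, "protein kinase receptor",
                                  top_k = k)$cs_id,
                     utils::head(full$cs_id, k))
  }
  # repeated queries are deterministic
  expect_identical(search_index(idx, "protein kinase receptor", top_k = 40L),
                   full)
})
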