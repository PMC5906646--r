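test_that("corpus specs validate their inputs", {
  expect_error(corpus_spec(0), "n_articles")
  expect_error(corpus_spec(2, citing_fraction = 1.5), "\\[0, 1\\]")
  expect_error(corpus_spec(2, planted_difference_levels = c(-5)),
               "\\[0, 100\\]")
  expect_error(corpus_spec(2, shared_citation_graph = list("1")),
               "one element per article")
})

test_that("generation is deterministic and seeds differentiate corpora", {
  spec <- corpus_spec(4, seed = 77)
  a1 <- generate_article(spec, 2)
  a2 <- generate_article(spec, 2)
  expect_identical(a1, a2)
  other <- generate_article(corpus_spec(4, seed = 78), 2)
  expect_false(identical(a1$xml, other$xml))
  # generation does not disturb the caller's RNG stream
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(generate_corpus(spec)); after <- runif(3)
  expect_identical(before, after)
})

test_that("citing_fraction pins the ground-truth statement count", {
  none <- generate_corpus(corpus_spec(3, sentences_per_article = 10,
                                      citing_fraction = 0, seed = 3))
  expect_identical(none$ground_truth$n_cs, 0L)
  all_cite <- generate_corpus(corpus_spec(3, sentences_per_article = 10,
                                          citing_fraction = 1, seed = 3))
  expect_identical(all_cite$ground_truth$n_cs, 30L)
})

test_that("generated articles parse and extraction matches the slice", {
  spec <- corpus_spec(12, sentences_per_article = 10,
                      abbreviation_rate = 0.5,
                      post_period_citation_rate = 0.4, seed = 19)
  for (i in c(1L, 5L, 12L)) {
    art <- generate_article(spec, i)
    rec <- parse_jats(art$xml)
    cs <- extract_cited_statements(rec)
    gt <- Filter(function(s) length(s$cited) > 0L, art$ground_truth$sentences)
    expect_length(cs, length(gt))
    expect_identical(
      extracted_cs_table(cs),
      sort(vapply(gt, function(s)
        paste(s$text, paste(sort(unlist(s$cited)), collapse = ","),
              sep = "\t"), character(1))))
  }
})

test_that("articles cite within the supplied citation graph", {
  graph <- list(c("11", "12"), c("12"), c("13", "11"))
  spec <- corpus_spec(3, citing_fraction = 1, shared_citation_graph = graph,
                      seed = 2)
  corp <- generate_corpus(spec)
  for (i in 1:3) {
    cited <- unlist(lapply(corp$ground_truth$articles[[i]]$sentences,
                           `[[`, "cited"))
    expect_true(all(cited %in% graph[[i]]))
  }
})

test_that("planted difference levels are realized exactly", {
  spec <- corpus_spec(5, planted_difference_levels = c(0, 25, 50, 75, 100),
                      seed = 9)
  corp <- generate_corpus(spec)
  planted <- corp$ground_truth$planted
  expect_identical(nrow(planted), 5L)
  for (k in seq_len(nrow(planted))) {
    pr <- corp$pr_texts[[planted$pr_id[k]]]
    # collect the planted citing sentences from the ground truth
    texts <- character(0)
    for (art in corp$ground_truth$articles) {
      for (s in art$sentences) {
        if (planted$pr_id[k] %in% unlist(s$cited)) texts <- c(texts, s$text)
      }
    }
    expect_gte(length(texts), 1L)
    rec <- max_difference_per_pr(pr, texts, pr_id = planted$pr_id[k])
    expect_equal(rec$max_diff_vs_title_abstract, planted$level[k])
    expect_equal(rec$max_diff_vs_fulltext, planted$level[k])
  }
})

test_that("unrealizable planted constraints fail with an explanation", {
  expect_error(
    generate_corpus(corpus_spec(2, planted_difference_levels = 33.3,
                                seed = 1)),
    "whole percentages")
  expect_error(
    generate_corpus(corpus_spec(
      2, planted_difference_levels = rep(50, 10), seed = 1)),
    "reserved vocabulary")
})
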