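test_that("fingerprints are deduplicated normalized word sets", {
  expect_setequal(make_fingerprint("The binding of proteins binds protein"),
                  c("bind", "protein"))
  expect_identical(make_fingerprint(""), character(0))
  expect_true("α" %in% make_fingerprint("the α-helix unwinds"))
  fp <- make_fingerprint("Binding BINDS bound, binding!")
  expect_identical(anyDuplicated(fp), 0L)
  expect_false(any(fp %in% english_stopwords()))
})

test_that("difference is exact set arithmetic with the CS denominator", {
  expect_error(fingerprint_difference(character(0), "a"),
               "empty statement fingerprint")
  same <- c("bind", "protein")
  expect_equal(fingerprint_difference(same, same),
               list(absolute = 0L, percent = 0))
  d <- fingerprint_difference(c("a", "b", "c", "d"), c("c", "d", "e"))
  expect_equal(d, list(absolute = 2L, percent = 50))
  disjoint <- fingerprint_difference(c("x", "y"), c("p", "q"))
  expect_equal(disjoint$percent, 100)
  # difference against an empty reference is total
  expect_equal(fingerprint_difference(c("x", "y"), character(0))$percent, 100)
})

test_that("difference matches naive set subtraction on random pairs", {
  withr::local_seed(21)
  pool <- c(letters, LETTERS, paste0("w", 1:40))
  for (i in 1:300) {
    a <- sample(pool, sample(1:12, 1))
    b <- sample(pool, sample(0:12, 1))
    d <- fingerprint_difference(a, b)
    expect_identical(d$absolute, length(setdiff(a, b)))
    expect_equal(d$percent, 100 * length(setdiff(a, b)) / length(a))
    # monotonicity: enlarging the reference never increases the difference
    b2 <- unique(c(b, sample(pool, 3)))
    expect_lte(fingerprint_difference(a, b2)$percent, d$percent)
  }
})

test_that("fingerprints are stable and shrink only by normalization", {
  texts <- c("The binding of proteins binds protein",
             "Activated kinases phosphorylate substrates rapidly",
             "α-helix stability and β-sheet formation")
  for (tx in texts) {
    fp <- make_fingerprint(tx)
    # re-fingerprinting the same text is the identity
    expect_identical(make_fingerprint(tx), fp)
    # never larger than the token inventory, never duplicated
    expect_lte(length(fp), length(tokenize_words(tx)))
    expect_identical(anyDuplicated(fp), 0L)
  }
  # on stem-fixed-point vocabulary, re-fingerprinting the joined words is
  # the identity (suffix-bearing English words may re-stem further; the
  # fingerprint is defined by a single analyzer pass)
  fp <- make_fingerprint(paste(.planted_vocab[1:20], collapse = " "))
  expect_setequal(make_fingerprint(paste(fp, collapse = " ")), fp)
})

test_that("per-document maxima and their distribution are exact", {
  pr <- list(title_abstract = "alpha beta gamma", fulltext = "alpha beta gamma delta")
  rec <- max_difference_per_pr(
    pr, c("alpha beta gamma.", "epsilon zeta alpha beta."), pr_id = "X")
  expect_equal(rec$max_diff_vs_title_abstract, 50)
  expect_equal(rec$max_diff_vs_fulltext, 50)
  expect_identical(rec$n_cs, 2L)

  single <- max_difference_per_pr(pr, "delta epsilon.", pr_id = "Y")
  expect_equal(single$max_diff_vs_title_abstract, 100)
  expect_equal(single$max_diff_vs_fulltext, 50)

  expect_warning(
    expect_error(max_difference_per_pr(pr, "the of", pr_id = "Z"),
                 "no usable citing statement"),
    "empty fingerprint")

  recs <- list(rec, single,
               max_difference_per_pr(pr, "alpha beta gamma.", pr_id = "W"))
  dist <- difference_distribution(recs, bin_width = 25)
  expect_identical(dist$n_pr, 3L)
  hist <- dist$histogram
  expect_identical(sum(hist$count[hist$reference == "title_abstract"]), 3L)
  expect_identical(sum(hist$count[hist$reference == "fulltext"]), 3L)
  # maxima 50, 100, 0 vs title/abstract -> fractions over thresholds
  expect_equal(unname(dist$fractions["title_abstract"]), 2 / 3)
  expect_equal(unname(dist$fractions["fulltext"]), 2 / 3)
  expect_error(difference_distribution(list()), "no comparison records")
})

test_that("histogram equals a direct recount on random records", {
  withr::local_seed(13)
  recs <- lapply(1:200, function(i) {
    structure(list(pr_id = as.character(i),
                   max_diff_vs_title_abstract = sample(0:100, 1),
                   max_diff_vs_fulltext = sample(0:100, 1),
                   n_cs = 1L), class = "pr_comparison")
  })
  dist <- difference_distribution(recs, bin_width = 10)
  ta <- vapply(recs, `[[`, numeric(1), "max_diff_vs_title_abstract")
  for (r in seq_len(10)) {
    lo <- (r - 1) * 10
    hi <- r * 10
    want <- if (r == 10) sum(ta >= lo & ta <= hi) else sum(ta >= lo & ta < hi)
    got <- dist$histogram$count[dist$histogram$reference == "title_abstract" &
                                  dist$histogram$bin_lo == lo]
    expect_identical(got, want)
  }
  expect_equal(unname(dist$fractions["title_abstract"]), mean(ta >= 50))
})
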