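#' Build the textual fingerprint of a text
#'
#' A fingerprint is the deduplicated set of normalized words of a text — a
#' proxy for how a keyword retrieval system "sees" it. The normalization is
#' the exact analysis chain of the search side ([analyze()]): tokenize,
#' case-fold, strip punctuation (letters of any script and digits survive,
#' so Greek symbols are retained), drop stop words, Porter-stem, then
#' deduplicate. Because fingerprints and the index share one analyzer, a
#' small fingerprint difference really does mean the retrieval system would
#' treat the two texts as near-equivalent.
#'
#' @param text character scalar.
#' @return character vector of unique normalized words (possibly empty).
#' @examples
#' make_fingerprint("The binding of proteins binds protein")
#' @export
make_fingerprint <- function(text) {
  unique(analyze(text))
}

#' Difference between a statement fingerprint and a reference fingerprint
#'
#' Counts the normalized words of the statement fingerprint that are absent
#' from the reference fingerprint, absolutely and as a percentage of the
#' statement fingerprint size. The percentage answers: how much of the
#' statement is *new* relative to the reference document? 0 means every
#' word of the statement also occurs in the reference; 100 means the two
#' share nothing.
#'
#' @param cs_fp fingerprint of the citing statement (non-empty).
#' @param ref_fp fingerprint of the reference text (title/abstract or full
#'   text); may be empty.
#' @return list with `absolute` (integer) and `percent` (numeric in
#'   \[0, 100\]).
#' @export
fingerprint_difference <- function(cs_fp, ref_fp) {
  if (length(cs_fp) == 0L) stop("empty statement fingerprint")
  absolute <- sum(!cs_fp %in% ref_fp)
  list(absolute = as.integer(absolute),
       percent = 100 * absolute / length(cs_fp))
}

#' Maximum fingerprint difference of the statements citing one document
#'
#' For one primary-research (PR) document — the document a set of citing
#' statements refers to — computes the fingerprint difference of every
#' statement against the PR's title/abstract and against its full text, and
#' records the maximum percentage for each reference. A large maximum means
#' at least one statement about this document carries wording that a
#' title/abstract (or full-text) search on the document itself could never
#' match.
#'
#' Statements whose fingerprint is empty after normalization are skipped
#' with a warning; if none remain the PR cannot be compared and an error is
#' raised (callers exclude the PR and log it).
#'
#' @param pr list with character fields `title_abstract` and `fulltext`.
#' @param cs_texts character vector of citing-statement texts (length >= 1).
#' @param pr_id identifier string for the PR document.
#' @return object of class `pr_comparison`: list with `pr_id`,
#'   `max_diff_vs_title_abstract`, `max_diff_vs_fulltext`, `n_cs`.
#' @export
max_difference_per_pr <- function(pr, cs_texts, pr_id = "") {
  stopifnot(is.list(pr), !is.null(pr$title_abstract), !is.null(pr$fulltext),
            length(cs_texts) >= 1L)
  ta_fp <- make_fingerprint(pr$title_abstract)
  ft_fp <- make_fingerprint(pr$fulltext)

  fps <- lapply(cs_texts, make_fingerprint)
  usable <- lengths(fps) > 0L
  if (any(!usable)) {
    warning(sum(!usable), " statement(s) with empty fingerprint skipped",
            call. = FALSE)
  }
  fps <- fps[usable]
  if (length(fps) == 0L) {
    stop("no usable citing statement for PR '", pr_id, "'", call. = FALSE)
  }

  d_ta <- vapply(fps, function(f) fingerprint_difference(f, ta_fp)$percent,
                 numeric(1))
  d_ft <- vapply(fps, function(f) fingerprint_difference(f, ft_fp)$percent,
                 numeric(1))
  structure(list(
    pr_id = pr_id,
    max_diff_vs_title_abstract = max(d_ta),
    max_diff_vs_fulltext = max(d_ft),
    n_cs = length(fps)
  ), class = "pr_comparison")
}

#' Distribution of per-document maximum differences
#'
#' Bins the per-PR maximum difference percentages into a histogram for each
#' reference type and reports, for each reference type, the fraction of PR
#' documents whose maximum difference reaches a threshold (by default 50%
#' against title/abstract and 25% against full text — the summary view of
#' whether citing statements carry information unavailable from the
#' documents themselves).
#'
#' @param records list of `pr_comparison` objects.
#' @param bin_width histogram bin width in percentage points (default 5).
#' @param thresholds named numeric vector with elements `title_abstract`
#'   and `fulltext`.
#' @return list with `histogram` (data.frame: `reference`, `bin_lo`,
#'   `bin_hi`, `count`; counts per reference sum to `length(records)`),
#'   `fractions` (named: fraction of PRs at or above each threshold) and
#'   `n_pr`.
#' @export
difference_distribution <- function(records, bin_width = 5,
                                    thresholds = c(title_abstract = 50,
                                                   fulltext = 25)) {
  if (length(records) == 0L) stop("no comparison records")
  stopifnot(bin_width > 0, 100 %% bin_width == 0)
  ta <- vapply(records, `[[`, numeric(1), "max_diff_vs_title_abstract")
  ft <- vapply(records, `[[`, numeric(1), "max_diff_vs_fulltext")

  n_bins <- as.integer(100 / bin_width)
  bin_of <- function(p) pmin(floor(p / bin_width), n_bins - 1L)
  hist_of <- function(p, ref) {
    counts <- tabulate(bin_of(p) + 1L, nbins = n_bins)
    data.frame(
      reference = ref,
      bin_lo = bin_width * (seq_len(n_bins) - 1L),
      bin_hi = bin_width * seq_len(n_bins),
      count = counts,
      stringsAsFactors = FALSE)
  }
  list(
    histogram = rbind(hist_of(ta, "title_abstract"), hist_of(ft, "fulltext")),
    fractions = c(
      title_abstract = mean(ta >= thresholds[["title_abstract"]]),
      fulltext = mean(ft >= thresholds[["fulltext"]])),
    n_pr = length(records))
}

#' @export
print.pr_comparison <- function(x, ...) {
  cat("<pr_comparison> ", x$pr_id, ": max diff ",
      round(x$max_diff_vs_title_abstract, 1), "% vs title/abstract, ",
      round(x$max_diff_vs_fulltext, 1), "% vs full text (",
      x$n_cs, " statement(s))\n", sep = "")
  invisible(x)
}
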