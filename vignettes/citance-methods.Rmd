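---
title: "Methods: extracting, ranking and comparing Cited Statements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extracting, ranking and comparing Cited Statements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citance)
```

## The object of study

A *Cited Statement* (CS) is a sentence in a peer-reviewed article that
carries one or more citations to other manuscripts; the cited manuscript is
the *primary research* (PR) document. A corpus constrained to CSs is
interesting for two reasons: each CS is a short, self-contained claim
backed by evidence, and each CS describes a PR document in words its own
title, abstract or even full text may never use. `citance` implements the
full desk-scale machinery for working with such a corpus: extraction from
JATS XML, keyword retrieval with a citation-aware tie-break, and the
fingerprint-difference statistic that quantifies how much of a CS is
textually new relative to the PR it cites.

## Extraction model

### Sentence segmentation

Scientific prose defeats naive period splitting, so segmentation uses
terminal periods with two protections:

* a pinned list of short-hands whose periods never split: `et al.`, `ca.`,
  `e.g.`, `i.e.`, `Fig.`, `Figs.`, `vs.`, `Dr.`, `cf.`, `approx.`, `Eq.`,
  `No.`;
* abbreviated genus names: a lone capital letter, a period, then a
  lower-case word (`H. pylori`). Requiring the following word to be
  lower-case is what keeps a genuine boundary such as "… showed X. We
  confirm …" splittable; the cost is that a genus followed by a
  capitalized species epithet would split, which we accept as rare.

Citation markers that trail a terminal period — directly attached,
space-separated, or bracket-wrapped, up to the first character of the next
sentence — are kept with the sentence they follow. This window is the
package's concrete reading of "a citation may occur after the sentence's
terminal period": the rule needs an extent, and anything past the next
sentence's first word would be ambiguous.

Segmentation is lossless (re-joining reproduces the paragraph modulo
inter-sentence whitespace), which is what makes exact ground-truth
comparison possible.

### What counts as a citation

In JATS, citations are `<xref>` elements. The package types an xref as
bibliographic when `ref-type="bibr"`, or, when `ref-type` is absent, when
its `rid` resolves into the back-matter reference list; figure and table
xrefs are non-bibliographic and can never create a CS nor contribute a
cited work. A bibliographic marker whose rid does not resolve still yields
a cited work carrying the raw rid (with a warning) — dropping the sentence
would silently bias extraction against articles with messy back matter.

Cited works are identified by PMID when present, else DOI, else the raw
rid, and deduplicated within a statement under that key. The same key
drives shared-citation counting at search time, so "the same work cited
twice" means the same thing everywhere.

Inline citation text (reference numerals such as `[1]`) is stripped from
the stored statement: the searchable unit is the claim, and indexing
numerals would let queries match typography rather than content.

## Retrieval model

The analyzer is one fixed chain used verbatim by both the index and the
fingerprints: tokenize on any character that is neither letter nor digit
(hyphens split compounds; Greek letters and digits survive), case-fold,
drop stop words, stem. The stop-word list and the Porter (1980) stemmer are
vendored inside the package rather than taken from an external library:
analysis must be bit-stable, because scores, fingerprints and the planted
ground truth are all defined relative to it.

Relevance is Okapi BM25 with `k1 = 1.2`, `b = 0.75`, smoothed idf
`ln(1 + (N − df + 0.5)/(df + 0.5))`, document length = analyzed token
count, summed over *distinct* query terms (repeating a keyword in a query
does not multiply its weight; queries here are keyword sets, not prose).
These constants are the contemporary defaults for short-document retrieval
and are recorded in the index object itself.

Ranking is two-tier: raw scores are rounded to one decimal —
half-away-from-zero, so `2.35 → 2.4` — and ties in the rounded score are
broken by the number of *other retrieved statements* sharing at least one
cited work, then by ascending statement id for full determinism. The
shared-citation count is computed over the whole candidate pool (every
statement with positive score, capped at `pool_size = 1000` by raw score)
*before* truncation to `top_k`, so a result's tie-break value does not
depend on how many results the caller asked to see. Among the plausible
readings of "shared citations between resulting documents" we chose the
per-result overlap count within the retrieved set; it is the reading that
directly expresses "statements about heavily co-cited work rank first" and
it is cheap to verify against an O(n²) scan.

Only statement text is indexed. A query that matches an article title and
no statement returns nothing — this opacity is asserted in the tests, since
it is the property that makes the corpus genuinely statement-constrained.

## Fingerprints and the difference statistic

The fingerprint of a text is its deduplicated set of analyzer tokens. The
difference of a statement fingerprint `S` against a reference fingerprint
`R` is `|S \ R|`, reported also as `100·|S \ R|/|S|`. The denominator is
`|S|`: the question asked is *how much of the statement* is new relative to
the document, and this normalization keeps single-sentence fingerprints
comparable regardless of reference length. An empty statement fingerprint
has no meaningful difference and is an error; pipeline callers skip such
records with a warning.

Reference texts come in two flavours per PR document: `title_abstract`
(title and abstract concatenated before fingerprinting) and `fulltext`,
which *includes* the title/abstract and *excludes* the reference list —
bibliographies would trivially absorb cited-author surnames and deflate
the statistic. Because the full-text fingerprint is a superset of the
title/abstract fingerprint, the difference against full text can never
exceed the difference against title/abstract.

Per PR document, the pipeline records the maximum difference over all its
citing statements, and `difference_distribution()` summarizes the records
as histograms plus the fractions of documents whose maximum reaches a
threshold (defaults 50% vs title/abstract, 25% vs full text).

One subtlety worth stating: fingerprints are defined by a *single* pass of
the analyzer. Porter stems are not fixed points of the stemmer
("kinases" stems to "kinas", which would re-stem to "kina"), so
re-fingerprinting the joined words of a fingerprint is not the identity in
general. No pipeline operation ever stems twice.

## The synthetic corpus

The generator produces well-formed JATS articles whose ground truth is
known by construction, emulating exactly the phenomena the extractor must
survive: protected abbreviations and genus short-hands inside sentences,
figure xrefs, bibliographic xrefs inline and after the terminal period,
xrefs with and without `ref-type`, multi-work citations, and a citation
graph that makes articles co-cite so the ranking tie-break is exercised.
Sentences are drawn from a fixed vocabulary chosen to survive stop-word
removal; per-article seeds derived from the spec seed make every article a
pure function of the spec (byte-identical on re-run, regardless of the
caller's RNG state).

Default rates — 10 sentences per article, citing fraction 0.5,
abbreviation rate 0.3, post-period citation rate 0.2, non-bibliographic
rate 0.1 — are the reference conditions used throughout the tests; they
put roughly one extraction hazard in every second sentence, which is
deliberately harsher than typical PMC prose.

Planted difference levels are engineered in stem space: each planted PR
document gets citing sentences built from a reserved vocabulary with
pairwise-distinct stems, and reference texts sharing exactly the number of
stems that realizes the requested percentage, with filler words disjoint
in stem space. Levels must be whole percentages realizable with a
fingerprint of at most a few dozen words (`n = 100/gcd(L, 100)` words,
padded to at least 4); anything else raises an explanatory error rather
than approximating. The construction is self-checked at generation time by
running the real fingerprint pipeline.

What the generator does **not** emulate: natural-language syntax and
morphology (tokens are dictionary words, not inflected prose), realistic
citation-count distributions, OCR noise, deeply nested JATS (tables,
display formulas, footnotes), and non-Latin scripts beyond what unit tests
cover. Passing the synthetic suite therefore demonstrates the pipeline's
*contracts* — exact extraction under the modelled hazards, exact scoring
and ordering, exact set arithmetic — not robustness to every artefact of
real PMC XML.

## Numerical and scale choices

* BM25 arithmetic is plain double precision; the engine and the in-test
  closed-form oracle agree to 1e−9 (observed: exactly, since both sum the
  same terms).
* Score rounding is half-away-from-zero on the double value; scores within
  5e−2 of each other can land in the same rounded tier, which is the
  intended collapsing behaviour.
* Ties after (rounded score, shared citations) break by ascending id —
  indexing order — so repeated queries are reproducible.
* Test and acceptance problem sizes: 200-article corpora for extraction
  exactness, 50–100 statements for scoring/ranking oracles, 1000 random
  pairs for set-difference properties, 40 articles for end-to-end
  round-trips. These sizes give exact oracles room to run in seconds while
  still exercising every code path; all scale linearly if enlarged.

## Known limitations

* The abbreviation list is fixed; domain-specific short-hands outside it
  ("wt.", "approx" variants, journal-specific abbreviations) will cause
  false splits. Extending the list is a one-line change but alters
  segmentation output, so it is versioned with the package.
* The genus rule requires a lower-case continuation, so "E. Coli"
  (capitalized epithet) splits.
* One sentence is one statement: a multi-sentence argument sharing a
  single citation yields one CS for the citing sentence only.
* `run_diff()` matches statements to PR documents by identifier equality
  (PMID, DOI or raw key); it does not attempt bibliographic record
  linkage.
* The index lives in memory and serializes via RDS; corpus scale is
  bounded by RAM, which is ample for desk-scale corpora but not for a
  production deployment.
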