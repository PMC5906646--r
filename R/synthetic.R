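# Generator vocabulary: lower-case biomedical words chosen so that none is a
# stop word and sentences built from them survive analysis unambiguously.
.corpus_vocab <- c(
  "protein", "kinase", "receptor", "genome", "sequence", "tumor", "neuron",
  "enzyme", "substrate", "membrane", "ligand", "antibody", "antigen",
  "plasmid", "chromatin", "histone", "promoter", "codon", "ribosome",
  "mitochondria", "cytoplasm", "nucleus", "peptide", "glucose", "insulin",
  "collagen", "fibroblast", "macrophage", "lymphocyte", "cytokine",
  "interferon", "apoptosis", "mutation", "allele", "phenotype", "genotype",
  "transcription", "translation", "replication", "polymerase", "helicase",
  "ligase", "nuclease", "telomere", "centromere", "microtubule", "actin",
  "myosin", "pathway", "signaling", "regulation", "expression",
  "inhibition", "activation", "infection", "bacteria", "virus",
  "differentiation", "proliferation", "migration", "adhesion", "oxidation",
  "phosphorylation", "methylation", "degradation", "stability",
  "conformation", "crystallography", "microscopy", "fluorescence",
  "quantification", "measurement", "hypothesis", "analysis", "algorithm",
  "clustering", "classification", "binding", "cleavage", "secretion"
)

# Reserved vocabulary for planted-difference construction. Stems must be
# pairwise distinct (asserted at plan time) so set arithmetic on
# fingerprints is exact by construction.
.planted_vocab <- c(
  "zebrafish", "drosophila", "nematode", "xenopus", "arabidopsis", "yeast",
  "maize", "salmon", "ferret", "marmoset", "axolotl", "lamprey", "diatom",
  "archaea", "bryozoan", "copepod", "krill", "plankton", "lichen", "moss",
  "fern", "conifer", "orchid", "cactus", "tundra", "estuary", "sediment",
  "basalt", "quartz", "feldspar", "gypsum", "obsidian", "magma", "glacier",
  "fjord", "lagoon", "atoll", "dune", "savanna", "taiga", "monsoon",
  "cyclone", "aurora", "eclipse", "quasar", "pulsar", "nebula", "comet",
  "asteroid", "meteorite", "isotope", "neutrino", "photon", "quark",
  "lepton", "boson", "hadron", "plasma", "vortex", "lattice"
)

.abbrev_phrases <- c("et al.", "ca.", "e.g.", "Fig. 2", "H. pylori",
                     "E. coli", "S. cerevisiae")

#' Specify a synthetic corpus
#'
#' Bundles the knobs of the synthetic JATS generator: corpus size, how often
#' sentences cite, how often they carry abbreviation traps for the sentence
#' splitter, how often citations land after the terminal period, plus an
#' optional citation graph and optional planted per-document fingerprint
#' difference levels. Every downstream draw is derived from `seed`, so a
#' spec pins the corpus byte-for-byte.
#'
#' @param n_articles number of articles (>= 1).
#' @param sentences_per_article sentences in each article body.
#' @param citing_fraction probability that a sentence cites (in \[0, 1\]).
#' @param abbreviation_rate probability a sentence carries a protected
#'   short-hand ("et al.", "ca.", a genus abbreviation, ...).
#' @param post_period_citation_rate probability that a citing sentence's
#'   citation appears after its terminal period.
#' @param nonbib_rate probability a sentence carries a non-bibliographic
#'   (figure) xref.
#' @param shared_citation_graph optional list, one element per article, of
#'   PMID strings the article may cite; `NULL` derives one from the seed.
#' @param planted_difference_levels optional numeric vector of target
#'   maximum fingerprint-difference percentages, one planted cited document
#'   each; names are used as document ids when given.
#' @param seed integer seed.
#' @return object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_articles,
                        sentences_per_article = 10L,
                        citing_fraction = 0.5,
                        abbreviation_rate = 0.3,
                        post_period_citation_rate = 0.2,
                        nonbib_rate = 0.1,
                        shared_citation_graph = NULL,
                        planted_difference_levels = NULL,
                        seed = 1L) {
  stopifnot(n_articles >= 1L, sentences_per_article >= 1L)
  for (p in c(citing_fraction, abbreviation_rate, post_period_citation_rate,
              nonbib_rate)) {
    if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1) {
      stop("rates must be single numbers in [0, 1]")
    }
  }
  if (!is.null(shared_citation_graph) &&
      length(shared_citation_graph) != n_articles) {
    stop("shared_citation_graph must have one element per article")
  }
  if (!is.null(planted_difference_levels)) {
    if (any(planted_difference_levels < 0 | planted_difference_levels > 100)) {
      stop("planted difference levels must lie in [0, 100]")
    }
  }
  structure(list(
    n_articles = as.integer(n_articles),
    sentences_per_article = as.integer(sentences_per_article),
    citing_fraction = citing_fraction,
    abbreviation_rate = abbreviation_rate,
    post_period_citation_rate = post_period_citation_rate,
    nonbib_rate = nonbib_rate,
    shared_citation_graph = shared_citation_graph,
    planted_difference_levels = planted_difference_levels,
    seed = as.integer(seed)
  ), class = "corpus_spec")
}

# run expr under a derived local seed without touching the caller's RNG
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

article_seed <- function(spec, article_index) {
  # computed in double to avoid 32-bit integer overflow for large corpora
  as.integer((as.numeric(spec$seed %% 100000L) * 20011 +
                as.numeric(article_index) * 7919) %% 2147483647)
}

# deterministic per-article citable PMID pool
citable_pmids <- function(spec, article_index) {
  if (!is.null(spec$shared_citation_graph)) {
    return(as.character(spec$shared_citation_graph[[article_index]]))
  }
  pool_size <- max(5L, ceiling(spec$n_articles / 4))
  pool <- as.character(1000000L + seq_len(pool_size))
  with_local_seed(article_seed(spec, article_index) + 1L,
                  sample(pool, min(3L, pool_size)))
}

# Plan for planted-difference documents: a pure function of the spec.
# Each level L gets one cited document with engineered texts and two citing
# sentences, the first realizing difference exactly L (in stem space, for
# both references), the second fully covered by the reference texts.
planted_plan <- function(spec) {
  levels <- spec$planted_difference_levels
  if (is.null(levels) || length(levels) == 0L) return(NULL)
  stems <- porter_stem(.planted_vocab)
  stopifnot(!anyDuplicated(stems), !any(.planted_vocab %in% .citance_stopwords))

  ids <- names(levels)
  if (is.null(ids)) ids <- as.character(2000000L + seq_along(levels))

  plan <- vector("list", length(levels))
  cursor <- 0L
  for (k in seq_along(levels)) {
    L <- levels[[k]]
    n0 <- 100L / gcd_int(as.integer(round(L)), 100L)
    if (abs(L - round(L)) > 1e-9) {
      stop("planted level ", L, " cannot be realized exactly: ",
           "levels must be whole percentages")
    }
    n <- n0 * ceiling(4 / n0)
    s <- n - as.integer(round(L * n / 100))
    need <- n + 7L
    if (cursor + need > length(.planted_vocab)) {
      stop("planted constraints exhaust the reserved vocabulary (",
           length(levels), " levels requested); reduce the number of ",
           "planted documents")
    }
    words <- .planted_vocab[cursor + seq_len(need)]
    cursor <- cursor + need
    cs_words <- words[seq_len(n)]
    fill_ta <- words[n + 1:4]
    fill_ft <- words[n + 5:7]
    ta_text <- paste(c(cs_words[seq_len(s)], fill_ta), collapse = " ")
    ft_text <- paste(c(ta_text, fill_ft), collapse = " ")
    cs1 <- paste0(paste(cs_words, collapse = " "), ".")
    cs2 <- paste0(paste(fill_ta, collapse = " "), ".")
    plan[[k]] <- list(
      pr_id = ids[k], level = L,
      article = 1L + (k - 1L) %% spec$n_articles,
      cs_texts = c(cs1, cs2),
      title_abstract = ta_text, fulltext = ft_text)
  }
  # construction self-check: recovered differences equal the planted levels
  for (p in plan) {
    d <- fingerprint_difference(make_fingerprint(p$cs_texts[1]),
                                make_fingerprint(p$title_abstract))$percent
    stopifnot(abs(d - p$level) < 1e-9)
  }
  plan
}

gcd_int <- function(a, b) {
  while (b != 0L) {
    t <- b
    b <- a %% b
    a <- t
  }
  max(a, 1L)
}

#' Generate one synthetic JATS article
#'
#' Builds a well-formed JATS XML article whose body sentences exercise, at
#' the rates in the spec, the situations the extraction pipeline must
#' handle: protected abbreviations, non-bibliographic figure xrefs,
#' bibliographic xrefs placed inline or after the terminal period, and
#' xrefs with and without an explicit `ref-type` attribute. The returned
#' ground truth records every sentence verbatim as the extractor should
#' recover it, together with the PMIDs it cites.
#'
#' Output is a pure function of `(spec, article_index)`: re-running with the
#' same spec yields byte-identical XML.
#'
#' @param spec a [corpus_spec()].
#' @param article_index article number (1-based).
#' @return list with `xml` (JATS document string) and `ground_truth`
#'   (list: `article_id`, `sentences` = list of `list(text, cited)`).
#' @export
generate_article <- function(spec, article_index) {
  stopifnot(inherits(spec, "corpus_spec"),
            article_index >= 1L, article_index <= spec$n_articles)
  citable <- citable_pmids(spec, article_index)
  plan <- planted_plan(spec)
  planted_here <- if (is.null(plan)) list() else {
    plan[vapply(plan, function(p) p$article == article_index, logical(1))]
  }

  with_local_seed(article_seed(spec, article_index), {
    sentences <- vector("list", spec$sentences_per_article)
    for (j in seq_len(spec$sentences_per_article)) {
      words <- sample(.corpus_vocab, sample(5:9, 1L))
      if (stats::runif(1) < spec$abbreviation_rate) {
        ab <- sample(.abbrev_phrases, 1L)
        pos <- sample(seq_along(words), 1L)
        words <- append(words, ab, after = pos)
      }
      cited <- character(0)
      post <- FALSE
      if (stats::runif(1) < spec$citing_fraction && length(citable) > 0L) {
        cited <- sample(citable, min(sample(1:2, 1L), length(citable)))
        post <- stats::runif(1) < spec$post_period_citation_rate
      }
      sentences[[j]] <- list(
        core = paste(words, collapse = " "),
        cited = cited, post = post,
        nonbib = stats::runif(1) < spec$nonbib_rate,
        no_reftype = stats::runif(1) < 0.25)
    }
    for (p in planted_here) {
      for (cs in p$cs_texts) {
        sentences[[length(sentences) + 1L]] <- list(
          core = sub("\\.$", "", cs),
          cited = p$pr_id, post = FALSE, nonbib = FALSE, no_reftype = FALSE)
      }
    }

    # rid assignment in first-use order
    used <- unique(unlist(lapply(sentences, `[[`, "cited")))
    rid_of <- stats::setNames(paste0("B", seq_along(used)), used)

    render_xref <- function(pmid, num, no_reftype) {
      rt <- if (no_reftype) "" else ' ref-type="bibr"'
      sprintf('<xref%s rid="%s">[%d]</xref>', rt, rid_of[[pmid]], num)
    }

    fig_count <- 0L
    xml_sentences <- vapply(seq_along(sentences), function(j) {
      s <- sentences[[j]]
      core <- s$core
      if (isTRUE(s$nonbib)) {
        fig_count <<- fig_count + 1L
        fig <- sprintf('<xref ref-type="fig" rid="F%d">Fig. %d</xref>',
                       fig_count, fig_count)
        core <- sub("(\\S+)", paste0("\\1", gsub("\\\\", "\\\\\\\\", fig)),
                    core)
      }
      if (length(s$cited) == 0L) return(paste0(core, "."))
      xrs <- paste(vapply(seq_along(s$cited), function(i) {
        render_xref(s$cited[[i]], match(s$cited[[i]], used), s$no_reftype)
      }, character(1)), collapse = "")
      if (isTRUE(s$post)) paste0(core, ".", xrs) else paste0(core, xrs, ".")
    }, character(1))

    paras <- split(xml_sentences,
                   ceiling(seq_along(xml_sentences) / 5))
    para_xml <- vapply(paras, function(p) {
      paste0("<p>", paste(p, collapse = " "), "</p>")
    }, character(1))

    refs_xml <- vapply(used, function(pmid) {
      doi <- if (as.numeric(gsub("\\D", "", pmid)) %% 2 == 0) {
        sprintf('<pub-id pub-id-type="doi">10.1000/synthetic.%s</pub-id>',
                pmid)
      } else ""
      sprintf(paste0('<ref id="%s"><element-citation>',
                     '<pub-id pub-id-type="pmid">%s</pub-id>%s',
                     "</element-citation></ref>"),
              rid_of[[pmid]], pmid, doi)
    }, character(1))

    pmid <- 9000000L + article_index
    title_words <- sample(.corpus_vocab, 2L)
    xml <- paste0(
      '<?xml version="1.0" encoding="UTF-8"?>\n',
      "<article><front>",
      "<journal-meta><journal-title-group><journal-title>",
      "Journal of Synthetic Biology ", 1L + article_index %% 3L,
      "</journal-title></journal-title-group></journal-meta>",
      "<article-meta>",
      '<article-id pub-id-type="pmcid">PMC', pmid, "</article-id>",
      '<article-id pub-id-type="pmid">', pmid, "</article-id>",
      "<title-group><article-title>Synthetic study of ",
      paste(title_words, collapse = " and "), " (", article_index,
      ")</article-title></title-group>",
      "</article-meta></front><body><sec><title>Results</title>",
      paste(para_xml, collapse = ""),
      "</sec></body><back><ref-list>",
      paste(refs_xml, collapse = ""),
      "</ref-list></back></article>\n")

    ground_truth <- list(
      article_id = paste0("PMC", pmid),
      sentences = lapply(sentences, function(s) {
        list(text = paste0(s$core, "."), cited = as.character(s$cited))
      }))
    list(xml = xml, ground_truth = ground_truth)
  })
}

#' Generate a synthetic corpus with ground truth
#'
#' Runs [generate_article()] over the whole spec and assembles the
#' corpus-level ground truth: the exact citing-sentence inventory (the
#' oracle for extraction precision/recall), the planted cited-document
#' texts and their target difference levels (the oracle for the
#' fingerprint analysis), and the total citing-sentence count.
#'
#' @param spec a [corpus_spec()].
#' @return list with `articles` (character vector of JATS XML documents),
#'   `ground_truth` (list: `articles` = per-article slices, `n_cs` = total
#'   citing-sentence count, `planted` = data.frame of planted levels or
#'   `NULL`), and `pr_texts` (named list of
#'   `list(title_abstract, fulltext)` for planted documents).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  gen <- lapply(seq_len(spec$n_articles), function(i)
    generate_article(spec, i))
  gts <- lapply(gen, `[[`, "ground_truth")
  n_cs <- sum(vapply(gts, function(g)
    sum(lengths(lapply(g$sentences, `[[`, "cited")) > 0L), integer(1)))

  plan <- planted_plan(spec)
  planted_df <- NULL
  pr_texts <- list()
  if (!is.null(plan)) {
    planted_df <- data.frame(
      pr_id = vapply(plan, `[[`, character(1), "pr_id"),
      level = vapply(plan, `[[`, numeric(1), "level"),
      article = vapply(plan, `[[`, integer(1), "article"),
      stringsAsFactors = FALSE)
    pr_texts <- stats::setNames(
      lapply(plan, function(p)
        list(title_abstract = p$title_abstract, fulltext = p$fulltext)),
      planted_df$pr_id)
  }

  list(articles = vapply(gen, `[[`, character(1), "xml"),
       ground_truth = list(articles = gts, n_cs = n_cs,
                           planted = planted_df),
       pr_texts = pr_texts)
}

#' @export
print.corpus_spec <- function(x, ...) {
  cat("<corpus_spec> ", x$n_articles, " article(s) x ",
      x$sentences_per_article, " sentence(s); citing ",
      x$citing_fraction, ", abbrev ", x$abbreviation_rate,
      ", post-period ", x$post_period_citation_rate,
      "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}
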