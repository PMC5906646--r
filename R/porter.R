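#' Porter stemmer (original 1980 algorithm)
#'
#' Reduces an English word to its stem using the original five-step Porter
#' suffix-stripping algorithm, so that inflected forms such as "binds" and
#' "binding" collapse onto a common stem ("bind"). The implementation is a
#' pinned, self-contained port of the published algorithm: analysis results
#' are bit-stable across machines and R versions, which matters because both
#' the search index and the text fingerprints are defined relative to this
#' exact stemmer.
#'
#' Only tokens consisting entirely of ASCII letters a-z are stemmed; tokens
#' carrying digits or non-Latin letters (Greek symbols such as "α",
#' gene identifiers like "p53") pass through unchanged, since the algorithm
#' is defined for English words only.
#'
#' @param words character vector of lower-cased tokens.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("binding", "proteins", "relational"))
#' @export
porter_stem <- function(words) {
  if (length(words) == 0L) return(character(0))
  u <- unique(words)
  stems <- vapply(u, function(w) {
    hit <- .stem_cache[[w]]
    if (is.null(hit)) {
      hit <- porter_stem1(w)
      assign(w, hit, envir = .stem_cache)
    }
    hit
  }, character(1), USE.NAMES = FALSE)
  stems[match(words, u)]
}

# stems are pure functions of the word: memoized for the session
.stem_cache <- new.env(parent = emptyenv())

porter_stem1 <- function(w) {
  if (!grepl("^[a-z]+$", w) || nchar(w) < 3L) return(w)
  w <- pt_step1a(w)
  w <- pt_step1b(w)
  w <- pt_step1c(w)
  w <- pt_step2(w)
  w <- pt_step3(w)
  w <- pt_step4(w)
  w <- pt_step5(w)
  w
}

# consonant test at position i (1-based); 'y' is a consonant unless preceded
# by a consonant
pt_cons <- function(ch, i) {
  c <- ch[i]
  if (c %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (c == "y") {
    if (i == 1L) return(TRUE)
    return(!pt_cons(ch, i - 1L))
  }
  TRUE
}

# the measure m: number of VC sequences in [C](VC){m}[V]
pt_measure <- function(stem) {
  ch <- strsplit(stem, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n == 0L) return(0L)
  flags <- vapply(seq_len(n), function(i) pt_cons(ch, i), logical(1))
  m <- 0L
  prev_vowel <- FALSE
  for (i in seq_len(n)) {
    if (flags[i]) {
      if (prev_vowel) m <- m + 1L
      prev_vowel <- FALSE
    } else {
      prev_vowel <- TRUE
    }
  }
  m
}

pt_has_vowel <- function(stem) {
  ch <- strsplit(stem, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n == 0L) return(FALSE)
  any(!vapply(seq_len(n), function(i) pt_cons(ch, i), logical(1)))
}

# *d: ends with a double consonant
pt_double_cons <- function(stem) {
  n <- nchar(stem)
  if (n < 2L) return(FALSE)
  ch <- strsplit(stem, "", fixed = TRUE)[[1]]
  ch[n] == ch[n - 1L] && pt_cons(ch, n)
}

# *o: ends cvc where the final consonant is not w, x or y
pt_cvc <- function(stem) {
  n <- nchar(stem)
  if (n < 3L) return(FALSE)
  ch <- strsplit(stem, "", fixed = TRUE)[[1]]
  pt_cons(ch, n - 2L) && !pt_cons(ch, n - 1L) && pt_cons(ch, n) &&
    !(ch[n] %in% c("w", "x", "y"))
}

pt_ends <- function(w, suf) {
  ns <- nchar(suf)
  nchar(w) >= ns && substring(w, nchar(w) - ns + 1L) == suf
}

pt_chop <- function(w, suf) substring(w, 1L, nchar(w) - nchar(suf))

pt_step1a <- function(w) {
  if (pt_ends(w, "sses")) return(pt_chop(w, "es"))
  if (pt_ends(w, "ies")) return(pt_chop(w, "es"))
  if (pt_ends(w, "ss")) return(w)
  if (pt_ends(w, "s")) return(pt_chop(w, "s"))
  w
}

pt_step1b <- function(w) {
  if (pt_ends(w, "eed")) {
    stem <- pt_chop(w, "eed")
    if (pt_measure(stem) > 0L) return(pt_chop(w, "d"))
    return(w)
  }
  removed <- FALSE
  if (pt_ends(w, "ed") && pt_has_vowel(pt_chop(w, "ed"))) {
    w <- pt_chop(w, "ed"); removed <- TRUE
  } else if (pt_ends(w, "ing") && pt_has_vowel(pt_chop(w, "ing"))) {
    w <- pt_chop(w, "ing"); removed <- TRUE
  }
  if (removed) {
    if (pt_ends(w, "at") || pt_ends(w, "bl") || pt_ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (pt_double_cons(w) &&
               !substring(w, nchar(w)) %in% c("l", "s", "z")) {
      w <- substring(w, 1L, nchar(w) - 1L)
    } else if (pt_measure(w) == 1L && pt_cvc(w)) {
      w <- paste0(w, "e")
    }
  }
  w
}

pt_step1c <- function(w) {
  if (pt_ends(w, "y") && pt_has_vowel(pt_chop(w, "y"))) {
    return(paste0(pt_chop(w, "y"), "i"))
  }
  w
}

# rule tables: longest matching suffix is taken, then its condition tested
pt_step2_rules <- list(
  c("ational", "ate"), c("ization", "ize"), c("iveness", "ive"),
  c("fulness", "ful"), c("ousness", "ous"), c("biliti", "ble"),
  c("tional", "tion"), c("ation", "ate"), c("alism", "al"),
  c("aliti", "al"), c("iviti", "ive"), c("entli", "ent"),
  c("ousli", "ous"), c("enci", "ence"), c("anci", "ance"),
  c("izer", "ize"), c("abli", "able"), c("alli", "al"),
  c("ator", "ate"), c("eli", "e")
)

pt_step3_rules <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"),
  c("iciti", "ic"), c("ical", "ic"), c("ness", ""), c("ful", "")
)

pt_apply_rules <- function(w, rules, min_m) {
  sufs <- vapply(rules, `[`, character(1), 1L)
  ord <- order(nchar(sufs), decreasing = TRUE)
  for (k in ord) {
    suf <- rules[[k]][1L]
    if (pt_ends(w, suf)) {
      stem <- pt_chop(w, suf)
      if (pt_measure(stem) > min_m - 1L) {
        return(paste0(stem, rules[[k]][2L]))
      }
      return(w)
    }
  }
  w
}

pt_step2 <- function(w) pt_apply_rules(w, pt_step2_rules, 1L)
pt_step3 <- function(w) pt_apply_rules(w, pt_step3_rules, 1L)

pt_step4_sufs <- c("ement", "ance", "ence", "able", "ible", "ment", "ant",
                   "ent", "ion", "ism", "ate", "iti", "ous", "ive", "ize",
                   "ou", "al", "er", "ic")

pt_step4 <- function(w) {
  for (suf in pt_step4_sufs[order(nchar(pt_step4_sufs), decreasing = TRUE)]) {
    if (pt_ends(w, suf)) {
      stem <- pt_chop(w, suf)
      if (pt_measure(stem) > 1L) {
        if (suf == "ion" &&
            !substring(stem, nchar(stem)) %in% c("s", "t")) {
          return(w)
        }
        return(stem)
      }
      return(w)
    }
  }
  w
}

pt_step5 <- function(w) {
  # 5a
  if (pt_ends(w, "e")) {
    stem <- pt_chop(w, "e")
    m <- pt_measure(stem)
    if (m > 1L || (m == 1L && !pt_cvc(stem))) w <- stem
  }
  # 5b
  if (pt_measure(w) > 1L && pt_double_cons(w) &&
      substring(w, nchar(w)) == "l") {
    w <- substring(w, 1L, nchar(w) - 1L)
  }
  w
}
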