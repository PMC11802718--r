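# Rule-based extraction baseline. Patterns are assembled from the lexicon:
# substance names, use-disorder phrases and severity specifiers, combined in
# the orderings seen in practice — optional leading severity and/or
# parenthetical, the substance, a bounded filler gap (parentheticals such as
# "(kratom)" or "(nitrous oxide)"), a use-disorder phrase, and an optional
# trailing severity/remission tail. Unlike the generative route, every match
# is by construction a verbatim substring of the note; the trade-off is that
# rules cannot use context, e.g. they cannot exclude "rule out" (r/o)
# diagnoses.

regex_escape <- function(x) {
  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
}

# Longest-first alternation so that e.g. "severe" wins over "sever" and
# "use disorder" over "disorder".
term_alternation <- function(terms) {
  terms <- terms[order(-nchar(terms))]
  paste0("(?:", paste(regex_escape(terms), collapse = "|"), ")")
}

#' Build regex rule patterns for one category
#'
#' @param lex A `sud_lexicon`.
#' @param max_filler Maximum character gap allowed between the substance name
#'   and the use-disorder phrase (default 40, enough for parentheticals like
#'   "(heroin/ vicodin)" without producing runaway spans).
#' @return A tibble of `RulePattern`s: `category`, `pattern` (PCRE, matched
#'   case-insensitively), `description`. All patterns are compiled once
#'   against a probe string; a failure to compile raises an error naming the
#'   pattern.
#' @export
#' @examples
#' pats <- build_patterns(load_lexicons()$alcohol)
#' extract_regex("hx: alcohol use disorder mod/severe", pats)$text
build_patterns <- function(lex, max_filler = 40L) {
  stopifnot(inherits(lex, "sud_lexicon"))
  sev <- term_alternation(lex$severity_terms)
  sub_ <- term_alternation(lex$substance_terms)
  dis <- term_alternation(lex$disorder_terms)
  paren <- "\\([^)\\n]{0,35}\\)"
  filler <- sprintf("[^\\n]{0,%d}?", max_filler)
  # trailing specifier tail: ", severe", ": mild", " mod/severe",
  # " - severe (on agonist therapy)", ", moderate, in remission", ...
  tail <- sprintf("(?:[ ,;:/-]{1,3}(?:%s|%s))*", sev, paren)
  lead_paren <- sprintf("(?:%s )?", paren)

  pats <- tibble::tibble(
    category = lex$category,
    pattern = c(
      sprintf("%s%s%s%s%s", sev, "[ ]{1,3}", lead_paren,
              sprintf("%s%s%s", sub_, filler, dis), tail),
      sprintf("%s%s%s", lead_paren, sprintf("%s%s%s", sub_, filler, dis),
              tail),
      sprintf("(?:meets criteria for )?%s[: ]{1,3}%s%s", dis, sub_,
              "(?:;? ?\\[[x ]?\\] ?[^\\[\\n]{0,30})*")
    ),
    description = c(
      "severity-first: (severity) (parenthetical)? substance .. disorder ..",
      "substance-first: (parenthetical)? substance .. disorder (tail)?",
      "checkbox/generic-first: disorder: substance [] mild ... [x] severe"
    )
  )
  for (i in seq_len(nrow(pats))) {
    ok <- tryCatch({
      regexpr(pats$pattern[i], "probe", perl = TRUE, ignore.case = TRUE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      stop("rule pattern failed to compile for category '", lex$category,
           "': ", pats$description[i], call. = FALSE)
    }
  }
  pats
}

#' Extract a span from a note with the regex baseline
#'
#' Runs every rule pattern over the note (case-insensitive) and returns the
#' leftmost match, ties broken by the longest match — or the unanswerable
#' sentinel when nothing matches. The matched text is verbatim from the note.
#'
#' @param note_text Full note text.
#' @param patterns Tibble from [build_patterns()].
#' @param note_id Optional note identifier carried into the result.
#' @return A one-row tibble: `note_id`, `category`, `text`,
#'   `selection_method = "regex"`.
#' @export
extract_regex <- function(note_text, patterns, note_id = NA_character_) {
  best_start <- Inf
  best_len <- -1L
  best_text <- SENTINEL
  for (pat in patterns$pattern) {
    m <- gregexpr(pat, note_text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] < 0L) next
    lens <- attr(m, "match.length")
    for (k in seq_along(m)) {
      if (m[k] < best_start ||
          (m[k] == best_start && lens[k] > best_len)) {
        best_start <- m[k]
        best_len <- lens[k]
        best_text <- substr(note_text, m[k], m[k] + lens[k] - 1L)
      }
    }
  }
  tibble::tibble(note_id = note_id, category = patterns$category[1],
                 text = best_text, selection_method = "regex")
}
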