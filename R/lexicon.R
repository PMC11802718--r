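# Category lexicons: the 11 DSM-5 SUD categories with their substance names,
# use-disorder phrases, severity specifiers, and proxy ground truth. These term
# sets drive the post-processing filters, the regex baseline, and proxy-answer
# selection.

#' Names of the 11 SUD categories
#'
#' @return Character vector of the 11 category identifiers, in the
#'   conventional reporting order (alcohol first, other psychoactive last).
#' @export
#' @examples
#' sud_categories()
sud_categories <- function() {
  c("alcohol", "opioid", "cannabis", "sedative_hypnotic_anxiolytic",
    "cocaine", "amphetamine", "caffeine", "hallucinogen", "nicotine",
    "inhalant", "other_psychoactive")
}

#' Path to the default lexicon configuration
#'
#' @return Path to the YAML lexicon file shipped with the package.
#' @export
default_lexicon_path <- function() {
  system.file("extdata", "lexicon_default.yaml", package = "sudspanr",
              mustWork = TRUE)
}

#' Load category lexicons from a configuration file
#'
#' Reads a YAML file with one block per SUD category (keys `substance_terms`,
#' `disorder_terms`, `severity_terms`, `proxy_ground_truth`; a `defaults`
#' block supplies disorder/severity terms shared by all categories) and
#' validates it: all 11 categories must be present, all term lists non-empty
#' and lowercase, and each proxy ground truth must contain at least one
#' substance term and one disorder term.
#'
#' @param path Path to the lexicon YAML; defaults to the shipped config.
#' @return A named list of `sud_lexicon` objects, one per category, in
#'   [sud_categories()] order.
#' @export
#' @examples
#' lex <- load_lexicons()
#' lex$alcohol$substance_terms
load_lexicons <- function(path = default_lexicon_path()) {
  if (!file.exists(path)) {
    stop("lexicon config file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$categories)) {
    stop("lexicon config has no 'categories' block", call. = FALSE)
  }
  defaults <- raw$defaults %||% list()
  wanted <- sud_categories()
  missing <- setdiff(wanted, names(raw$categories))
  if (length(missing) > 0L) {
    stop("lexicon config is missing categories: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lex <- lapply(wanted, function(cat) {
    block <- raw$categories[[cat]]
    new_lexicon(
      category = cat,
      display_name = block$display_name %||% gsub("_", " ", cat),
      substance_terms = as.character(block$substance_terms),
      disorder_terms = as.character(block$disorder_terms %||%
                                      defaults$disorder_terms),
      severity_terms = as.character(block$severity_terms %||%
                                      defaults$severity_terms),
      proxy_ground_truth = as.character(block$proxy_ground_truth)
    )
  })
  names(lex) <- wanted
  lex
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_lexicon <- function(category, display_name, substance_terms,
                        disorder_terms, severity_terms, proxy_ground_truth) {
  check_terms <- function(terms, what) {
    if (length(terms) == 0L) {
      stop("category '", category, "': empty ", what, call. = FALSE)
    }
    if (any(!nzchar(terms)) || anyNA(terms)) {
      stop("category '", category, "': ", what,
           " contains an empty entry", call. = FALSE)
    }
    if (any(terms != tolower(terms))) {
      stop("category '", category, "': ", what,
           " entries must be lowercase", call. = FALSE)
    }
    terms
  }
  check_terms(substance_terms, "substance_terms")
  check_terms(disorder_terms, "disorder_terms")
  check_terms(severity_terms, "severity_terms")
  if (length(proxy_ground_truth) != 1L || !nzchar(proxy_ground_truth)) {
    stop("category '", category, "': proxy_ground_truth must be a single ",
         "non-empty string", call. = FALSE)
  }
  lex <- structure(
    list(category = category,
         display_name = display_name,
         substance_terms = substance_terms,
         disorder_terms = disorder_terms,
         severity_terms = severity_terms,
         proxy_ground_truth = proxy_ground_truth),
    class = "sud_lexicon"
  )
  if (!contains_substance(proxy_ground_truth, lex)) {
    stop("category '", category, "': proxy_ground_truth contains no ",
         "substance term", call. = FALSE)
  }
  if (!any(vapply(lex$disorder_terms, grepl, logical(1),
                  x = normalize_text(proxy_ground_truth), fixed = TRUE))) {
    stop("category '", category, "': proxy_ground_truth contains no ",
         "disorder term", call. = FALSE)
  }
  lex
}

#' @export
print.sud_lexicon <- function(x, ...) {
  cat("<sud_lexicon>", x$category, "(", x$display_name, ")\n")
  cat("  substance_terms:", paste(x$substance_terms, collapse = ", "), "\n")
  cat("  disorder_terms: ", paste(x$disorder_terms, collapse = ", "), "\n")
  cat("  severity_terms: ", paste(x$severity_terms, collapse = ", "), "\n")
  cat("  proxy:          ", x$proxy_ground_truth, "\n")
  invisible(x)
}

# First character position (1-based) at which any of `terms` occurs as a plain
# substring of normalized `text`; NA if none occurs.
first_term_pos <- function(text, terms) {
  pos <- vapply(terms, function(tm) {
    p <- regexpr(tm, text, fixed = TRUE)
    if (p < 0L) NA_integer_ else as.integer(p)
  }, integer(1))
  if (all(is.na(pos))) NA_integer_ else min(pos, na.rm = TRUE)
}

#' Does a text mention the category's substance?
#'
#' Plain substring test on lowercased, whitespace-collapsed text: true iff at
#' least one of the lexicon's substance terms occurs anywhere in the text.
#' This is post-processing filter (i).
#'
#' @param text Character string (any casing).
#' @param lex A `sud_lexicon`.
#' @return Logical scalar.
#' @export
#' @examples
#' lex <- load_lexicons()
#' contains_substance("severe etoh use d/o", lex$alcohol)
contains_substance <- function(text, lex) {
  stopifnot(inherits(lex, "sud_lexicon"))
  if (length(text) != 1L || is.na(text) || !nzchar(text)) return(FALSE)
  txt <- normalize_text(text)
  !is.na(first_term_pos(txt, lex$substance_terms))
}

#' Does a use-disorder phrase follow the substance mention?
#'
#' True iff a disorder term occurs at or after the character position of the
#' first substance-term occurrence in the lowercased, whitespace-collapsed
#' text. This is post-processing filter (ii): a phrase such as "dependence" or
#' "use d/o" must follow the substance name for the mention to count as a
#' use-disorder diagnosis.
#'
#' @inheritParams contains_substance
#' @return Logical scalar; always `FALSE` when no substance term is present,
#'   so `contains_disorder()` implies [contains_substance()].
#' @export
#' @examples
#' lex <- load_lexicons()
#' contains_disorder("severe etoh use d/o", lex$alcohol)   # TRUE
#' contains_disorder("patient drinks etoh daily", lex$alcohol) # FALSE
contains_disorder <- function(text, lex) {
  stopifnot(inherits(lex, "sud_lexicon"))
  if (length(text) != 1L || is.na(text) || !nzchar(text)) return(FALSE)
  txt <- normalize_text(text)
  sub_pos <- first_term_pos(txt, lex$substance_terms)
  if (is.na(sub_pos)) return(FALSE)
  for (tm in lex$disorder_terms) {
    hits <- gregexpr(tm, txt, fixed = TRUE)[[1]]
    if (hits[1] > 0L && any(hits >= sub_pos)) return(TRUE)
  }
  FALSE
}
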