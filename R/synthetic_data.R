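# Seeded synthetic clinical-note corpus. The real study corpus (VA TIU notes)
# is not publicly available, so the generator emulates its documented
# statistical structure: 11 SUD categories with per-category positive-note
# prevalence between 3% and 33% (mean 10%), note lengths log-normally
# distributed around a median of 423 tokens (mean 1043, clamped to 11-10719),
# free-text scaffolding with no fixed section order, severity phrasings
# spanning plain, abbreviated, checkbox, remission, parenthetical,
# slash-combined and unspecified styles, comorbid multi-SUD statements, and
# distractor mentions (past problem lists, rule-out diagnoses, negated use).
# Gold annotations are verbatim single continuous spans containing the
# substance and a use-disorder phrase, with the severity specifier present or
# absent (absent means unspecified severity).

#' Synthetic corpus specification
#'
#' @param n_notes Number of notes to generate.
#' @param prevalence Named numeric vector of per-category positive-note
#'   prevalences in (0, 1]; the default spans 0.03-0.33 with mean 0.10
#'   across the 11 categories.
#' @param median_tokens,mean_tokens Median and mean of the log-normal note
#'   length model (in whitespace tokens); the default 423 / 1043 fixes
#'   `meanlog = log(median)` and `sdlog = sqrt(2 log(mean/median))`.
#' @param min_tokens,max_tokens Length clamp (11-10719 by default).
#' @param comorbidity_rate Probability that a note positive for two or more
#'   categories writes its diagnosis spans adjacent in a single
#'   semicolon-joined statement rather than on separate lines (default
#'   0.244, the documented multi-SUD comorbidity rate).
#' @param p_past_problem,p_rule_out,p_negated Per-note probabilities of the
#'   three distractor blocks (historical problem list, "r/o" rule-out
#'   diagnosis, negated use), each mentioning a category that is *not*
#'   positive for the note and therefore absent from gold.
#' @param seed Integer seed fixing the corpus byte-for-byte.
#' @return An object of class `sud_corpus_spec`.
#' @export
corpus_spec <- function(n_notes = 577L,
                        prevalence = default_prevalence(),
                        median_tokens = 423, mean_tokens = 1043,
                        min_tokens = 11L, max_tokens = 10719L,
                        comorbidity_rate = 0.244,
                        p_past_problem = 0.15, p_rule_out = 0.10,
                        p_negated = 0.15,
                        seed = 42L) {
  stopifnot(n_notes >= 0L,
            all(prevalence > 0), all(prevalence <= 1),
            setequal(names(prevalence), sud_categories()),
            median_tokens > 0, mean_tokens >= median_tokens,
            min_tokens >= 1L, max_tokens >= min_tokens,
            comorbidity_rate >= 0, comorbidity_rate <= 1)
  structure(
    list(n_notes = as.integer(n_notes),
         prevalence = prevalence[sud_categories()],
         median_tokens = median_tokens,
         mean_tokens = mean_tokens,
         meanlog = log(median_tokens),
         sdlog = sqrt(2 * log(mean_tokens / median_tokens)),
         min_tokens = as.integer(min_tokens),
         max_tokens = as.integer(max_tokens),
         comorbidity_rate = comorbidity_rate,
         p_past_problem = p_past_problem,
         p_rule_out = p_rule_out,
         p_negated = p_negated,
         seed = as.integer(seed)),
    class = "sud_corpus_spec"
  )
}

#' Default per-category prevalences
#'
#' Spans 0.03 (caffeine, hallucinogen, inhalant) to 0.33 (alcohol) with mean
#' 0.10, matching the documented range and ordered to reflect relative SUD
#' frequency in a veteran clinical population (alcohol and nicotine most
#' common).
#'
#' @return Named numeric vector over [sud_categories()].
#' @export
default_prevalence <- function() {
  c(alcohol = 0.33, opioid = 0.12, cannabis = 0.15,
    sedative_hypnotic_anxiolytic = 0.05, cocaine = 0.09,
    amphetamine = 0.08, caffeine = 0.03, hallucinogen = 0.03,
    nicotine = 0.14, inhalant = 0.03, other_psychoactive = 0.05)
}

DIAGNOSIS_STYLES <- c("plain", "abbreviated", "checkbox", "remission",
                      "parenthetical", "slash_combined", "unspecified")

# Category-specific abbreviation used by the "abbreviated" style; must itself
# contain a lexicon substance term.
CATEGORY_ABBREV <- c(
  alcohol = "etoh", opioid = "opioid", cannabis = "mj",
  sedative_hypnotic_anxiolytic = "sedative", cocaine = "cocaine",
  amphetamine = "amphetamine", caffeine = "caffeine",
  hallucinogen = "hallucinogen", nicotine = "tobacco", inhalant = "inhalant",
  other_psychoactive = "kava"
)

CATEGORY_DETAIL <- list(
  alcohol = c("beer", "liquor"),
  opioid = c("kratom", "heroin/ vicodin", "oxycodone"),
  cannabis = c("thc vape", "edibles"),
  sedative_hypnotic_anxiolytic = c("xanax", "valium"),
  cocaine = c("crack"),
  amphetamine = c("methamphetamine"),
  caffeine = c("energy drinks"),
  hallucinogen = c("mdma/ecstasy", "lsd"),
  nicotine = c("cigarette"),
  inhalant = c("nitrous oxide"),
  other_psychoactive = c("coricidin", "kava")
)

#' Diagnosis surface-form grammar
#'
#' The template table behind [render_diagnosis()]: generic templates
#' (category `"*"`) with `{subst}`, `{abbr}`, `{sev}`, `{detail}`, `{osub}`
#' placeholders, plus the verbatim real-world variant strings attached to
#' their categories. `gold_ok` marks templates whose rendered spans satisfy
#' post-processing filters (i)-(ii) and may therefore serve as gold
#' annotations; the remaining forms (e.g. "marijuana user (in remission)",
#' the generic-first checkbox) are renderable but excluded from gold.
#'
#' @return Tibble with columns `category`, `style`, `template`, `gold_ok`.
#' @export
diagnosis_templates <- function() {
  g <- function(style, template, gold_ok = TRUE, category = "*") {
    tibble::tibble(category = category, style = style, template = template,
                   gold_ok = gold_ok)
  }
  dplyr::bind_rows(
    # generic forms
    g("plain", "{subst} use disorder, {sev}"),
    g("plain", "{sev} {subst} use disorder"),
    g("plain", "{subst} use disorder: {sev}"),
    g("plain", "{subst} dependence, {sev}"),
    g("abbreviated", "{sev} {abbr} use d/o"),
    g("abbreviated", "{sev} {abbr} use do"),
    g("abbreviated", "{abbr} ud"),
    g("checkbox", paste0("{subst} use disorder: [] mild (2-3); ",
                         "[] moderate (4-5); [x] severe (6 or more)")),
    g("checkbox", paste0("meets criteria for substance use disorder: ",
                         "{subst} [] mild (2-3); [] moderate (4-5); ",
                         "[x] severe (6 or more)"), gold_ok = FALSE),
    g("remission", "{subst} use disorder, in sustained remission"),
    g("remission", "{subst} use disorder, {sev}, in remission"),
    g("remission", "{subst} dependence, in early remission"),
    g("parenthetical", "{subst} ({detail}) use disorder, {sev}"),
    g("parenthetical", "{sev} {subst} ({detail}) use d/o"),
    g("parenthetical", "{subst} ({detail}) use disorder, severity unspecified"),
    g("slash_combined", "{subst}/{osub} use disorder: {sev}"),
    g("unspecified", "{subst} use disorder"),
    g("unspecified", "{subst} use disorder, severity unspecified"),
    # verbatim real-world variants
    g("slash_combined", "cannabis/alcohol/opioid use disorder: mild",
      category = "cannabis"),
    g("plain", "alcohol use disorder mod/severe", category = "alcohol"),
    g("abbreviated", "moderate caffeine use do", category = "caffeine"),
    g("parenthetical",
      "opioid (heroin/ vicodin) use disorder - severe (on agonist therapy)",
      category = "opioid"),
    g("remission", "marijuana user (in remission)", gold_ok = FALSE,
      category = "cannabis"),
    g("parenthetical", "cannabis (thc vape) use disorder, mild",
      category = "cannabis"),
    g("remission", "(ephedrine) sedative use disorder, in sustained remission",
      category = "sedative_hypnotic_anxiolytic"),
    g("parenthetical", "sedative hypnotic use disorder, severe (xanax)",
      category = "sedative_hypnotic_anxiolytic"),
    g("checkbox", paste0("meets criteria for substance use disorder: cocaine ",
                         "[] mild (2-3); [] moderate (4-5); ",
                         "[x] severe (6 or more)"), gold_ok = FALSE,
      category = "cocaine"),
    g("remission", paste0("amphetamine (methamphetamine) or other stimulant, ",
                          "without perceptual disturbances disorder, sever, ",
                          "in remission"), category = "amphetamine"),
    g("remission", paste0("other hallucinogen use disorder (mdma/ecstasy), ",
                          "moderate, in remission"), category = "hallucinogen"),
    g("parenthetical", "other/unknown substance disorder: severe (coricidin)",
      category = "other_psychoactive"),
    g("parenthetical", "moderate inhalant (nitrous oxide) use d/o",
      category = "inhalant")
  )
}

fill_template <- function(template, category, lex) {
  out <- template
  fill <- function(out, ph, choices) {
    while (grepl(ph, out, fixed = TRUE)) {
      out <- sub(ph, sample(choices, 1L), out, fixed = TRUE)
    }
    out
  }
  out <- fill(out, "{subst}", lex$substance_terms)
  out <- fill(out, "{abbr}", CATEGORY_ABBREV[[category]])
  out <- fill(out, "{sev}", c("mild", "moderate", "severe"))
  out <- fill(out, "{detail}", CATEGORY_DETAIL[[category]])
  if (grepl("{osub}", out, fixed = TRUE)) {
    other <- setdiff(sud_categories(), category)
    out <- fill(out, "{osub}",
                unname(CATEGORY_FIRST_SUBSTANCE[sample(other, 1L)]))
  }
  out
}

#' Render one diagnosis span from the grammar
#'
#' Draws a template for the category and style (generic and category-specific
#' templates pooled) and fills its placeholders using the current RNG state;
#' call inside `set.seed()` for reproducibility. Every documented real-world
#' variant string is producible by some (style, draw) pair.
#'
#' @param category One of [sud_categories()].
#' @param style One of `r paste(DIAGNOSIS_STYLES, collapse = ", ")`.
#' @param lexicons Lexicon list from [load_lexicons()].
#' @param gold_only Restrict to templates whose spans pass filters (i)-(ii)
#'   and can serve as gold annotations.
#' @return A single diagnosis span string.
#' @export
#' @examples
#' set.seed(1)
#' render_diagnosis("inhalant", "parenthetical")
.template_cache <- new.env(parent = emptyenv())

cached_templates <- function() {
  if (is.null(.template_cache$tpl)) .template_cache$tpl <- diagnosis_templates()
  .template_cache$tpl
}

render_diagnosis <- function(category, style, lexicons = load_lexicons(),
                             gold_only = FALSE) {
  if (!style %in% DIAGNOSIS_STYLES) {
    stop("unknown diagnosis style: ", style, call. = FALSE)
  }
  stopifnot(category %in% sud_categories())
  tpl <- cached_templates()
  tpl <- tpl[tpl$style == style & tpl$category %in% c("*", category), ,
             drop = FALSE]
  if (gold_only) tpl <- tpl[tpl$gold_ok, , drop = FALSE]
  row <- tpl[sample(nrow(tpl), 1L), , drop = FALSE]
  fill_template(row$template, category, lexicons[[category]])
}

# Neutral clinical filler; kept free of every substance term so filler can
# never satisfy post-processing filter (i) for any category.
FILLER_SENTENCES <- c(
  "patient seen today for scheduled follow up visit.",
  "vital signs reviewed and within normal limits.",
  "patient arrived on time and was cooperative throughout the interview.",
  "sleep has been fair with occasional early waking.",
  "appetite is stable and weight is unchanged since last visit.",
  "mood reported as even with no acute distress observed.",
  "patient continues to attend weekly group sessions.",
  "housing situation remains stable at this time.",
  "patient is employed part time and reports adequate finances.",
  "no acute safety concerns were identified during this encounter.",
  "thought process linear and goal directed.",
  "speech normal in rate and volume.",
  "denies current suicidal or homicidal ideation.",
  "patient was oriented to person place and time.",
  "coping skills were reviewed and practiced in session.",
  "medication adherence was discussed and encouraged.",
  "patient reports attending community support meetings regularly.",
  "laboratory results were reviewed with the patient.",
  "plan reviewed and patient agrees with next steps.",
  "return to clinic in four weeks or sooner as needed.",
  "care coordination with primary provider will continue.",
  "patient verbalized understanding of the treatment plan.",
  "family remains supportive and involved in care.",
  "transportation barriers were discussed with social work.",
  "patient completed screening questionnaires at intake.",
  "relapse prevention strategies were reviewed in detail.",
  "progress toward treatment goals is steady.",
  "patient reports improved energy over the past month.",
  "grooming and hygiene appropriate to setting.",
  "no adverse medication effects were reported today."
)

SECTION_HEADERS <- c("subjective:", "history of present illness:",
                     "interval history:", "mental status exam:",
                     "medications:", "plan:", "social history:")

NOTE_TYPES <- c("mental health", "suicide prevention",
                "sud treatment program", "education", "psychiatry",
                "administrative", "psychology", "nursing",
                "primary care", "social work", "pharmacy", "telehealth")

DIAGNOSIS_HEADERS <- c("diagnosis:", "diagnoses:", "assessment:",
                       "dsm-5 diagnoses:")

render_gold_span <- function(category, lexicons, max_tries = 25L) {
  lex <- lexicons[[category]]
  styles <- DIAGNOSIS_STYLES
  for (i in seq_len(max_tries)) {
    span <- render_diagnosis(category, sample(styles, 1L), lexicons,
                            gold_only = TRUE)
    if (contains_substance(span, lex) && contains_disorder(span, lex)) {
      return(span)
    }
  }
  # canonical fallback, always filter-safe
  paste0(lex$substance_terms[1], " use disorder, moderate")
}

distractor_block <- function(kind, category) {
  term <- unname(CATEGORY_FIRST_SUBSTANCE[category])
  switch(kind,
    past_problem = paste0("previous encounters problem list includes:\n{x} ",
                          term, " abuse\n{x} adjustment difficulties"),
    rule_out = paste0("r/o ", term, " use disorder"),
    negated = paste0("patient denies any current ", term, " use.")
  )
}

#' Generate one synthetic note with gold annotations
#'
#' Assembles header, filler sections, optional distractor blocks and a
#' diagnoses block containing the gold spans verbatim. Positive categories
#' are drawn independently at the spec prevalences; gold spans are drawn from
#' the grammar and rejection-sampled until they satisfy filters (i)-(ii)
#' (which, with verbatim embedding, guarantees they also pass the grounding
#' filter against their own note). Uses the current RNG state; call inside
#' `set.seed()` or via [generate_corpus()].
#'
#' @param spec A [corpus_spec()].
#' @param lexicons Lexicon list from [load_lexicons()].
#' @param note_id,patient_id Identifiers for the generated note.
#' @return List with `note` (one-row tibble: `note_id`, `patient_id`,
#'   `note_type`, `text`) and `gold` (tibble: `note_id`, `category`,
#'   `span_text`, one row per positive category).
#' @export
generate_note <- function(spec, lexicons = load_lexicons(),
                          note_id = "N00001", patient_id = "P00001") {
  stopifnot(inherits(spec, "sud_corpus_spec"))
  target_len <- round(min(max(rlnorm(1, spec$meanlog, spec$sdlog),
                              spec$min_tokens), spec$max_tokens))
  prev <- spec$prevalence
  positive <- names(prev)[runif(length(prev)) < prev]
  gold_spans <- vapply(positive, render_gold_span, character(1),
                       lexicons = lexicons)

  note_type <- sample(NOTE_TYPES, 1L)
  header <- c(paste0("note type: ", note_type),
              paste0("patient: ", patient_id),
              paste0("visit id: ", note_id))

  # diagnoses block: comorbid notes may join their spans into one statement
  diag_block <- character(0)
  if (length(positive) > 0L) {
    diag_block <- sample(DIAGNOSIS_HEADERS, 1L)
    if (length(positive) >= 2L && runif(1) < spec$comorbidity_rate) {
      diag_block <- c(diag_block, paste(gold_spans, collapse = "; "))
    } else {
      diag_block <- c(diag_block,
                      paste0(seq_along(gold_spans), ". ", gold_spans))
    }
  }

  distractors <- character(0)
  negatives <- setdiff(names(prev), positive)
  if (length(negatives) > 0L) {
    for (kind in c("past_problem", "rule_out", "negated")) {
      p <- switch(kind, past_problem = spec$p_past_problem,
                  rule_out = spec$p_rule_out, negated = spec$p_negated)
      if (runif(1) < p) {
        distractors <- c(distractors,
                         distractor_block(kind, sample(negatives, 1L)))
      }
    }
  }

  skeleton <- c(header,
                sample(SECTION_HEADERS, 2L),
                distractors,
                diag_block,
                sample(SECTION_HEADERS, 1L))
  n_have <- length(unlist(strsplit(skeleton, "\\s+")))
  sent_tokens <- lengths(strsplit(FILLER_SENTENCES, " ", fixed = TRUE))
  filler <- character(0)
  while (n_have < target_len) {
    k <- max(1L, ceiling((target_len - n_have) / mean(sent_tokens)))
    idx <- sample(length(FILLER_SENTENCES), k, replace = TRUE)
    cum <- n_have + cumsum(sent_tokens[idx])
    take <- which(cum >= target_len)
    keep <- if (length(take) == 0L) k else take[1]
    filler <- c(filler, FILLER_SENTENCES[idx[seq_len(keep)]])
    n_have <- cum[keep]
  }
  # free-text structure: no fixed section order; diagnoses land somewhere
  # inside the note, filler around them
  n_f <- length(filler)
  cut1 <- if (n_f > 0L) sample(0:n_f, 1L) else 0L
  body <- c(header,
            sample(SECTION_HEADERS, 1L),
            head(filler, cut1),
            distractors,
            diag_block,
            sample(SECTION_HEADERS, 1L),
            if (n_f > cut1) filler[(cut1 + 1L):n_f])
  text <- paste(body, collapse = "\n")

  for (sp in gold_spans) {
    if (!grepl(sp, text, fixed = TRUE)) {
      stop("internal error: gold span not embedded verbatim: ", sp)
    }
  }
  list(
    note = tibble::tibble(note_id = note_id, patient_id = patient_id,
                          note_type = note_type, text = text),
    gold = tibble::tibble(note_id = rep(note_id, length(positive)),
                          category = positive, span_text = unname(gold_spans))
  )
}

#' Generate a full synthetic corpus
#'
#' Seeds the RNG from the spec and generates `n_notes` notes with gold
#' annotations. Patient identifiers are assigned so that a small fraction of
#' patients contribute two notes (577 notes over 574 patients at the default
#' size). The result is byte-reproducible for a given spec.
#'
#' @param spec A [corpus_spec()].
#' @param lexicons Lexicon list from [load_lexicons()].
#' @return An object of class `sud_corpus`: list with `notes` (tibble
#'   `note_id`, `patient_id`, `note_type`, `text`), `gold` (tibble `note_id`,
#'   `category`, `span_text`) and `spec`.
#' @export
#' @examples
#' corp <- generate_corpus(corpus_spec(n_notes = 5, seed = 7))
#' corp$gold
generate_corpus <- function(spec, lexicons = load_lexicons()) {
  stopifnot(inherits(spec, "sud_corpus_spec"))
  n <- spec$n_notes
  if (n == 0L) {
    return(structure(list(
      notes = tibble::tibble(note_id = character(0), patient_id = character(0),
                             note_type = character(0), text = character(0)),
      gold = tibble::tibble(note_id = character(0), category = character(0),
                            span_text = character(0)),
      spec = spec), class = "sud_corpus"))
  }
  set.seed(spec$seed)
  n_patients <- max(1L, round(n * 574 / 577))
  pool <- c(seq_len(n_patients),
            if (n > n_patients) sample(n_patients, n - n_patients,
                                       replace = TRUE))
  patient_ids <- sprintf("P%05d", sample(pool))
  out <- lapply(seq_len(n), function(i) {
    generate_note(spec, lexicons, note_id = sprintf("N%05d", i),
                  patient_id = patient_ids[i])
  })
  structure(
    list(notes = dplyr::bind_rows(lapply(out, `[[`, "note")),
         gold = dplyr::bind_rows(lapply(out, `[[`, "gold")),
         spec = spec),
    class = "sud_corpus"
  )
}

#' @export
print.sud_corpus <- function(x, ...) {
  cat("<sud_corpus>", nrow(x$notes), "notes,", nrow(x$gold),
      "gold spans, seed", x$spec$seed, "\n")
  invisible(x)
}

#' Split a corpus into development and test sets by patient
#'
#' Samples whole patients into the development split until it holds
#' approximately `dev_fraction` of the notes (57 of 577 at the defaults), so
#' no patient appears in both splits.
#'
#' @param corpus A `sud_corpus`.
#' @param dev_fraction Target fraction of notes in the development split.
#' @param seed Seed for the patient draw; defaults to the corpus seed plus
#'   one so the split is reproducible but independent of generation.
#' @return List with `dev` and `test`, each a list of `notes` and `gold`
#'   tibbles.
#' @export
split_corpus <- function(corpus, dev_fraction = 0.1,
                         seed = corpus$spec$seed + 1L) {
  stopifnot(inherits(corpus, "sud_corpus"),
            dev_fraction > 0, dev_fraction < 1)
  set.seed(seed)
  target <- round(dev_fraction * nrow(corpus$notes))
  pids <- sample(unique(corpus$notes$patient_id))
  n_notes <- cumsum(table(corpus$notes$patient_id)[pids])
  k <- which(n_notes >= target)
  dev_pids <- pids[seq_len(if (length(k) == 0L) length(pids) else k[1])]
  in_dev <- corpus$notes$patient_id %in% dev_pids
  dev_notes <- corpus$notes[in_dev, , drop = FALSE]
  test_notes <- corpus$notes[!in_dev, , drop = FALSE]
  list(
    dev = list(notes = dev_notes,
               gold = corpus$gold[corpus$gold$note_id %in% dev_notes$note_id,
                                  , drop = FALSE]),
    test = list(notes = test_notes,
                gold = corpus$gold[corpus$gold$note_id %in%
                                     test_notes$note_id, , drop = FALSE])
  )
}
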