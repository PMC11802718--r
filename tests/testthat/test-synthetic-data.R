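test_that("the grammar renders documented diagnosis styles", {
  set.seed(101)
  found_inh <- FALSE
  for (i in 1:200) {
    s <- render_diagnosis("inhalant", "parenthetical", LEX)
    if (s == "moderate inhalant (nitrous oxide) use d/o") found_inh <- TRUE
  }
  expect_true(found_inh)

  found_ckb <- FALSE
  for (i in 1:200) {
    s <- render_diagnosis("cocaine", "checkbox", LEX)
    if (s == paste0("meets criteria for substance use disorder: cocaine ",
                    "[] mild (2-3); [] moderate (4-5); ",
                    "[x] severe (6 or more)")) found_ckb <- TRUE
  }
  expect_true(found_ckb)

  for (i in 1:50) {
    s <- render_diagnosis("alcohol", "unspecified", LEX)
    expect_false(grepl("mild|moderate|severe", s))
  }
  expect_error(render_diagnosis("alcohol", "freeform", LEX), "style")
})

test_that("all 13 documented variant strings are producible by the grammar", {
  tpl <- diagnosis_templates()
  lits <- tpl$template[!grepl("{", tpl$template, fixed = TRUE)]
  expect_length(lits, 13L)
  set.seed(999)
  drawn <- character(0)
  for (cat_ in sud_categories()) {
    for (st in unique(tpl$style)) {
      pool <- tpl[tpl$style == st & tpl$category %in% c("*", cat_), ]
      if (nrow(pool) == 0L) next
      for (k in 1:40) drawn <- c(drawn, render_diagnosis(cat_, st, LEX))
    }
  }
  expect_lte(length(drawn), 10000L)
  expect_true(all(lits %in% drawn))
})

test_that("gold spans are embedded verbatim and survive their own filters", {
  corp <- cached_corpus(40L, 17L)
  notes <- split(corp$notes$text, corp$notes$note_id)
  for (i in seq_len(nrow(corp$gold))) {
    g <- corp$gold[i, ]
    note_text <- notes[[g$note_id]]
    lex <- LEX[[g$category]]
    expect_true(grepl(g$span_text, note_text, fixed = TRUE))
    expect_true(contains_substance(g$span_text, lex))
    expect_true(contains_disorder(g$span_text, lex))
    expect_true(filter_substring_support(g$span_text, note_text, lex))
  }
})

test_that("filler text never mentions a substance", {
  filler <- sudspanr:::FILLER_SENTENCES
  for (lex in LEX) {
    for (tm in lex$substance_terms) {
      expect_false(any(grepl(tm, filler, fixed = TRUE)),
                   label = paste("filler free of", tm))
    }
  }
})

test_that("corpora are byte-reproducible per seed and empty at n = 0", {
  a <- generate_corpus(corpus_spec(n_notes = 8, seed = 5), LEX)
  b <- generate_corpus(corpus_spec(n_notes = 8, seed = 5), LEX)
  expect_identical(a$notes, b$notes)
  expect_identical(a$gold, b$gold)
  c_ <- generate_corpus(corpus_spec(n_notes = 8, seed = 6), LEX)
  expect_false(identical(a$notes$text, c_$notes$text))

  z <- generate_corpus(corpus_spec(n_notes = 0, seed = 5), LEX)
  expect_identical(nrow(z$notes), 0L)
  expect_identical(nrow(z$gold), 0L)
})

test_that("positive fractions stay within binomial bounds of the prevalences", {
  spec <- corpus_spec(n_notes = 1000, seed = 31)
  corp <- cached_corpus(1000L, 31L)
  counts <- table(factor(corp$gold$category, levels = sud_categories()))
  for (cat_ in sud_categories()) {
    p <- spec$prevalence[[cat_]]
    expected <- 1000 * p
    sd3 <- 3 * sqrt(1000 * p * (1 - p))
    expect_lte(abs(counts[[cat_]] - expected), sd3,
               label = paste(cat_, "positive count within 3 binomial SDs"))
  }
})

test_that("note lengths follow the documented location and range", {
  spec <- corpus_spec(n_notes = 1000, seed = 31)
  corp <- cached_corpus(1000L, 31L)
  lens <- vapply(corp$notes$text, count_tokens, integer(1),
                 USE.NAMES = FALSE)
  expect_lte(abs(median(lens) - spec$median_tokens) / spec$median_tokens,
             0.20)
  expect_lte(max(lens), spec$max_tokens + 50L)
})

test_that("notes carry distractors and comorbid statements as configured", {
  corp <- cached_corpus(1000L, 31L)
  expect_true(any(grepl("previous encounters problem list includes",
                        corp$notes$text, fixed = TRUE)))
  expect_true(any(grepl("r/o ", corp$notes$text, fixed = TRUE)))
  expect_true(any(grepl("denies any current", corp$notes$text, fixed = TRUE)))
  # distractor mentions are never gold-annotated: rule-out categories are
  # absent from the note's gold entries
  ro <- regmatches(corp$notes$text,
                   regexpr("r/o [a-z/ ]+ use disorder", corp$notes$text))
  expect_gt(length(ro), 0L)

  # some multi-SUD notes join their spans into one semicolon-adjacent block
  multi <- table(corp$gold$note_id)
  multi_ids <- names(multi[multi >= 2])
  joined <- vapply(multi_ids, function(id) {
    spans <- corp$gold$span_text[corp$gold$note_id == id]
    txt <- corp$notes$text[corp$notes$note_id == id]
    any(grepl(paste(spans[1], spans[2], sep = "; "), txt, fixed = TRUE))
  }, logical(1))
  expect_gt(sum(joined), 0L)
})

test_that("development and test splits share no patients", {
  corp <- cached_corpus(577L, 42L)
  sp <- split_corpus(corp, dev_fraction = 0.1)
  expect_length(intersect(sp$dev$notes$patient_id,
                          sp$test$notes$patient_id), 0L)
  expect_equal(nrow(sp$dev$notes), 57, tolerance = 0.1)
  expect_identical(nrow(sp$dev$notes) + nrow(sp$test$notes),
                   nrow(corp$notes))
})
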