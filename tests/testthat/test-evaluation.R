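test_that("answer tokenization isolates punctuation but preserves slashes", {
  expect_identical(answer_tokens("severe etoh use d/o"),
                   c("severe", "etoh", "use", "d/o"))
  expect_identical(answer_tokens("unanswerable"), character(0))
  expect_identical(answer_tokens(""), character(0))
  expect_identical(answer_tokens("Alcohol use disorder, severe"),
                   c("alcohol", "use", "disorder", ",", "severe"))
})

test_that("relaxed scores follow the TP/FP/FN token-multiset definitions", {
  g <- c("severe", "etoh", "use", "d/o")
  expect_equal(relaxed_scores(g, g), c(precision = 1, recall = 1, f1 = 1))
  got <- relaxed_scores(g, c(g, "daily"))
  expect_equal(unname(got), c(0.8, 1.0, 2 * 0.8 / 1.8), tolerance = 1e-12)
  expect_equal(unname(relaxed_scores(character(0), character(0))), c(1, 1, 1))
  expect_equal(unname(relaxed_scores(g, character(0))), c(1, 0, 0))
  expect_equal(unname(relaxed_scores(character(0), g)), c(0, 1, 0))
  # repeated tokens cost precision (multiset, not set, counting)
  expect_equal(unname(relaxed_scores(c("a", "b"), c("a", "a", "b")))[1],
               2 / 3)
})

test_that("relaxed scores agree with a brute-force counter to 1e-12", {
  set.seed(97)
  vocab <- c("alcohol", "use", "disorder", "severe", "mild", "d/o", "etoh",
             ",", "in", "remission", "dx", "noted")
  for (i in seq_len(1000)) {
    g <- random_token_multiset(vocab)
    p <- random_token_multiset(vocab)
    expect_equal(unname(relaxed_scores(g, p)), bf_relaxed(g, p),
                 tolerance = 1e-12)
  }
})

test_that("precision and recall are mirror images under argument swap", {
  set.seed(98)
  vocab <- letters[1:6]
  for (i in seq_len(200)) {
    g <- random_token_multiset(vocab)
    p <- random_token_multiset(vocab)
    expect_identical(relaxed_scores(g, p)[["precision"]],
                     relaxed_scores(p, g)[["recall"]])
  }
})

test_that("strict matching is binary exact equality with the No-SUD rule", {
  expect_identical(strict_f1("severe etoh use d/o", "severe etoh use d/o"), 1L)
  expect_identical(strict_f1("severe etoh use d/o",
                             "dx severe etoh use d/o today"), 0L)
  expect_identical(strict_f1("", "alcohol use disorder"), 0L)
  expect_identical(strict_f1("", sud_sentinel()), 1L)
  expect_identical(strict_f1("", ""), 1L)
  # normalization: casefold and whitespace collapse only
  expect_identical(strict_f1("Severe  ETOH use d/o", "severe etoh use d/o"),
                   1L)
  # strict match implies relaxed F1 of 1
  expect_equal(relaxed_scores(answer_tokens("severe etoh use d/o"),
                              answer_tokens("severe etoh use d/o"))[["f1"]],
               1)
})

test_that("scenario labels follow the five-case analysis in order", {
  expect_identical(classify_scenario(1, 1), "strict_match")
  expect_identical(classify_scenario(0.8, 1), "recall_only")
  expect_identical(classify_scenario(1, 0.6), "precision_only")
  expect_identical(classify_scenario(0, 0), "no_match")
  expect_identical(classify_scenario(0.5, 0.5), "other")
})

test_that("macro averages are per-category means over notes", {
  answers <- tibble::tibble(
    note_id = c("n1", "n2", "n3"),
    category = "alcohol",
    text = c("severe etoh use d/o", "wrong answer etoh use disorder x",
             sud_sentinel()))
  gold <- tibble::tibble(note_id = c("n1", "n2"), category = "alcohol",
                         span_text = c("severe etoh use d/o",
                                       "etoh use disorder"))
  rec <- evaluate_answers(answers, gold)
  expect_warning(tab <- macro_table(rec), "no scored notes")
  row <- tab[tab$category == "alcohol", ]
  expect_identical(row$n_pos, 2L)
  expect_equal(row$f1_strict_pos, 0.5)
  expect_equal(row$f1_strict_neg, 1)
  # combined is the mean over all notes, not the mean of subgroup means
  expect_equal(row$f1_strict_combined, 2 / 3)

  # all-sentinel answers on an all-negative corpus score a strict macro of 1
  neg <- evaluate_answers(
    tibble::tibble(note_id = c("m1", "m2"), category = "cocaine",
                   text = sud_sentinel()),
    tibble::tibble(note_id = character(0), category = character(0),
                   span_text = character(0)))
  expect_true(all(neg$strict_f1 == 1L))

  single <- evaluate_answers(
    tibble::tibble(note_id = "s1", category = "alcohol",
                   text = "severe etoh use d/o"),
    tibble::tibble(note_id = "s1", category = "alcohol",
                   span_text = "severe etoh use d/o"))
  expect_warning(stab <- macro_table(single), "no scored notes")
  expect_equal(stab$f1_strict_combined, 1)
})

test_that("candidate-count correlation matches the covariance formula", {
  lens <- tibble::tibble(note_id = paste0("n", 1:10), n_tokens = 1:10)
  cnt <- tibble::tibble(note_id = paste0("n", 1:10), category = "alcohol",
                        n_candidates = 1:10)
  rep1 <- candidate_count_report(cnt, lens)
  expect_equal(rep1$summary$pearson_r, 1, tolerance = 1e-12)

  flat <- dplyr::mutate(cnt, n_candidates = 2L)
  expect_warning(rep2 <- candidate_count_report(flat, lens), "undefined")
  expect_true(is.na(rep2$summary$pearson_r))
  expect_equal(rep2$summary$frac_multi, 1)

  set.seed(12)
  x <- sample(50:2000, 20)
  y <- rbinom(20, 4, 0.4) + 1L
  tab <- candidate_count_report(
    tibble::tibble(note_id = paste0("k", 1:20), category = "cannabis",
                   n_candidates = y),
    tibble::tibble(note_id = paste0("k", 1:20), n_tokens = x))
  expect_equal(tab$summary$pearson_r, bf_pearson(x, y), tolerance = 1e-12)
  ct <- cor.test(x, y)
  expect_equal(tab$summary$p_value, ct$p.value, tolerance = 1e-12)
})
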