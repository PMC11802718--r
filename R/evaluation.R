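# Strict and relaxed span evaluation. Relaxed scoring is token-multiset
# overlap between the gold span and the answer (true positives = shared
# tokens, false negatives = gold-only tokens, false positives = answer-only
# tokens); strict scoring is binary exact-match on normalized text. For notes
# with no gold span ("No SUD" cases) an empty answer scores 1 and any
# non-empty answer scores 0. Macro averages are arithmetic means over notes
# within a category, reported separately for notes containing SUD
# information, notes containing none, and all notes combined.

#' Tokenize an answer for relaxed scoring
#'
#' Lowercases, maps the unanswerable sentinel (or empty/missing text) to the
#' empty multiset, isolates punctuation as separate tokens — except "/",
#' preserved inside tokens so abbreviations like "d/o" and "mod/severe" stay
#' whole — and splits on whitespace. The token unit is deliberately
#' word-level, not model wordpieces, so the metrics do not depend on a
#' generation backend.
#'
#' @param text Character string.
#' @return Character vector (a token multiset).
#' @export
#' @examples
#' answer_tokens("severe etoh use d/o")
#' answer_tokens("unanswerable")
answer_tokens <- function(text) {
  if (length(text) == 0L || is.na(text)) return(character(0))
  txt <- tolower(text)
  if (grepl(SENTINEL, txt, fixed = TRUE)) return(character(0))
  txt <- gsub("([^[:alnum:][:space:]/])", " \\1 ", txt)
  toks <- strsplit(trimws(txt), "\\s+")[[1]]
  toks[nzchar(toks)]
}

multiset_overlap <- function(gold, pred) {
  tg <- table(gold)
  tp <- table(pred)
  shared <- intersect(names(tg), names(tp))
  sum(pmin(as.integer(tg[shared]), as.integer(tp[shared])))
}

#' Relaxed precision, recall and F1 from token multisets
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)` with token-multiset
#' counts. Conventions for empty multisets: both empty gives (1, 1, 1) — no
#' gold tokens and no false positives is a perfect answer; only the
#' prediction empty gives (1, 0, 0); only the gold empty gives (0, 1, 0);
#' F1 is 0 whenever `P + R = 0`.
#'
#' @param gold,pred Token multisets (character vectors, as from
#'   [answer_tokens()]).
#' @return Named numeric vector `c(precision, recall, f1)`, all in [0, 1].
#' @export
#' @examples
#' relaxed_scores(c("severe", "etoh"), c("severe", "etoh", "daily"))
relaxed_scores <- function(gold, pred) {
  ng <- length(gold)
  np <- length(pred)
  if (ng == 0L && np == 0L) {
    return(c(precision = 1, recall = 1, f1 = 1))
  }
  if (np == 0L) return(c(precision = 1, recall = 0, f1 = 0))
  if (ng == 0L) return(c(precision = 0, recall = 1, f1 = 0))
  tp <- multiset_overlap(gold, pred)
  precision <- tp / np
  recall <- tp / ng
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  c(precision = precision, recall = recall, f1 = f1)
}

strict_normalize <- function(text) {
  if (length(text) == 0L || is.na(text)) return("")
  txt <- normalize_text(text)
  if (grepl(SENTINEL, txt, fixed = TRUE)) return("")
  txt
}

#' Strict-match F1 (binary)
#'
#' 1 iff the normalized prediction exactly equals the normalized gold span
#' (casefold + whitespace collapse; the sentinel and missing gold both
#' normalize to empty), else 0. In particular: an exact match scores 1; a
#' prediction that merely contains the gold span scores 0; on a note with no
#' gold span an empty answer scores 1 and any non-empty answer scores 0.
#'
#' @param gold_text Gold span text ("" or `NA` for a note with no span).
#' @param pred_text Predicted answer text (the sentinel counts as empty).
#' @return 0 or 1.
#' @export
#' @examples
#' strict_f1("severe etoh use d/o", "severe etoh use d/o")     # 1
#' strict_f1("severe etoh use d/o", "dx severe etoh use d/o")  # 0
#' strict_f1("", "unanswerable")                               # 1
strict_f1 <- function(gold_text, pred_text) {
  as.integer(identical(strict_normalize(gold_text),
                       strict_normalize(pred_text)))
}

#' Classify the evaluation scenario of a positive-note record
#'
#' The five scenarios, evaluated in order: (i) `strict_match` — precision and
#' recall both 1; (ii) `recall_only` — recall 1, the prediction fully
#' contains the gold span; (iii) `precision_only` — precision 1, every
#' predicted token is in the gold span; (iv) `no_match` — precision and
#' recall both 0; (v) `other`.
#'
#' @param precision,recall Relaxed precision and recall (vectors accepted).
#' @return Character vector of scenario labels.
#' @export
classify_scenario <- function(precision, recall) {
  stopifnot(length(precision) == length(recall))
  ifelse(precision == 1 & recall == 1, "strict_match",
  ifelse(recall == 1, "recall_only",
  ifelse(precision == 1, "precision_only",
  ifelse(precision == 0 & recall == 0, "no_match", "other"))))
}

#' Score final answers against gold annotations
#'
#' Produces one `EvalRecord` per (note, category): relaxed precision, recall
#' and F1, strict F1, whether the note is positive for the category, and the
#' scenario label (positive notes only).
#'
#' @param answers Final answers: tibble with `note_id`, `category`, `text`.
#' @param gold Gold annotations: tibble with `note_id`, `category`,
#'   `span_text` (positive notes only; absent rows mean no span).
#' @return Tibble of per-(note, category) records.
#' @export
evaluate_answers <- function(answers, gold) {
  stopifnot(all(c("note_id", "category", "text") %in% names(answers)))
  key <- paste(answers$note_id, answers$category, sep = "\r")
  if (anyDuplicated(key)) {
    stop("answers contain duplicate (note_id, category) pairs", call. = FALSE)
  }
  gold_map <- gold_lookup(gold)
  gold_text <- vapply(key, function(k) {
    sp <- gold_map[[k]]
    if (is.null(sp)) "" else sp[1]
  }, character(1), USE.NAMES = FALSE)

  rel <- t(vapply(seq_along(key), function(i) {
    relaxed_scores(answer_tokens(gold_text[i]),
                   answer_tokens(answers$text[i]))
  }, numeric(3)))
  strict <- vapply(seq_along(key), function(i) {
    strict_f1(gold_text[i], answers$text[i])
  }, integer(1))
  positive <- nzchar(gold_text)
  tibble::tibble(
    note_id = answers$note_id,
    category = answers$category,
    positive = positive,
    relaxed_precision = rel[, "precision"],
    relaxed_recall = rel[, "recall"],
    relaxed_f1 = rel[, "f1"],
    strict_f1 = strict,
    scenario = ifelse(positive,
                      classify_scenario(rel[, "precision"], rel[, "recall"]),
                      NA_character_)
  )
}

#' Macro-averaged score table
#'
#' Per category: means over positive notes of strict F1 and relaxed F1 /
#' recall / precision, the strict F1 mean over negative notes, and the strict
#' F1 mean over all notes combined (the mean over all notes, not the mean of
#' the two subgroup means). Categories with no scored notes are omitted with
#' a warning.
#'
#' @param records Tibble from [evaluate_answers()].
#' @param categories Categories expected in the table; defaults to all 11.
#'   Expected categories absent from `records` are the ones omitted with a
#'   warning.
#' @return Tibble with one row per category.
#' @export
macro_table <- function(records, categories = sud_categories()) {
  stopifnot(all(categories %in% sud_categories()))
  cats <- intersect(categories, unique(records$category))
  absent <- setdiff(unique(records$category), sud_categories())
  if (length(absent) > 0L) {
    stop("unknown categories in records: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(categories, cats)
  if (length(missing) > 0L) {
    warning("no scored notes for categories: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(cats, function(cat) {
    rc <- records[records$category == cat, , drop = FALSE]
    pos <- rc[rc$positive, , drop = FALSE]
    neg <- rc[!rc$positive, , drop = FALSE]
    mean_or_na <- function(x) if (length(x) == 0L) NA_real_ else mean(x)
    tibble::tibble(
      category = cat,
      n_pos = nrow(pos),
      n_neg = nrow(neg),
      f1_strict_pos = mean_or_na(pos$strict_f1),
      f1_relaxed_pos = mean_or_na(pos$relaxed_f1),
      recall_relaxed_pos = mean_or_na(pos$relaxed_recall),
      precision_relaxed_pos = mean_or_na(pos$relaxed_precision),
      f1_strict_neg = mean_or_na(neg$strict_f1),
      f1_strict_combined = mean(rc$strict_f1)
    )
  })
  dplyr::bind_rows(rows)
}

#' Scenario histogram per category
#'
#' Counts positive-note records by scenario label, per category.
#'
#' @param records Tibble from [evaluate_answers()].
#' @return Tibble `category`, `scenario`, `n`, `fraction` (of the category's
#'   positive notes).
#' @export
scenario_histogram <- function(records) {
  pos <- records[records$positive, , drop = FALSE]
  out <- dplyr::count(pos, .data$category, .data$scenario, name = "n")
  totals <- dplyr::count(pos, .data$category, name = "total")
  out <- dplyr::left_join(out, totals, by = "category")
  out$fraction <- out$n / out$total
  out$total <- NULL
  out
}

significance_stars <- function(p) {
  ifelse(is.na(p), "",
  ifelse(p < 0.001, "***",
  ifelse(p < 0.01, "**",
  ifelse(p < 0.05, "*", ""))))
}

#' Candidate-count analysis
#'
#' Per category: the fraction of notes with more than one surviving candidate
#' answer, the Pearson correlation between note length (in tokens) and
#' candidate count with its two-sided significance (stars at 0.05 / 0.01 /
#' 0.001), and a stacked distribution of notes by candidate count. With fewer
#' than 3 notes or zero variance in either variable the correlation is
#' undefined and reported as `NA` with a warning.
#'
#' @param counts Tibble with `note_id`, `category`, `n_candidates` (surviving
#'   candidate answers per note and category).
#' @param note_lengths Tibble with `note_id`, `n_tokens`.
#' @return List with `summary` (per-category tibble: `frac_multi`,
#'   `pearson_r`, `p_value`, `stars`) and `distribution` (tibble `category`,
#'   `n_candidates`, `n_notes`).
#' @export
candidate_count_report <- function(counts, note_lengths) {
  stopifnot(all(c("note_id", "category", "n_candidates") %in% names(counts)),
            all(c("note_id", "n_tokens") %in% names(note_lengths)))
  merged <- dplyr::left_join(counts, note_lengths, by = "note_id")
  if (anyNA(merged$n_tokens)) {
    stop("candidate counts reference notes with no recorded length",
         call. = FALSE)
  }
  summary <- dplyr::bind_rows(lapply(split(merged, merged$category),
                                     function(d) {
    r <- NA_real_
    p <- NA_real_
    if (nrow(d) < 3L || stats::sd(d$n_tokens) == 0 ||
        stats::sd(d$n_candidates) == 0) {
      warning("Pearson r undefined for category '", d$category[1],
              "' (too few notes or zero variance)", call. = FALSE)
    } else {
      ct <- stats::cor.test(d$n_tokens, d$n_candidates, method = "pearson",
                            alternative = "two.sided")
      r <- unname(ct$estimate)
      p <- ct$p.value
    }
    tibble::tibble(category = d$category[1], n_notes = nrow(d),
                   frac_multi = mean(d$n_candidates > 1),
                   pearson_r = r, p_value = p,
                   stars = significance_stars(p))
  }))
  distribution <- dplyr::count(merged, .data$category, .data$n_candidates,
                               name = "n_notes")
  list(summary = summary, distribution = distribution)
}
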