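# Generation backends. A backend is a list with a name and a
# generate(input_text, config, context) function returning a single string;
# the context carries the (note_id, category, chunk_index, chunk_text) of the
# call. The deterministic mocks below exercise every downstream stage:
#
# * oracle     — returns the gold span when it appears verbatim in the chunk,
#                else the sentinel; drives the end-to-end correctness tests.
# * noisy      — oracle output wrapped in fixed extra words; produces answers
#                that fully contain the gold span (relaxed recall 1) without
#                matching it exactly (strict 0), the dominant error mode of
#                generative extractors.
# * hallucinating — replaces the oracle answer with a span from a different
#                category on a deterministic pseudo-random subset of chunks;
#                exercises the grounding filter.
#
# A real seq2seq model is plugged in through new_backend() with a generate()
# function that ignores the context argument.

#' Construct a generation backend
#'
#' @param name Backend name (recorded in logs and warnings).
#' @param generate Function `(input_text, config, context) -> string`. Under
#'   greedy decoding it must be deterministic in its arguments, and its output
#'   must not exceed `config$max_new_tokens` tokens.
#' @return An object of class `sud_backend`.
#' @export
new_backend <- function(name, generate) {
  stopifnot(is.character(name), length(name) == 1L, is.function(generate))
  structure(list(name = name, generate = generate), class = "sud_backend")
}

truncate_tokens <- function(text, max_new_tokens,
                            tokenizer = tokenizer_whitespace()) {
  toks <- tokenizer$tokenize(text)
  if (length(toks) > max_new_tokens) {
    text <- tokenizer$detokenize(toks[seq_len(max_new_tokens)])
  }
  text
}

gold_lookup <- function(gold) {
  stopifnot(all(c("note_id", "category", "span_text") %in% names(gold)))
  key <- paste(gold$note_id, gold$category, sep = "\r")
  split(gold$span_text, key)
}

#' Oracle mock backend
#'
#' Returns the note's gold span for the prompted category when that span
#' appears verbatim in the chunk, and the unanswerable sentinel otherwise.
#' With this backend the full pipeline must recover every gold annotation
#' exactly, which pins down the contracts of the chunker, the filters and the
#' evaluator.
#'
#' @param gold Gold annotations: data frame with `note_id`, `category`,
#'   `span_text`.
#' @return A `sud_backend`.
#' @export
backend_oracle <- function(gold) {
  lookup <- gold_lookup(gold)
  new_backend("oracle", function(input_text, config, context) {
    spans <- lookup[[paste(context$note_id, context$category, sep = "\r")]]
    if (!is.null(spans)) {
      for (sp in spans) {
        if (grepl(sp, context$chunk_text, fixed = TRUE)) {
          return(truncate_tokens(sp, config$max_new_tokens))
        }
      }
    }
    SENTINEL
  })
}

#' Noisy mock backend
#'
#' Wraps the oracle answer in fixed extra words ("response: ... (see chart
#' review)"), leaving sentinel answers untouched. Every positive answer then
#' fully contains the gold span but never equals it, reproducing the
#' recall-1/strict-0 pattern typical of generative extraction.
#'
#' @inheritParams backend_oracle
#' @param prefix,suffix Deterministic decoration added around non-sentinel
#'   oracle answers. The defaults use words that the synthetic diagnosis
#'   grammar never emits, so decorated answers always cost relaxed precision.
#' @return A `sud_backend`.
#' @export
backend_noisy <- function(gold, prefix = "response:",
                          suffix = "(see chart review)") {
  oracle <- backend_oracle(gold)
  new_backend("noisy", function(input_text, config, context) {
    ans <- oracle$generate(input_text, config, context)
    if (is_unanswerable(ans)) return(ans)
    truncate_tokens(paste(prefix, ans, suffix), config$max_new_tokens)
  })
}

#' Hallucinating mock backend
#'
#' On a deterministic pseudo-random subset of chunks (selected by hashing the
#' note id, category and chunk index, so the decision is reproducible and
#' independent of call order), returns a fabricated diagnosis span for a
#' *different* SUD category instead of the oracle answer. Such spans mention
#' the wrong substance and are typically absent from the note, so the
#' post-processing filters must remove them.
#'
#' @inheritParams backend_oracle
#' @param rate Fraction of chunks replaced by a hallucinated span, in [0, 1].
#' @param salt Integer mixed into the hash; vary it to obtain a different
#'   (still deterministic) hallucination pattern.
#' @return A `sud_backend`. The backend records each hallucinated
#'   `(note_id, category, chunk_index)` decision via the attribute function
#'   `is_hallucinated(note_id, category, chunk_index)` for test bookkeeping.
#' @export
backend_hallucinating <- function(gold, rate = 0.3, salt = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  oracle <- backend_oracle(gold)
  cats <- sud_categories()
  decide <- function(note_id, category, chunk_index) {
    h <- det_hash(paste(salt, note_id, category, chunk_index, sep = "|"))
    (h %% 10000L) / 10000 < rate
  }
  fabricate <- function(note_id, category, chunk_index) {
    other <- setdiff(cats, category)
    h <- det_hash(paste("pick", salt, note_id, category, chunk_index,
                        sep = "|"))
    pick <- other[(h %% length(other)) + 1L]
    first_term <- CATEGORY_FIRST_SUBSTANCE[[pick]]
    paste("severe", first_term, "use disorder")
  }
  bk <- new_backend("hallucinating", function(input_text, config, context) {
    if (decide(context$note_id, context$category, context$chunk_index)) {
      truncate_tokens(
        fabricate(context$note_id, context$category, context$chunk_index),
        config$max_new_tokens)
    } else {
      oracle$generate(input_text, config, context)
    }
  })
  bk$is_hallucinated <- decide
  bk
}

# Leading substance term per category, used by the hallucinating mock's
# fabricated spans (kept in code so the mock does not need a lexicon object).
CATEGORY_FIRST_SUBSTANCE <- c(
  alcohol = "alcohol", opioid = "opioid", cannabis = "cannabis",
  sedative_hypnotic_anxiolytic = "sedative", cocaine = "cocaine",
  amphetamine = "amphetamine", caffeine = "caffeine",
  hallucinogen = "hallucinogen", nicotine = "nicotine",
  inhalant = "inhalant", other_psychoactive = "other psychoactive"
)
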