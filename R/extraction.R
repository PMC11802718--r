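# Prompt construction and zero-shot extraction. One prompt per SUD category;
# only the category noun phrase changes between categories. The generation
# backend is pluggable: deterministic mock backends (see backends.R) make the
# whole downstream pipeline testable without a deployed language model, and an
# instruction-tuned seq2seq model can be adapted through the same contract.

# Display noun phrases inlined into the per-category prompts.
CATEGORY_DISPLAY <- c(
  alcohol = "alcohol",
  opioid = "opioid",
  cannabis = "cannabis",
  sedative_hypnotic_anxiolytic = "sedative, hypnotic or anxiolytic",
  cocaine = "cocaine",
  amphetamine = "amphetamine",
  caffeine = "caffeine",
  hallucinogen = "hallucinogen",
  nicotine = "nicotine",
  inhalant = "inhalant",
  other_psychoactive = "other psychoactive substance"
)

DEFAULT_PROMPT_TEMPLATE <- paste0(
  "Extract the reference to {category} use disorder diagnosis with ",
  "surrounding information relevant to it from the diagnoses section in the ",
  "following note. If you can't find the answer, please respond ",
  "\"unanswerable\". Note: {note}"
)

#' Display name of a SUD category
#'
#' @param category One of [sud_categories()].
#' @return The noun phrase used in prompts (e.g. `"sedative, hypnotic or
#'   anxiolytic"` for `sedative_hypnotic_anxiolytic`).
#' @export
category_display <- function(category) {
  if (!category %in% names(CATEGORY_DISPLAY)) {
    stop("unknown SUD category: ", category, call. = FALSE)
  }
  unname(CATEGORY_DISPLAY[[category]])
}

#' Build the extraction prompt for a category and note chunk
#'
#' Substitutes the category's display name and the chunk text into the prompt
#' template. The template must contain exactly one `{note}` placeholder and
#' the literal escape instruction ending in the unanswerable sentinel.
#'
#' @param category One of [sud_categories()].
#' @param chunk_text The note chunk to embed in the prompt (may be empty, e.g.
#'   to measure the prompt's own token count).
#' @param template Prompt template with `{category}` and `{note}`
#'   placeholders; the default is the template refined for the alcohol
#'   category, with only the category noun phrase adjusted for the others.
#' @return The prompt string.
#' @export
#' @examples
#' substr(build_prompt("alcohol", "dx: severe etoh use d/o"), 1, 52)
build_prompt <- function(category, chunk_text,
                         template = DEFAULT_PROMPT_TEMPLATE) {
  display <- category_display(category)
  n_note <- lengths(regmatches(template, gregexpr("{note}", template,
                                                  fixed = TRUE)))
  if (n_note != 1L) {
    stop("prompt template must contain exactly one {note} placeholder",
         call. = FALSE)
  }
  if (!grepl(SENTINEL, template, fixed = TRUE)) {
    stop("prompt template must contain the escape instruction with the ",
         "sentinel \"", SENTINEL, "\"", call. = FALSE)
  }
  out <- gsub("{category}", display, template, fixed = TRUE)
  # sub() interprets backslashes in the replacement even with fixed patterns
  sub("{note}", gsub("\\", "\\\\", chunk_text, fixed = TRUE), out,
      fixed = TRUE)
}

#' Text-generation decoding configuration
#'
#' Greedy decoding with temperature 1 and at most 100 new tokens: under greedy
#' decoding repeated calls on identical input yield identical output, which is
#' what makes the candidate files byte-reproducible.
#'
#' @param decoding Decoding strategy; only `"greedy"` is supported.
#' @param temperature Softmax temperature (kept at 1; irrelevant under greedy
#'   decoding but recorded for provenance).
#' @param max_new_tokens Maximum generated length in backend tokens.
#' @return An object of class `sud_generation_config`.
#' @export
generation_config <- function(decoding = "greedy", temperature = 1,
                              max_new_tokens = 100L) {
  if (!identical(decoding, "greedy")) {
    stop("only greedy decoding is supported", call. = FALSE)
  }
  stopifnot(max_new_tokens >= 1L)
  structure(list(decoding = decoding, temperature = temperature,
                 max_new_tokens = as.integer(max_new_tokens)),
            class = "sud_generation_config")
}

#' Is a generated answer the unanswerable sentinel?
#'
#' Case-insensitive substring containment: any generated text containing
#' "unanswerable" counts as the escape answer, since generated casing and
#' surrounding words are uncontrolled.
#'
#' @param text Character vector of generated answers.
#' @return Logical vector.
#' @export
#' @examples
#' is_unanswerable(c("unanswerable", "severe etoh use d/o", "Unanswerable."))
is_unanswerable <- function(text) {
  out <- grepl(SENTINEL, tolower(text), fixed = TRUE)
  out[is.na(text)] <- TRUE
  out
}

#' Run zero-shot extraction for one note and category
#'
#' Plans the chunk window from the prompt's own token count, splits the note
#' into sliding windows, builds one prompt per chunk and collects the
#' backend's raw output as one candidate answer per chunk, in chunk order.
#' A backend error on a chunk is recorded as the unanswerable sentinel and the
#' run continues; an empty note yields zero candidates with a warning.
#'
#' @param note A list or one-row data frame with elements `note_id` and
#'   `text`.
#' @param category One of [sud_categories()].
#' @param backend A `sud_backend` (see [backend_oracle()] and friends).
#' @param config A [generation_config()].
#' @param max_len Maximum model input length in tokens (default 512).
#' @param stride Document stride between chunk starts (default 128).
#' @param tokenizer Tokenizer used for counting and chunking.
#' @param template Prompt template passed to [build_prompt()].
#' @return A tibble of candidate answers: `note_id`, `category`,
#'   `chunk_index`, `text`.
#' @export
run_extraction <- function(note, category, backend,
                           config = generation_config(),
                           max_len = 512L, stride = 128L,
                           tokenizer = tokenizer_whitespace(),
                           template = DEFAULT_PROMPT_TEMPLATE) {
  stopifnot(inherits(backend, "sud_backend"),
            inherits(config, "sud_generation_config"))
  note_id <- as.character(note$note_id)
  prompt_prefix <- build_prompt(category, "", template)
  prompt_tokens <- tokenizer$tokenize(prompt_prefix)
  window <- plan_window(prompt_tokens, max_len)

  note_tokens <- tokenizer$tokenize(note$text)
  if (length(note_tokens) == 0L) {
    warning("note '", note_id, "' is empty; no candidates generated",
            call. = FALSE)
    return(tibble::tibble(note_id = character(0), category = character(0),
                          chunk_index = integer(0), text = character(0)))
  }
  chunks <- make_chunks(note_tokens, window, stride)
  texts <- vapply(seq_len(nrow(chunks)), function(i) {
    ctx <- list(note_id = note_id, category = category,
                chunk_index = chunks$chunk_index[i],
                chunk_text = chunks$text[i])
    input <- build_prompt(category, chunks$text[i], template)
    tryCatch(
      backend$generate(input, config, ctx),
      error = function(e) {
        warning("backend '", backend$name, "' failed on note '", note_id,
                "' chunk ", ctx$chunk_index, ": ", conditionMessage(e),
                call. = FALSE)
        SENTINEL
      }
    )
  }, character(1))
  tibble::tibble(note_id = note_id, category = category,
                 chunk_index = chunks$chunk_index, text = texts)
}
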