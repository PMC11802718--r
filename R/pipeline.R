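# End-to-end pipeline: chunk every note, extract per-category candidates
# through the backend, post-process to one final answer per (note, category),
# and — when gold annotations are supplied — produce the macro score table,
# the scenario histogram and the candidate-count analysis.

#' Pipeline configuration
#'
#' Collects every tunable of the workflow in one serializable object; the
#' configuration hash is embedded in output files for provenance.
#'
#' @param backend_name Name of the generation backend (recorded only; the
#'   backend object itself is passed to [run_pipeline()]).
#' @param max_len Maximum model input length in tokens.
#' @param stride Document stride between chunk starts.
#' @param max_new_tokens Generation length cap.
#' @param min_len Minimum grounded common-substring length for filter (iii).
#' @param metric Distance metric for proxy selection.
#' @param dedupe Deduplicate identical surviving candidates.
#' @param lexicon_path Lexicon configuration file.
#' @param seed Seed recorded for provenance.
#' @return An object of class `sud_pipeline_config`.
#' @export
pipeline_config <- function(backend_name = "oracle", max_len = 512L,
                            stride = 128L, max_new_tokens = 100L,
                            min_len = 5L,
                            metric = c("euclidean", "cosine"),
                            dedupe = TRUE,
                            lexicon_path = default_lexicon_path(),
                            seed = 42L) {
  metric <- match.arg(metric)
  structure(list(backend_name = backend_name, max_len = as.integer(max_len),
                 stride = as.integer(stride),
                 max_new_tokens = as.integer(max_new_tokens),
                 min_len = as.integer(min_len), metric = metric,
                 dedupe = dedupe, lexicon_path = lexicon_path,
                 seed = as.integer(seed)),
            class = "sud_pipeline_config")
}

#' Run the full extraction pipeline over a corpus
#'
#' For every note and every SUD category: sliding-window chunking, one
#' backend call per chunk, and post-processing to a single final answer.
#' With gold annotations, also computes per-record evaluation, the
#' macro-averaged score table, the scenario histogram and the
#' candidate-count report. Per-note backend errors are downgraded to sentinel
#' answers and do not abort the run.
#'
#' @param notes Tibble with `note_id` and `text` (e.g. a corpus `notes`
#'   table or [read_notes()] output).
#' @param backend A `sud_backend`.
#' @param gold Optional gold annotations (`note_id`, `category`,
#'   `span_text`).
#' @param config A [pipeline_config()].
#' @param categories Categories to run (default: all 11).
#' @param lexicons Lexicon list; loaded from `config$lexicon_path` by
#'   default.
#' @param embedder Embedder for proxy selection.
#' @param verbose Log per-stage counts to stderr.
#' @return List with `answers` (final answers incl. selection method and
#'   survivor counts), `candidates` (all raw per-chunk candidates), `counts`
#'   (per-stage totals: notes, chunks, candidates, survivors, sentinels) and,
#'   when gold is given, `records`, `scores`, `scenarios`,
#'   `candidate_report`.
#' @export
run_pipeline <- function(notes, backend, gold = NULL,
                         config = pipeline_config(),
                         categories = sud_categories(),
                         lexicons = load_lexicons(config$lexicon_path),
                         embedder = embedder_hash(),
                         verbose = FALSE) {
  stopifnot(inherits(backend, "sud_backend"),
            inherits(config, "sud_pipeline_config"),
            all(categories %in% sud_categories()))
  gen_cfg <- generation_config(max_new_tokens = config$max_new_tokens)
  tokenizer <- tokenizer_whitespace()
  say <- function(...) if (verbose) message(...)

  if (nrow(notes) == 0L) {
    warning("empty notes input; producing empty outputs", call. = FALSE)
  }
  answers <- list()
  candidates <- list()
  n_chunks_total <- 0L
  for (cat in categories) {
    lex <- lexicons[[cat]]
    for (i in seq_len(nrow(notes))) {
      note <- notes[i, , drop = FALSE]
      cand <- run_extraction(note, cat, backend, gen_cfg,
                             max_len = config$max_len,
                             stride = config$stride,
                             tokenizer = tokenizer)
      n_chunks_total <- n_chunks_total + nrow(cand)
      final <- postprocess_note(cand, note$text, lex, embedder,
                                min_len = config$min_len,
                                metric = config$metric,
                                dedupe = config$dedupe)
      if (is.na(final$note_id[1])) final$note_id <- note$note_id
      answers[[length(answers) + 1L]] <- final
      candidates[[length(candidates) + 1L]] <- cand
    }
    say("category ", cat, ": ", nrow(notes), " notes processed")
  }
  answers <- if (length(answers) == 0L) {
    tibble::tibble(note_id = character(0), category = character(0),
                   text = character(0), selection_method = character(0),
                   n_candidates = integer(0), n_survivors = integer(0))
  } else {
    dplyr::bind_rows(answers)
  }
  candidates <- if (length(candidates) == 0L) {
    tibble::tibble(note_id = character(0), category = character(0),
                   chunk_index = integer(0), text = character(0))
  } else {
    dplyr::bind_rows(candidates)
  }
  counts <- list(
    notes = nrow(notes),
    categories = length(categories),
    chunks = n_chunks_total,
    candidates = nrow(candidates),
    survivors = sum(answers$n_survivors),
    sentinel_answers = sum(is_unanswerable(answers$text))
  )
  say("totals: ", counts$chunks, " chunks, ", counts$candidates,
      " candidates, ", counts$sentinel_answers, " sentinel answers")

  out <- list(answers = answers, candidates = candidates, counts = counts,
              config = config)
  if (!is.null(gold) && nrow(notes) > 0L) {
    records <- evaluate_answers(answers, gold)
    note_lengths <- tibble::tibble(
      note_id = notes$note_id,
      n_tokens = vapply(notes$text, count_tokens, integer(1),
                        USE.NAMES = FALSE)
    )
    cand_counts <- tibble::tibble(
      note_id = answers$note_id,
      category = answers$category,
      n_candidates = answers$n_survivors
    )
    out$records <- records
    out$scores <- macro_table(records, categories)
    out$scenarios <- scenario_histogram(records)
    out$candidate_report <- suppressWarnings(
      candidate_count_report(cand_counts, note_lengths)
    )
  }
  out
}
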