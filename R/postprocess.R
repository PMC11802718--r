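# Four-stage post-processing cascade. Per (note, category), the per-chunk
# candidates are reduced to one final answer:
#   (i)   drop answers lacking any category substance term,
#   (ii)  drop answers where no use-disorder phrase follows the substance,
#   (iii) drop answers whose note-grounded material (maximal common substrings
#         of >= min_len characters with the note) fails (i)-(ii) — the
#         hallucination check,
#   (iv)  if more than one distinct answer survives, pick the one closest to
#         the category's proxy ground truth in embedding space (minimum
#         Euclidean distance by default).
# Filtered answers are replaced by the unanswerable sentinel.

#' Character positions of a candidate grounded in the note
#'
#' Computes which characters of `candidate` lie inside a maximal common
#' substring (of at least `min_len` characters) shared with `note_text`, on
#' lowercased whitespace-collapsed text.
#'
#' @param candidate Candidate answer text.
#' @param note_text Full note text.
#' @param min_len Minimum common-substring length in characters.
#' @return Logical vector over the characters of the normalized candidate.
#' @keywords internal
supported_positions <- function(candidate, note_text, min_len = 5L) {
  cand <- normalize_text(candidate)
  note <- normalize_text(note_text)
  if (!nzchar(cand) || !nzchar(note)) {
    return(logical(nchar(cand)))
  }
  .supported_mask_cpp(utf8ToInt(cand), utf8ToInt(note), as.integer(min_len))
}

#' Grounding filter: is the candidate's lexicon content supported by the note?
#'
#' Post-processing filter (iii). Finds all maximal common substrings of length
#' at least `min_len` characters between the lowercased candidate and note;
#' returns `TRUE` iff at least one exists and the concatenation of the
#' supported candidate material (unsupported stretches replaced by a single
#' space) still satisfies [contains_substance()] and [contains_disorder()].
#' A candidate whose substance/disorder phrases are not verbatim from the note
#' is thereby flagged as hallucination-like and removed. The default
#' `min_len = 5` matches the shortest real-world use-disorder reference,
#' "mj ud" (5 characters).
#'
#' @inheritParams supported_positions
#' @param lex A `sud_lexicon`.
#' @return Logical scalar.
#' @export
#' @examples
#' lex <- load_lexicons()
#' filter_substring_support("severe etoh use d/o",
#'                          "dx: severe etoh use d/o", lex$alcohol)
filter_substring_support <- function(candidate, note_text, lex,
                                     min_len = 5L) {
  stopifnot(inherits(lex, "sud_lexicon"))
  if (is_unanswerable(candidate)) return(FALSE)
  mask <- supported_positions(candidate, note_text, min_len)
  if (!any(mask)) return(FALSE)
  chars <- strsplit(normalize_text(candidate), "")[[1]]
  chars[!mask] <- "\r"
  supported <- gsub("\r+", " ", paste(chars, collapse = ""))
  contains_substance(supported, lex) && contains_disorder(supported, lex)
}

#' Apply post-processing filters (i)-(iii) to candidate answers
#'
#' Keeps, in original chunk order, the candidates that are not the sentinel
#' and pass [contains_substance()], [contains_disorder()] and
#' [filter_substring_support()] against the note. Removed candidates are
#' recorded (replaced by the sentinel) in the `"replaced"` attribute of the
#' result.
#'
#' @param candidates Tibble of candidate answers (`note_id`, `category`,
#'   `chunk_index`, `text`), as produced by [run_extraction()].
#' @param note_text Full note text.
#' @param lex A `sud_lexicon`.
#' @param min_len Minimum grounded common-substring length, in characters.
#' @return The surviving rows of `candidates`; attribute `"replaced"` holds
#'   the removed rows with their text set to the sentinel.
#' @export
apply_filters <- function(candidates, note_text, lex, min_len = 5L) {
  keep <- vapply(candidates$text, function(txt) {
    !is_unanswerable(txt) &&
      contains_substance(txt, lex) &&
      contains_disorder(txt, lex) &&
      filter_substring_support(txt, note_text, lex, min_len)
  }, logical(1), USE.NAMES = FALSE)
  out <- candidates[keep, , drop = FALSE]
  replaced <- candidates[!keep, , drop = FALSE]
  if (nrow(replaced) > 0L) replaced$text <- SENTINEL
  attr(out, "replaced") <- replaced
  out
}

expand_proxy <- function(proxy) {
  toks <- strsplit(normalize_text(proxy), " ", fixed = TRUE)[[1]]
  variants <- list(character(0))
  for (tok in toks) {
    alts <- if (grepl("/", tok, fixed = TRUE)) {
      strsplit(tok, "/", fixed = TRUE)[[1]]
    } else {
      tok
    }
    variants <- unlist(lapply(variants, function(v) {
      lapply(alts, function(a) c(v, a))
    }), recursive = FALSE)
  }
  unique(vapply(variants, paste, character(1), collapse = " "))
}

#' Select the candidate closest to the proxy ground truth
#'
#' Post-processing step (iv). Embeds the proxy phrase and each candidate and
#' returns the candidate at minimum Euclidean distance from the proxy (ties
#' broken by lowest chunk index). A proxy written with "/" alternatives
#' ("... use disorder/dependence") is expanded into its variants and each
#' candidate is scored by its best variant. Cosine distance is available via
#' `metric = "cosine"`. If the embedder fails, the candidate with the lowest
#' chunk index is returned with a warning.
#'
#' @param candidates Tibble with at least `chunk_index` and `text`; two or
#'   more rows.
#' @param proxy The category's proxy ground-truth phrase.
#' @param embedder A `sud_embedder`.
#' @param metric Distance metric, `"euclidean"` (default) or `"cosine"`.
#' @return The selected row of `candidates`.
#' @export
select_by_proxy <- function(candidates, proxy, embedder = embedder_hash(),
                            metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  stopifnot(nrow(candidates) >= 2L)
  ord <- order(candidates$chunk_index)
  candidates <- candidates[ord, , drop = FALSE]
  dists <- tryCatch({
    proxy_embs <- lapply(expand_proxy(proxy), embedder$embed)
    vapply(candidates$text, function(txt) {
      ce <- embedder$embed(txt)
      min(vapply(proxy_embs, embedding_distance, numeric(1), a = ce,
                 metric = metric))
    }, numeric(1), USE.NAMES = FALSE)
  }, error = function(e) {
    warning("embedder failed (", conditionMessage(e),
            "); falling back to lowest chunk index", call. = FALSE)
    NULL
  })
  if (is.null(dists)) return(candidates[1L, , drop = FALSE])
  candidates[which.min(dists), , drop = FALSE]
}

#' Reduce candidate answers to one final answer
#'
#' Runs filters (i)-(iii), deduplicates surviving answers by exact text (the
#' same span extracted from overlapping chunks counts once), then resolves:
#' zero survivors give the sentinel (`all_unanswerable` if every candidate was
#' already the sentinel, else `all_filtered`); a single distinct survivor is
#' returned as-is (`single_survivor`); multiple distinct survivors go to proxy
#' selection (`proxy_embedding`).
#'
#' @inheritParams apply_filters
#' @param embedder A `sud_embedder` for step (iv).
#' @param metric Distance metric for step (iv).
#' @param dedupe Deduplicate identical surviving answers before counting
#'   (default `TRUE`).
#' @return A one-row tibble: `note_id`, `category`, `text`,
#'   `selection_method`, `n_candidates`, `n_survivors`.
#' @export
postprocess_note <- function(candidates, note_text, lex,
                             embedder = embedder_hash(), min_len = 5L,
                             metric = c("euclidean", "cosine"),
                             dedupe = TRUE) {
  metric <- match.arg(metric)
  note_id <- if (nrow(candidates) > 0L) candidates$note_id[1] else NA_character_
  answer_row <- function(text, method, n_surv) {
    tibble::tibble(note_id = note_id, category = lex$category, text = text,
                   selection_method = method,
                   n_candidates = nrow(candidates), n_survivors = n_surv)
  }
  if (nrow(candidates) == 0L) {
    return(answer_row(SENTINEL, "all_unanswerable", 0L))
  }
  stopifnot(length(unique(candidates$note_id)) == 1L,
            length(unique(candidates$category)) == 1L)
  surv <- apply_filters(candidates, note_text, lex, min_len)
  if (dedupe && nrow(surv) > 1L) {
    surv <- surv[!duplicated(surv$text), , drop = FALSE]
  }
  if (nrow(surv) == 0L) {
    method <- if (all(is_unanswerable(candidates$text))) {
      "all_unanswerable"
    } else {
      "all_filtered"
    }
    return(answer_row(SENTINEL, method, 0L))
  }
  if (nrow(surv) == 1L) {
    return(answer_row(surv$text[1], "single_survivor", 1L))
  }
  sel <- select_by_proxy(surv, lex$proxy_ground_truth, embedder, metric)
  answer_row(sel$text[1], "proxy_embedding", nrow(surv))
}
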