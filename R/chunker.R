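# Sliding-window chunker. Clinical notes routinely exceed the model's maximum
# input length (512 tokens for the encoder-decoder models targeted here), and
# because free-text notes have no reliable section structure the whole note is
# presented to the model as overlapping fixed-size windows. The stride is the
# advance between consecutive window start offsets, following the
# reading-comprehension sliding-window convention; with window 462 and stride
# 128 consecutive chunks share 334 tokens, so any span of up to 335 tokens is
# guaranteed to appear intact in at least one chunk.

#' Window size available for note text given a prompt
#'
#' The chunk window is whatever remains of the model's maximum sequence length
#' after the prompt tokens are prepended: a 50-token prompt with a 512-token
#' limit leaves a 462-token window.
#'
#' @param prompt_tokens Character vector of prompt tokens, or a single
#'   non-negative integer giving the prompt token count.
#' @param max_len Maximum model input length in tokens (default 512).
#' @return Integer window size `max_len - length(prompt_tokens)`.
#' @export
#' @examples
#' plan_window(rep("w", 50), 512)  # 462
plan_window <- function(prompt_tokens, max_len = 512L) {
  n_prompt <- prompt_token_count(prompt_tokens)
  stopifnot(max_len >= 1L)
  if (n_prompt >= max_len) {
    stop("prompt has ", n_prompt, " tokens, which does not fit a maximum ",
         "input length of ", max_len, call. = FALSE)
  }
  as.integer(max_len - n_prompt)
}

prompt_token_count <- function(prompt_tokens) {
  if (is.numeric(prompt_tokens) && length(prompt_tokens) == 1L) {
    stopifnot(prompt_tokens >= 0, prompt_tokens == as.integer(prompt_tokens))
    as.integer(prompt_tokens)
  } else {
    length(prompt_tokens)
  }
}

#' Split a tokenized note into sliding windows
#'
#' Chunk start offsets are `0, stride, 2*stride, ...`; each chunk holds
#' `min(window, n - start)` tokens and generation stops with the first chunk
#' whose end reaches the final token. A note that fits in one window yields
#' exactly one chunk; every token is covered by at least one chunk and
#' consecutive chunks overlap by `window - stride` tokens.
#'
#' @param note_tokens Character vector of note tokens.
#' @param window Window size in tokens (positive).
#' @param stride Advance between consecutive chunk starts, `1 <= stride <=
#'   window`.
#' @return A tibble with one row per chunk: `chunk_index` (0-based),
#'   `start_token` / `end_token` (0-based, end exclusive) and `text` (the
#'   detokenized window). An empty token list yields zero rows with attribute
#'   `empty_note = TRUE`.
#' @export
#' @examples
#' make_chunks(paste0("w", 1:590), window = 462, stride = 128)[, 1:3]
make_chunks <- function(note_tokens, window, stride) {
  stopifnot(window >= 1L, stride >= 1L)
  if (stride > window) {
    stop("stride (", stride, ") must not exceed window (", window, ")",
         call. = FALSE)
  }
  n <- length(note_tokens)
  if (n == 0L) {
    out <- tibble::tibble(chunk_index = integer(0), start_token = integer(0),
                          end_token = integer(0), text = character(0))
    attr(out, "empty_note") <- TRUE
    return(out)
  }
  starts <- integer(0)
  ends <- integer(0)
  s <- 0L
  repeat {
    e <- min(s + window, n)
    starts <- c(starts, s)
    ends <- c(ends, e)
    if (e >= n) break
    s <- s + as.integer(stride)
  }
  tibble::tibble(
    chunk_index = seq_along(starts) - 1L,
    start_token = starts,
    end_token = as.integer(ends),
    text = vapply(seq_along(starts), function(i) {
      paste(note_tokens[(starts[i] + 1L):ends[i]], collapse = " ")
    }, character(1))
  )
}

#' Prepend prompt tokens to a note chunk
#'
#' Forms one model input text: prompt tokens followed by the chunk tokens,
#' joined with single spaces. Errors if the combined length would exceed
#' `max_len`, with the window size to re-chunk at.
#'
#' @param prompt_tokens Character vector of prompt tokens.
#' @param chunk A one-row chunk (as from [make_chunks()]) or a character
#'   vector of chunk tokens.
#' @param max_len Maximum model input length in tokens.
#' @return The assembled input text (single string).
#' @export
assemble_input <- function(prompt_tokens, chunk, max_len = 512L) {
  chunk_tokens <- if (is.character(chunk)) {
    chunk
  } else {
    strsplit(chunk$text, " ", fixed = TRUE)[[1]]
  }
  n_total <- length(prompt_tokens) + length(chunk_tokens)
  if (n_total > max_len) {
    stop("prompt (", length(prompt_tokens), " tokens) plus chunk (",
         length(chunk_tokens), " tokens) exceeds max_len ", max_len,
         "; re-chunk the note with window = ",
         max_len - length(prompt_tokens), call. = FALSE)
  }
  paste(c(prompt_tokens, chunk_tokens), collapse = " ")
}
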