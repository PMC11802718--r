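# Tokenizer contract. Token counts throughout the pipeline are defined by a
# tokenizer object; the shipped whitespace tokenizer keeps the chunker and the
# synthetic-data generator backend-free. An adapter for a real model backend
# can supply its own subword tokenizer through the same contract.

#' Whitespace tokenizer
#'
#' Splits text on runs of whitespace and joins tokens back with single spaces.
#' Detokenization therefore collapses whitespace, but preserves every
#' single-space-separated phrase (in particular all lexicon terms) as a
#' substring, which is the contract the downstream string filters rely on.
#'
#' @return An object of class `sud_tokenizer` with elements `name`,
#'   `tokenize(text)` and `detokenize(tokens)`.
#' @export
#' @examples
#' tk <- tokenizer_whitespace()
#' tk$tokenize("severe etoh  use d/o")
tokenizer_whitespace <- function() {
  structure(
    list(
      name = "whitespace",
      tokenize = function(text) {
        stopifnot(length(text) == 1L)
        if (is.na(text) || !nzchar(trimws(text))) return(character(0))
        strsplit(trimws(text), "\\s+")[[1]]
      },
      detokenize = function(tokens) paste(tokens, collapse = " ")
    ),
    class = "sud_tokenizer"
  )
}

#' Count tokens in a text
#'
#' @param text Character string.
#' @param tokenizer A `sud_tokenizer`; whitespace by default.
#' @return Integer token count.
#' @export
count_tokens <- function(text, tokenizer = tokenizer_whitespace()) {
  length(tokenizer$tokenize(text))
}
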