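# Shared fixtures and independent oracles. Everything is built in code; the
# brute-force oracles deliberately use different algorithms than the package
# implementation they check.

# lexicons are immutable; load once per test run
LEX <- load_lexicons()

# Memoized corpora so the heavier end-to-end tests share one generation pass.
.corpus_cache <- new.env(parent = emptyenv())
cached_corpus <- function(n_notes, seed) {
  key <- paste0("n", n_notes, "_s", seed)
  if (is.null(.corpus_cache[[key]])) {
    .corpus_cache[[key]] <- generate_corpus(
      corpus_spec(n_notes = n_notes, seed = seed), LEX)
  }
  .corpus_cache[[key]]
}

# study-scale corpus used by the end-to-end and acceptance tests
study_corpus <- function() cached_corpus(577L, 42L)

# Tiny deterministic two-note corpus for unit tests.
tiny_notes <- function() {
  tibble::tibble(
    note_id = c("n1", "n2"),
    text = c(paste("visit note", "dx: severe etoh use d/o",
                   "patient doing well", sep = "\n"),
             "follow up visit\nno concerns raised today")
  )
}

tiny_gold <- function() {
  tibble::tibble(note_id = "n1", category = "alcohol",
                 span_text = "severe etoh use d/o")
}

# Brute-force chunk-start enumerator (vectorized closed form, independent of
# the package's repeat-loop implementation).
bf_chunk_bounds <- function(n, window, stride) {
  starts <- seq(0L, max(n - 1L, 0L), by = stride)
  ends <- pmin(starts + window, n)
  k <- which(ends >= n)[1]
  list(starts = starts[seq_len(k)], ends = ends[seq_len(k)])
}

# Brute-force token-multiset precision/recall/F1: removes matched gold tokens
# one at a time instead of using tabulation.
bf_relaxed <- function(gold, pred) {
  if (length(gold) == 0L && length(pred) == 0L) return(c(1, 1, 1))
  if (length(pred) == 0L) return(c(1, 0, 0))
  if (length(gold) == 0L) return(c(0, 1, 0))
  pool <- gold
  tp <- 0L
  for (tok in pred) {
    hit <- match(tok, pool)
    if (!is.na(hit)) {
      tp <- tp + 1L
      pool <- pool[-hit]
    }
  }
  p <- tp / length(pred)
  r <- tp / length(gold)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(p, r, f)
}

# Direct covariance-formula Pearson correlation.
bf_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

random_token_multiset <- function(vocab, max_len = 8L) {
  n <- sample(0:max_len, 1L)
  if (n == 0L) character(0) else sample(vocab, n, replace = TRUE)
}
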