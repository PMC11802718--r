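# Embedding contract for proxy-based answer selection. The pipeline only
# requires embed(text) -> fixed-length real vector, deterministic. The shipped
# embedder is a signed feature-hashing bag of words and character trigrams:
# word-level features capture the lexical overlap between a candidate and the
# proxy phrase, character trigrams capture abbreviation-level similarity
# ("etoh" vs "alcohol" contexts, "d/o" vs "disorder"), and counts are left
# unnormalized so that Euclidean distance stays sensitive to answer length —
# the property that motivates preferring Euclidean distance over cosine
# similarity when ranking candidates of very different verbosity.

#' Deterministic feature-hashing embedder
#'
#' @param dim Embedding dimensionality.
#' @param char_ngram Character n-gram order added alongside word features.
#' @return An object of class `sud_embedder` with elements `name`, `dim` and
#'   `embed(text)`.
#' @export
#' @examples
#' emb <- embedder_hash()
#' length(emb$embed("alcohol use disorder, severe"))
embedder_hash <- function(dim = 256L, char_ngram = 3L) {
  stopifnot(dim >= 2L, char_ngram >= 2L)
  dim <- as.integer(dim)
  p <- 2147483647
  feature_hash <- function(feat) {
    h <- 7
    for (cp in utf8ToInt(feat)) h <- (h * 131 + cp) %% p
    h
  }
  embed <- function(text) {
    v <- numeric(dim)
    txt <- normalize_text(text)
    if (!nzchar(txt)) return(v)
    feats <- strsplit(txt, " ", fixed = TRUE)[[1]]
    padded <- paste0("^", gsub(" ", "_", txt), "$")
    nc <- nchar(padded)
    if (nc >= char_ngram) {
      feats <- c(feats, substring(padded, 1:(nc - char_ngram + 1L),
                                  char_ngram:nc))
    }
    for (f in feats) {
      h <- feature_hash(f)
      bucket <- (h %% dim) + 1L
      sign <- if ((h %/% dim) %% 2 == 0) 1 else -1
      v[bucket] <- v[bucket] + sign
    }
    v
  }
  structure(list(name = "hash", dim = dim, embed = embed),
            class = "sud_embedder")
}

#' Distance between two embedding vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @param metric `"euclidean"` (default, used for candidate selection) or
#'   `"cosine"` (returned as a distance, `1 - cosine similarity`).
#' @return Non-negative scalar distance.
#' @export
embedding_distance <- function(a, b, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  stopifnot(length(a) == length(b))
  if (metric == "euclidean") {
    sqrt(sum((a - b)^2))
  } else {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(1)
    1 - sum(a * b) / (na * nb)
  }
}
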