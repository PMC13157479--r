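# Embedding backend interface. The packaged fallback is a deterministic
# signed character-n-gram hashing embedder: each n-gram of the
# normalized text is hashed to a coordinate and a sign, counts are
# accumulated and the vector L2-normalized. No model weights, no
# external calls; the same text always yields the same vector.

#' Hashing embedding backend
#'
#' A deterministic dense-vector embedder over character n-grams.
#' Lexically similar strings share n-grams and therefore have high
#' cosine similarity, which is what the K = 1 retrieval tier needs from
#' an embedding space; it does not model cross-lingual semantics (the
#' translation stage handles language).
#'
#' @param dim Vector dimension (default 256).
#' @param ngram Character n-gram length (default 3).
#' @param seed Integer hash seed; part of the backend identity.
#' @param instruction Optional instruction string prepended to every
#'   text before hashing (mirrors instruction-tuned embedders; default
#'   empty).
#' @return An object of class `hash_backend`.
#' @export
hash_embedding_backend <- function(dim = 256L, ngram = 3L, seed = 17L,
                                   instruction = "") {
  stopifnot(dim >= 8, ngram >= 1)
  structure(
    list(
      id = sprintf("hash-ngram%d-dim%d-seed%d", ngram, dim, seed),
      dim = as.integer(dim), ngram = as.integer(ngram),
      seed = as.integer(seed), instruction = instruction
    ),
    class = c("hash_backend", "ophpo_embedding_backend")
  )
}

#' Embed texts as L2-normalized row vectors
#'
#' @param backend An embedding backend.
#' @param texts Character vector.
#' @param ... Passed to methods.
#' @return Numeric matrix, one row per text, `backend$dim` columns,
#'   rows of unit L2 norm.
#' @export
embed_texts <- function(backend, texts, ...) UseMethod("embed_texts")

#' @rdname embed_texts
#' @export
embed_texts.hash_backend <- function(backend, texts, ...) {
  n <- length(texts)
  out <- matrix(0, nrow = n, ncol = backend$dim)
  for (i in seq_len(n)) {
    out[i, ] <- .hash_embed_one(texts[[i]], backend)
  }
  rownames(out) <- NULL
  out
}

.hash_embed_one <- function(text, backend) {
  txt <- normalize_surface(paste0(backend$instruction, text))
  txt <- paste0("^", txt, "$") # boundary markers so affixes count
  ints <- utf8ToInt(enc2utf8(txt))
  k <- backend$ngram
  if (length(ints) < k) ints <- c(ints, rep(36L, k - length(ints))) # pad '$'
  v <- numeric(backend$dim)
  for (s in seq_len(length(ints) - k + 1L)) {
    h <- .roll_hash(ints[s:(s + k - 1L)], seed = backend$seed)
    bucket <- (h %% backend$dim) + 1L
    sign <- if ((h %/% backend$dim) %% 2 == 0) 1 else -1
    v[bucket] <- v[bucket] + sign
  }
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) { # signs cancelled exactly; deterministic fallback basis vector
    v[1] <- 1
    nrm <- 1
  }
  v / nrm
}
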