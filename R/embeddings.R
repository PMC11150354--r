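# Sentence encoders: a pluggable production-transformer hook and a
# deterministic hash-based encoder used everywhere offline.

#' Describe a sentence encoder
#'
#' Two backends are supported. `"deterministic"` is a download-free encoder
#' whose vectors are a pure function of the token multiset, embedding
#' dimension and seed; texts sharing more tokens get higher cosine similarity
#' in expectation, which is all the graph builders need. `"transformer"`
#' delegates to a user-supplied encoding function (e.g. wrapping a
#' sentence-transformer such as all-mpnet-base-v2, the production encoder
#' whose 768 dimensions the default `dim` mirrors); it is never required by
#' any test or offline path.
#'
#' @param backend `"deterministic"` or `"transformer"`.
#' @param model_name Informative model label (transformer backend).
#' @param dim Embedding dimension.
#' @param seed Seed for the deterministic backend.
#' @param normalize L2-normalize output vectors so cosine = dot product.
#' @param encode_fun For the transformer backend: `function(texts)` returning
#'   an n x dim numeric matrix.
#' @return An `encoder_spec` object.
#' @export
encoder_spec <- function(backend = c("deterministic", "transformer"),
                         model_name = "all-mpnet-base-v2",
                         dim = 768L, seed = 0L, normalize = TRUE,
                         encode_fun = NULL) {
  backend <- match.arg(backend)
  stopifnot(dim > 0L)
  structure(list(backend = backend, model_name = model_name,
                 dim = as.integer(dim), seed = as.integer(seed),
                 normalize = isTRUE(normalize), encode_fun = encode_fun),
            class = "encoder_spec")
}

# Deterministic 32-bit polynomial hash of a string (platform-independent),
# used to seed per-token RNG draws.
hash_string <- function(s) {
  codes <- utf8ToInt(s)
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

token_vector <- function(token, dim, seed, cache = NULL) {
  key <- token
  if (!is.null(cache)) {
    v <- cache[[key]]
    if (!is.null(v)) return(v)
  }
  h <- (hash_string(token) + 7919 * (seed %% 262139)) %% 2147483647
  v <- withr::with_seed(as.integer(h), stats::rnorm(dim))
  v <- v / sqrt(sum(v^2))
  if (!is.null(cache)) cache[[key]] <- v
  v
}

#' Deterministically embed one text
#'
#' The embedding is the L2-normalized sum of per-token unit vectors, where
#' each token's vector is drawn from a RNG seeded by a hash of
#' (token, seed). Identical texts therefore always map to identical vectors,
#' and texts with larger token overlap have larger expected cosine
#' similarity.
#'
#' @param text Non-empty string (whitespace-tokenized).
#' @param dim Embedding dimension.
#' @param seed Integer seed.
#' @param cache Optional environment memoizing token vectors across calls.
#' @return Numeric vector of length `dim` with unit L2 norm.
#' @export
deterministic_embed <- function(text, dim = 768L, seed = 0L, cache = NULL) {
  tokens <- strsplit(trimws(text), "\\s+")[[1L]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) {
    stop("cannot embed a text with zero tokens: ", deparse(text))
  }
  v <- numeric(dim)
  for (tok in tokens) v <- v + token_vector(tok, dim, seed, cache)
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-12) v else v / nrm  # opposite-token cancellation is measure-zero
}

#' Encode a list of sentences
#'
#' Order-preserving: row i of the result encodes `texts[i]`.
#'
#' @param texts Character vector of non-empty texts.
#' @param spec An [encoder_spec()].
#' @return Numeric matrix (length(texts) x spec$dim); unit row norms when
#'   `spec$normalize`.
#' @export
encode_sentences <- function(texts, spec = encoder_spec()) {
  stopifnot(inherits(spec, "encoder_spec"), length(texts) > 0L)
  if (any(!nzchar(trimws(texts)))) stop("encode_sentences: empty text in input")
  if (spec$backend == "transformer") {
    if (is.null(spec$encode_fun)) {
      stop("transformer backend requires a user-supplied `encode_fun` ",
           "(model download / inference is not performed by this package); ",
           "use backend = \"deterministic\" for offline work")
    }
    emb <- spec$encode_fun(texts)
    emb <- matrix(as.numeric(emb), nrow = length(texts))
  } else {
    cache <- new.env(parent = emptyenv())
    emb <- t(vapply(texts, deterministic_embed, numeric(spec$dim),
                    dim = spec$dim, seed = spec$seed, cache = cache,
                    USE.NAMES = FALSE))
  }
  if (spec$normalize) {
    nrm <- sqrt(rowSums(emb^2))
    nrm[nrm < 1e-12] <- 1
    emb <- emb / nrm
  }
  if (any(!is.finite(emb))) stop("non-finite entries in embeddings")
  emb
}

#' Cosine similarity between the rows of two matrices
#'
#' @param a,b Numeric matrices with the same number of columns; `b` defaults
#'   to `a`.
#' @return Matrix of cosines, `nrow(a)` x `nrow(b)`.
#' @export
cosine_matrix <- function(a, b = a) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) stop("embedding dimension mismatch: ", ncol(a), " vs ", ncol(b))
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  na[na < 1e-12] <- 1; nb[nb < 1e-12] <- 1
  sim <- tcrossprod(a / na, b / nb)
  pmin(pmax(sim, -1), 1)
}
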