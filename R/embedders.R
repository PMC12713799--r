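#' Sentence embedders
#'
#' The semantic measures in this package are averages of cosine
#' similarities between sentence embeddings and are agnostic to which
#' embedding model produces the vectors.  An embedder is a small object
#' with a `name`, a declared `dimension`, and an `embed(sentences)`
#' function returning one fixed-dimension numeric vector per sentence;
#' identical strings must yield identical vectors.
#'
#' Two constructors ship with the package:
#' * [hash_embedder()] — the default deterministic backend: sentences are
#'   lowercased, tokenized on non-alphanumeric boundaries, and each token
#'   is hashed to one of `dim` buckets; the embedding is the vector of
#'   bucket counts.  It is fully offline, bit-reproducible across
#'   platforms, and non-negative (so cosines lie in `[0, 1]`).
#' * [custom_embedder()] — wraps any user-supplied embedding function,
#'   e.g. a 512-dimensional transformer sentence encoder served through
#'   an external runtime.
#'
#' @name embedders
NULL

.hash_token <- function(token, dim, seed) {
  # polynomial rolling hash in exact double arithmetic (< 2^53 throughout)
  h <- seed
  for (b in utf8ToInt(token)) h <- (h * 31 + b) %% 2147483647
  (h %% dim) + 1L
}

.tokenize <- function(sentence) {
  toks <- strsplit(tolower(sentence), "[^[:alnum:]]+")[[1]]
  toks[nzchar(toks)]
}

#' @rdname embedders
#' @param dim embedding dimension (number of hash buckets).
#' @param seed fixed hash seed; changing it yields an unrelated embedding
#'   basis.
#' @return an object of class `dc_embedder`.
#' @export
hash_embedder <- function(dim = 512L, seed = 17L) {
  dim <- as.integer(dim)
  stopifnot(dim >= 2L)
  embed_one <- function(s) {
    v <- numeric(dim)
    for (tok in .tokenize(s)) {
      i <- .hash_token(tok, dim, seed)
      v[i] <- v[i] + 1
    }
    v
  }
  structure(list(name = sprintf("hash-%d", dim), dimension = dim,
                 embed = function(sentences) {
                   t(vapply(as.character(sentences), embed_one, numeric(dim),
                            USE.NAMES = FALSE))
                 }),
            class = "dc_embedder")
}

#' @rdname embedders
#' @param name backend name.
#' @param dimension declared embedding dimension.
#' @param fun function mapping a character vector of sentences to a
#'   numeric matrix with one row per sentence and `dimension` columns.
#' @export
custom_embedder <- function(name, dimension, fun) {
  stopifnot(is.function(fun), dimension >= 1)
  structure(list(name = name, dimension = as.integer(dimension),
                 embed = function(sentences) {
                   m <- fun(as.character(sentences))
                   m <- matrix(as.numeric(m), nrow = length(sentences))
                   if (ncol(m) != dimension) {
                     stop("embedder '", name, "' returned dimension ", ncol(m),
                          ", declared ", dimension)
                   }
                   if (!all(is.finite(m))) stop("embedding has non-finite components")
                   m
                 }),
            class = "dc_embedder")
}

#' @export
print.dc_embedder <- function(x, ...) {
  cat("sentence embedder:", x$name, "(dimension", x$dimension, ")\n")
  invisible(x)
}

#' Embed a set of sentences
#'
#' @param embedder a `dc_embedder`.
#' @param sentences character vector.
#' @return numeric matrix, one row per sentence.
#' @export
embed_sentences <- function(embedder, sentences) {
  stopifnot(inherits(embedder, "dc_embedder"))
  if (length(sentences) == 0L) {
    return(matrix(numeric(0), nrow = 0, ncol = embedder$dimension))
  }
  embedder$embed(sentences)
}

#' Cosine similarity between two embedding vectors
#'
#' @param u,v numeric vectors of equal length; neither may be all-zero
#'   (a zero vector signals a degenerate embedding).
#' @return `dot(u, v) / (|u| |v|)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal dimension")
  if (!all(is.finite(u)) || !all(is.finite(v))) stop("non-finite components")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for a zero vector")
  max(-1, min(1, sum(u * v) / (nu * nv)))
}
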