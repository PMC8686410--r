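## Token-feature providers.
##
## The tagger is agnostic to where per-character token vectors come from: the
## default provider is a trainable character-lookup table; a contextual
## adapter slot accepts any external system (e.g. a fine-tuned transformer)
## producing per-character vectors of a declared width. Swapping providers
## changes vector content only, never sequence lengths or downstream shapes.

UNK <- "<UNK>"

#' Create a token-embedding provider
#'
#' @param kind `"trainable_lookup"` (default): a character-lookup table with
#'   an `<UNK>` row, trainable during tagger training. `"contextual_adapter"`:
#'   wraps an external function producing contextual per-character vectors.
#' @param dim Output vector width (default 64 for the lookup provider).
#' @param vocabulary Character vector of known characters
#'   (`trainable_lookup` only); an `<UNK>` row is always added.
#' @param seed Integer seed for reproducible initialization.
#' @param backend For `contextual_adapter`: a function taking a character
#'   vector and returning a numeric matrix with one row per character and
#'   `dim` columns. Leave `NULL` if no backend is attached.
#' @return An `embedding_provider` object.
#' @export
embedding_provider <- function(kind = c("trainable_lookup", "contextual_adapter"),
                               dim = 64L, vocabulary = character(0), seed = 1L,
                               backend = NULL) {
  kind <- match.arg(kind)
  stopifnot(dim >= 1L)
  p <- list(kind = kind, dim = as.integer(dim), seed = as.integer(seed))
  if (kind == "trainable_lookup") {
    vocab <- unique(c(vocabulary, UNK))
    p$vocab <- stats::setNames(seq_along(vocab), vocab)
    p$vectors <- with_local_seed(seed, {
      matrix(stats::runif(length(vocab) * dim, -0.5 / dim, 0.5 / dim),
             nrow = length(vocab), ncol = dim)
    })
  } else {
    p$backend <- backend
  }
  structure(p, class = "embedding_provider")
}

#' @export
print.embedding_provider <- function(x, ...) {
  cat(sprintf("<embedding_provider %s> dim=%d%s\n", x$kind, x$dim,
              if (x$kind == "trainable_lookup")
                sprintf(", vocab=%d", length(x$vocab)) else ""))
  invisible(x)
}

#' Build a provider vocabulary from a corpus
#'
#' @param docs List of [ann_doc()] objects.
#' @return Sorted character vector of all characters occurring in the corpus.
#' @export
corpus_vocabulary <- function(docs) {
  sort(unique(unlist(lapply(docs, function(d) chars_of(d$text)))))
}

token_rows <- function(chars, provider) {
  i <- provider$vocab[chars]
  i[is.na(i)] <- provider$vocab[[UNK]]
  unname(i)
}

#' Embed the real characters of a model sequence
#'
#' Returns one vector per mask-true position; `[CLS]`/`[SEP]`/`[PAD]` control
#' tokens are excluded and never reach the encoder.
#'
#' @param seq A [to_model_sequence()] object.
#' @param provider An [embedding_provider()].
#' @return Numeric matrix, one row per real character, `provider$dim` columns.
#' @export
embed_tokens <- function(seq, provider) {
  stopifnot(inherits(seq, "model_seq"), inherits(provider, "embedding_provider"))
  chars <- seq$tokens[seq$mask]
  if (provider$kind == "trainable_lookup") {
    m <- provider$vectors[token_rows(chars, provider), , drop = FALSE]
    rownames(m) <- NULL
    return(m)
  }
  if (is.null(provider$backend)) {
    stop("contextual_adapter has no backend attached; use a trainable_lookup ",
         "provider (embedding_provider(\"trainable_lookup\")) or supply ",
         "`backend = <function(chars) matrix>`")
  }
  m <- provider$backend(chars)
  if (!is.matrix(m) || nrow(m) != length(chars) || ncol(m) != provider$dim) {
    stop("contextual_adapter backend returned wrong shape: expected ",
         length(chars), " x ", provider$dim)
  }
  m
}

#' Concatenate token and radical feature vectors position-wise
#'
#' The model input x = [token vector, radical vector], token part first.
#'
#' @param token_vecs Numeric matrix (positions x token width).
#' @param radical_vecs Numeric matrix (positions x radical width).
#' @return Numeric matrix of width `ncol(token_vecs) + ncol(radical_vecs)`.
#' @export
concat_features <- function(token_vecs, radical_vecs) {
  if (nrow(token_vecs) != nrow(radical_vecs)) {
    stop("length mismatch: ", nrow(token_vecs), " token vectors vs ",
         nrow(radical_vecs), " radical vectors")
  }
  cbind(token_vecs, radical_vecs)
}
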