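## Length-limited splitting and model-ready sequences with control tokens.

CLS <- "[CLS]"
SEP <- "[SEP]"
PAD <- "[PAD]"

#' Split a long document into fragments below a length limit
#'
#' Documents longer than `max_content_len` are split into consecutive
#' fragments whose texts concatenate back to the original. Split points
#' prefer the last Chinese sentence-final punctuation mark
#' (\ifelse{latex}{sentence enders}{。？！；}) inside the window; otherwise
#' the fragment is hard-cut at the limit. A split point is always moved left
#' so that no entity span is bisected; every entity therefore appears intact
#' in exactly one fragment, with its offsets shifted.
#'
#' @param doc An [ann_doc()].
#' @param max_content_len Maximum fragment length in characters (>= 2).
#' @return List of [ann_doc()] fragments. Each fragment carries an
#'   `origin_offset` attribute: the 0-based offset of its first character in
#'   the original text. Fragment ids are `doc_id` for an unsplit document and
#'   `doc_id/1`, `doc_id/2`, ... otherwise.
#' @export
split_long <- function(doc, max_content_len = 510L) {
  stopifnot(inherits(doc, "ann_doc"), max_content_len >= 2L)
  e <- doc$entities
  if (nrow(e) > 0 && any(e$end - e$start > max_content_len)) {
    stop("entity longer than max_content_len (", max_content_len,
         ") in document '", doc$doc_id, "'")
  }
  n <- nchar(doc$text)
  if (n <= max_content_len) {
    frag <- doc
    attr(frag, "origin_offset") <- 0L
    return(list(frag))
  }
  ch <- chars_of(doc$text)
  enders <- c("。", "？", "！", "；")  # 。？！；
  cuts <- integer(0)  # 0-based positions where a new fragment starts
  pos <- 0L
  while (n - pos > max_content_len) {
    hi <- pos + max_content_len
    window <- ch[(pos + 1L):hi]
    punct <- which(window %in% enders)
    s <- if (length(punct) > 0) pos + punct[length(punct)] else hi
    # move left out of any bisected entity
    repeat {
      inside <- which(e$start < s & s < e$end)
      if (length(inside) == 0) break
      s <- min(e$start[inside])
    }
    if (s <= pos) {
      # punctuation-based cut collapsed onto the previous cut; fall back to a
      # hard cut at the limit, again respecting entity boundaries
      s <- hi
      repeat {
        inside <- which(e$start < s & s < e$end)
        if (length(inside) == 0) break
        s <- min(e$start[inside])
      }
      if (s <= pos) stop("cannot split document '", doc$doc_id,
                         "' without bisecting an entity")
    }
    cuts <- c(cuts, s)
    pos <- s
  }
  starts <- c(0L, cuts)
  ends <- c(cuts, n)
  lapply(seq_along(starts), function(k) {
    s <- starts[k]; t <- ends[k]
    keep <- e$start >= s & e$end <= t
    frag <- ann_doc(paste0(doc$doc_id, "/", k),
                    paste(ch[(s + 1L):t], collapse = ""),
                    entity_spans(e$etype[keep], e$start[keep] - s, e$end[keep] - s))
    attr(frag, "origin_offset") <- s
    frag
  })
}

#' Wrap a fragment in control tokens and pad to a fixed length
#'
#' Produces the model input representation: `[CLS]`, the characters, `[SEP]`,
#' then `[PAD]` up to `max_len`. The mask is `TRUE` exactly on the real
#' character positions.
#'
#' @param fragment An [ann_doc()] with at most `max_len - 2` characters.
#' @param max_len Total sequence length including control tokens (default 512).
#' @return A `model_seq` object: list with `tokens` (length `max_len`
#'   character vector), `mask` (logical), and `origin` (`doc_id` plus the
#'   0-based offset of the first real character in the source document).
#' @export
to_model_sequence <- function(fragment, max_len = 512L) {
  stopifnot(inherits(fragment, "ann_doc"))
  n <- nchar(fragment$text)
  if (n == 0L) stop("empty fragment cannot be encoded")
  if (n > max_len - 2L) {
    stop("fragment of length ", n, " exceeds max_len - 2 = ", max_len - 2L,
         "; split it first with split_long()")
  }
  off <- attr(fragment, "origin_offset")
  tokens <- c(CLS, chars_of(fragment$text), SEP, rep(PAD, max_len - n - 2L))
  mask <- c(FALSE, rep(TRUE, n), rep(FALSE, max_len - n - 1L))
  structure(list(tokens = tokens, mask = mask,
                 origin = list(doc_id = fragment$doc_id,
                               offset = if (is.null(off)) 0L else off)),
            class = "model_seq")
}
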