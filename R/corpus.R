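#' @keywords internal
"_PACKAGE"

## Closed entity-type vocabulary and the BIO tag alphabet built from it.
## Tag order matters: "O" first, then B-/I- per type, so that the Viterbi
## tie-break toward the lowest index prefers "O".

#' Entity types recognised by the package
#'
#' The three span types annotated in Chinese adverse drug event narratives:
#' `Reason` (the disease, symptom, or treatment motivating drug use), `Drug`
#' (generic name, trade name, or abbreviation such as "10% GS"), and `ADR`
#' (the adverse reaction itself).
#'
#' @return Character vector of the three entity type names.
#' @export
entity_types <- function() c("Reason", "Drug", "ADR")

#' The BIO tag alphabet
#'
#' `O` plus `B-`/`I-` tags for each entity type, in the fixed order used by
#' the CRF layer (`O` has index 1, so score ties resolve toward `O`).
#'
#' @return Character vector of 7 tags.
#' @export
bio_tags <- function() {
  types <- entity_types()
  c("O", as.vector(rbind(paste0("B-", types), paste0("I-", types))))
}

#' Split a string into single characters
#'
#' @param text A length-1 character string (UTF-8).
#' @return Character vector with one element per Unicode character.
#' @export
chars_of <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (nchar(text) == 0L) return(character(0))
  strsplit(text, "", fixed = FALSE)[[1]]
}

#' Construct an entity span table
#'
#' Spans use 0-based, half-open `[start, end)` character offsets.
#'
#' @param etype Character vector of entity types (see [entity_types()]).
#' @param start Integer vector of 0-based inclusive start offsets.
#' @param end Integer vector of exclusive end offsets.
#' @return A `data.frame` with columns `etype`, `start`, `end`.
#' @export
entity_spans <- function(etype = character(0), start = integer(0), end = integer(0)) {
  stopifnot(length(etype) == length(start), length(start) == length(end))
  bad <- setdiff(unique(etype), entity_types())
  if (length(bad) > 0) {
    stop("unknown entity type(s): ", paste(bad, collapse = ", "))
  }
  data.frame(etype = as.character(etype), start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

#' Construct an annotated document
#'
#' An annotated document pairs a character sequence with a set of typed,
#' non-overlapping entity spans (gold or predicted).
#'
#' @param doc_id Opaque document identifier.
#' @param text The narrative text, a length-1 UTF-8 string.
#' @param entities An entity span table from [entity_spans()], or a
#'   data.frame with columns `etype`, `start`, `end`.
#' @return An object of class `ann_doc`.
#' @examples
#' ann_doc("r1", "患者头痛", entity_spans("ADR", 2, 4))
#' @export
ann_doc <- function(doc_id, text, entities = entity_spans()) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L)
  stopifnot(is.character(text), length(text) == 1L)
  entities <- entity_spans(entities$etype, entities$start, entities$end)
  doc <- structure(list(doc_id = doc_id, text = text, entities = entities),
                   class = "ann_doc")
  validate_ann_doc(doc)
  doc
}

#' @export
print.ann_doc <- function(x, ...) {
  cat(sprintf("<ann_doc '%s'> %d chars, %d entities\n",
              x$doc_id, nchar(x$text), nrow(x$entities)))
  if (nrow(x$entities) > 0) {
    ch <- chars_of(x$text)
    surf <- vapply(seq_len(nrow(x$entities)), function(i) {
      paste(ch[(x$entities$start[i] + 1):x$entities$end[i]], collapse = "")
    }, character(1))
    cat(sprintf("  %s [%d,%d) %s\n", x$entities$etype,
                x$entities$start, x$entities$end, surf), sep = "")
  }
  invisible(x)
}

validate_ann_doc <- function(doc) {
  n <- nchar(doc$text)
  e <- doc$entities
  if (nrow(e) == 0) return(invisible(doc))
  if (any(e$start < 0 | e$start >= e$end | e$end > n)) {
    stop("entity span out of bounds in document '", doc$doc_id,
         "' (need 0 <= start < end <= ", n, ")")
  }
  e <- e[order(e$start), , drop = FALSE]
  if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
    stop("overlapping entity spans in document '", doc$doc_id, "'")
  }
  invisible(doc)
}

#' Encode entity spans as a BIO tag sequence
#'
#' Each span of type `T` contributes `B-T` at its first character and `I-T`
#' over the rest; every other position is `O`.
#'
#' @param doc An [ann_doc()].
#' @return Character vector of tags, one per character of `doc$text`.
#' @examples
#' spans_to_tags(ann_doc("d", "abcde", entity_spans("Drug", 1, 3)))
#' @export
spans_to_tags <- function(doc) {
  stopifnot(inherits(doc, "ann_doc"))
  validate_ann_doc(doc)
  tags <- rep("O", nchar(doc$text))
  e <- doc$entities
  for (i in seq_len(nrow(e))) {
    tags[e$start[i] + 1L] <- paste0("B-", e$etype[i])
    if (e$end[i] - e$start[i] > 1L) {
      tags[(e$start[i] + 2L):e$end[i]] <- paste0("I-", e$etype[i])
    }
  }
  tags
}

#' Decode a BIO tag sequence into entity spans
#'
#' Total function: ill-formed sequences are repaired by the conlleval
#' convention that a stray `I-T` (not preceded by `B-T` or `I-T` of the same
#' type) starts a new entity of type `T`. On well-formed input this is the
#' exact inverse of [spans_to_tags()].
#'
#' @param tags Character vector over the alphabet of [bio_tags()].
#' @return An entity span table (see [entity_spans()]).
#' @examples
#' tags_to_spans(c("O", "B-Drug", "I-Drug", "O", "O"))
#' tags_to_spans(c("I-ADR", "I-ADR"))  # repaired to one ADR span
#' @export
tags_to_spans <- function(tags) {
  bad <- setdiff(unique(tags), bio_tags())
  if (length(bad) > 0) stop("unknown tag label(s): ", paste(bad, collapse = ", "))
  etype <- character(0); start <- integer(0); end <- integer(0)
  cur_type <- NA_character_; cur_start <- NA_integer_
  flush <- function(pos) {
    if (!is.na(cur_type)) {
      etype <<- c(etype, cur_type); start <<- c(start, cur_start); end <<- c(end, pos)
    }
    cur_type <<- NA_character_
  }
  for (i in seq_along(tags)) {
    t <- tags[i]
    if (t == "O") {
      flush(i - 1L)
    } else {
      kind <- substr(t, 1, 1)
      ty <- substring(t, 3)
      if (kind == "B" || is.na(cur_type) || cur_type != ty) {
        flush(i - 1L)
        cur_type <- ty; cur_start <- i - 1L
      }
    }
  }
  flush(length(tags))
  entity_spans(etype, start, end)
}

#' Rebuild an annotated document from text and tags
#'
#' @param doc_id Document identifier.
#' @param chars Character vector (one element per character).
#' @param tags BIO tag vector of the same length.
#' @return An [ann_doc()].
#' @export
doc_from_tags <- function(doc_id, chars, tags) {
  stopifnot(length(chars) == length(tags))
  ann_doc(doc_id, paste(chars, collapse = ""), tags_to_spans(tags))
}

#' Extract the surface text of each entity in a document
#'
#' @param doc An [ann_doc()].
#' @return Character vector of entity surface strings, parallel to
#'   `doc$entities` rows.
#' @export
entity_text <- function(doc) {
  ch <- chars_of(doc$text)
  vapply(seq_len(nrow(doc$entities)), function(i) {
    paste(ch[(doc$entities$start[i] + 1):doc$entities$end[i]], collapse = "")
  }, character(1))
}
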