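## CoNLL-style two-column BIO corpus files.
## Dialect: UTF-8, one "char<TAB>tag" per line, blank line between sequences,
## optional "# doc_id" comment line before a sequence.

#' Read a two-column BIO corpus file
#'
#' @param path Path to a UTF-8 file with one `char<TAB>tag` pair per line and
#'   a blank line between sequences. A `# doc_id` comment line may precede
#'   each sequence.
#' @return A list of [ann_doc()] objects. Documents without a `#` comment get
#'   ids `"seq1"`, `"seq2"`, ...
#' @export
read_bio <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  alphabet <- bio_tags()
  docs <- list()
  chars <- character(0); tags <- character(0); cur_id <- NULL
  flush <- function(lineno) {
    if (length(chars) == 0) return()
    id <- if (is.null(cur_id)) paste0("seq", length(docs) + 1L) else cur_id
    docs[[length(docs) + 1L]] <<- doc_from_tags(id, chars, tags)
    chars <<- character(0); tags <<- character(0); cur_id <<- NULL
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (line == "") {
      flush(i)
    } else if (startsWith(line, "# ")) {
      if (length(chars) > 0) {
        stop("line ", i, ": comment line inside a sequence")
      }
      cur_id <- substring(line, 3)
    } else {
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(parts) != 2L || nchar(parts[1]) != 1L) {
        stop("line ", i, ": malformed line (expected 'char<TAB>tag'): ",
             utils::head(line, 1))
      }
      if (!(parts[2] %in% alphabet)) {
        stop("line ", i, ": unknown tag label '", parts[2], "'")
      }
      chars <- c(chars, parts[1]); tags <- c(tags, parts[2])
    }
  }
  flush(length(lines) + 1L)
  docs
}

#' Write documents as a two-column BIO corpus file
#'
#' Inverse of [read_bio()]: the round-trip through a file is exact, including
#' document ids (written as `# doc_id` comment lines).
#'
#' @param docs List of [ann_doc()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bio <- function(docs, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (doc in docs) {
    stopifnot(inherits(doc, "ann_doc"))
    writeLines(paste0("# ", doc$doc_id), con)
    writeLines(paste0(chars_of(doc$text), "\t", spans_to_tags(doc)), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read plain-text documents for prediction
#'
#' @param path UTF-8 file with one document per line.
#' @return Character vector of document texts (empty lines dropped).
#' @export
read_texts <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines[nzchar(lines)]
}
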