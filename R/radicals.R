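## Kangxi radical lookup and the radical embedding table.
##
## Radical identity is the canonical Kangxi radical number (1-214), never the
## glyph, so variant surface forms (e.g. the three-dot water 氵 in 液) collapse
## onto their canonical radical (水, 85). Identifier 0 is the "no radical"
## sentinel used for non-CJK characters and control tokens.

N_RADICALS <- 214L

#' Build a radical index from a character-to-radical table
#'
#' @param table_file Path to a UTF-8 TSV with header `character`,
#'   `kangxi_index` mapping single characters to Kangxi radical numbers
#'   (1-214). Defaults to the curated table shipped with the package, which
#'   covers the characters of the synthetic corpus and common clinical
#'   Chinese.
#' @return A `radical_index` object supporting [radical_of()].
#' @export
build_radical_index <- function(table_file = system.file("extdata", "kangxi_radicals.tsv",
                                                         package = "radner")) {
  lines <- readLines(table_file, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 1L || lines[1] != "character\tkangxi_index") {
    stop("radical table must start with header 'character<TAB>kangxi_index'")
  }
  tab <- integer(0)
  for (i in seq_along(lines)[-1]) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    idx <- suppressWarnings(as.integer(parts[2]))
    if (length(parts) != 2L || nchar(parts[1]) != 1L || is.na(idx)) {
      stop("radical table row ", i, ": malformed line")
    }
    if (idx < 1L || idx > N_RADICALS) {
      stop("radical table row ", i, ": kangxi_index ", idx, " outside 1-214")
    }
    tab[parts[1]] <- idx
  }
  env <- new.env(parent = emptyenv())
  env$table <- tab
  env$warned <- FALSE
  structure(env, class = "radical_index")
}

#' @export
print.radical_index <- function(x, ...) {
  cat(sprintf("<radical_index> %d characters mapped to %d distinct radicals\n",
              length(x$table), length(unique(x$table))))
  invisible(x)
}

is_cjk <- function(ch) {
  cp <- utf8ToInt(ch)
  !is.na(cp) && cp >= 0x4E00 && cp <= 0x9FFF
}

#' Look up the canonical Kangxi radical of a character
#'
#' Total function: non-CJK characters (Latin letters, digits, punctuation,
#' control tokens) return the sentinel 0, as do CJK characters absent from
#' the index (reported with a single message per index).
#'
#' @param ch A single character.
#' @param index A [build_radical_index()] object.
#' @return Integer radical identifier in 0-214.
#' @examples
#' idx <- build_radical_index()
#' radical_of("痛", idx)  # 痛 -> 104 (疒)
#' radical_of("A", idx)       # -> 0
#' @export
radical_of <- function(ch, index) {
  stopifnot(inherits(index, "radical_index"), nchar(ch) == 1L)
  r <- index$table[ch]
  if (!is.na(r)) return(unname(r))
  if (is_cjk(ch) && !index$warned) {
    message("radical_of: CJK character(s) without a radical entry (e.g. '",
            ch, "') map to sentinel 0")
    index$warned <- TRUE
  }
  0L
}

#' Map a character sequence to radical identifiers
#'
#' Vectorised [radical_of()].
#'
#' @param chars Character vector of single characters.
#' @param index A [build_radical_index()] object.
#' @return Integer vector of radical identifiers in 0-214.
#' @export
radicals_of <- function(chars, index) {
  vapply(chars, radical_of, integer(1), index = index, USE.NAMES = FALSE)
}

#' Create a radical embedding table
#'
#' One trainable vector per radical identifier 0-214 (215 rows), initialized
#' uniformly on `[-0.5/dim, +0.5/dim]`; reproducible given `seed`.
#'
#' @param dim Embedding width (default 20).
#' @param seed Integer seed controlling initialization.
#' @return A numeric matrix with 215 rows named `"0"`..`"214"`.
#' @export
radical_embedding_table <- function(dim = 20L, seed = 1L) {
  stopifnot(dim >= 1L)
  vecs <- with_local_seed(seed, {
    matrix(stats::runif((N_RADICALS + 1L) * dim, -0.5 / dim, 0.5 / dim),
           nrow = N_RADICALS + 1L, ncol = dim)
  })
  rownames(vecs) <- as.character(0:N_RADICALS)
  vecs
}

#' Embed a character sequence through its radicals
#'
#' @param chars Character vector of single characters (control tokens and
#'   non-CJK characters pass through the sentinel row 0).
#' @param index A [build_radical_index()] object.
#' @param table A [radical_embedding_table()] matrix.
#' @return Numeric matrix, one row per input character, `ncol(table)` columns.
#' @export
embed_radicals <- function(chars, index, table) {
  ids <- radicals_of(chars, index)
  m <- table[ids + 1L, , drop = FALSE]
  rownames(m) <- NULL
  m
}

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
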