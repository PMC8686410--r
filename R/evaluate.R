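## Strict-boundary entity-level scoring: a predicted span counts as a true
## positive only if its (type, start, end) triple exactly matches a gold
## span of the same document. Micro metrics pool TP/FP/FN counts over all
## entity types before computing P/R/F1.
##
## Zero-denominator convention: precision (or recall) over an empty
## prediction (or gold) set is 0, and F1 is 0 when P + R = 0.

prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  list(tp = tp, fp = fp, fn = fn, precision = p, recall = r,
       f1 = f1_score(p, r))
}

#' Harmonic mean of precision and recall
#'
#' `F1 = 2PR / (P + R)`, on the same scale as its inputs (fractions in, a
#' fraction out; percentages in, a percentage out). Defined as 0 when both
#' inputs are 0.
#'
#' @param p,r Precision and recall, both non-negative.
#' @return The F1 score.
#' @examples
#' f1_score(96.4, 96.0)  # 96.199...
#' @export
f1_score <- function(p, r) {
  stopifnot(p >= 0, r >= 0)
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

span_keys <- function(doc) {
  e <- doc$entities
  if (nrow(e) == 0) return(character(0))
  paste(e$etype, e$start, e$end, sep = ":")
}

#' Strict-match entity-level scoring
#'
#' @param gold,pred Lists of [ann_doc()]; paired by `doc_id`, which must
#'   cover the same set of ids.
#' @return An `eval_report`: list with `per_type` (one [prf] record per
#'   entity type) and `micro` (pooled counts).
#' @export
strict_match_score <- function(gold, pred) {
  gids <- vapply(gold, `[[`, "", "doc_id")
  pids <- vapply(pred, `[[`, "", "doc_id")
  if (anyDuplicated(gids) || anyDuplicated(pids)) {
    stop("duplicate doc_ids in gold or predictions")
  }
  if (!setequal(gids, pids)) {
    stop("gold and prediction doc_ids do not match (",
         length(setdiff(gids, pids)), " missing, ",
         length(setdiff(pids, gids)), " extra)")
  }
  pred <- pred[match(gids, pids)]
  types <- entity_types()
  tp <- fp <- fn <- stats::setNames(numeric(length(types)), types)
  for (i in seq_along(gold)) {
    gk <- span_keys(gold[[i]])
    pk <- span_keys(pred[[i]])
    for (ty in types) {
      g <- gk[startsWith(gk, paste0(ty, ":"))]
      p <- pk[startsWith(pk, paste0(ty, ":"))]
      hit <- sum(p %in% g)
      tp[ty] <- tp[ty] + hit
      fp[ty] <- fp[ty] + length(p) - hit
      fn[ty] <- fn[ty] + length(g) - hit
    }
  }
  per_type <- lapply(stats::setNames(types, types),
                     function(ty) prf(tp[[ty]], fp[[ty]], fn[[ty]]))
  structure(list(per_type = per_type, micro = prf(sum(tp), sum(fp), sum(fn))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  fmt <- function(nm, m) {
    sprintf("  %-7s P %5.1f%%  R %5.1f%%  F1 %5.1f%%  (TP %d FP %d FN %d)\n",
            nm, 100 * m$precision, 100 * m$recall, 100 * m$f1,
            m$tp, m$fp, m$fn)
  }
  cat("<eval_report> strict matching\n")
  for (ty in names(x$per_type)) cat(fmt(ty, x$per_type[[ty]]))
  cat(fmt("micro", x$micro))
  invisible(x)
}

#' Flatten an evaluation report to a data frame
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A data.frame with one row per entity type plus a `micro` row.
#' @export
as.data.frame.eval_report <- function(x, ...) {
  rows <- c(x$per_type, list(micro = x$micro))
  data.frame(type = names(rows),
             tp = vapply(rows, `[[`, 0, "tp"),
             fp = vapply(rows, `[[`, 0, "fp"),
             fn = vapply(rows, `[[`, 0, "fn"),
             precision = vapply(rows, `[[`, 0, "precision"),
             recall = vapply(rows, `[[`, 0, "recall"),
             f1 = vapply(rows, `[[`, 0, "f1"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate repeated evaluation runs
#'
#' Mean and sample standard deviation (n - 1 denominator) of every metric
#' over n >= 2 runs, with a `"mean (SD)"` formatter for tabulation.
#'
#' @param reports List of at least two `eval_report` objects with identical
#'   type sets.
#' @return A `run_aggregate`: data.frame with columns `type`, `metric`,
#'   `mean`, `sd`, `formatted`.
#' @export
aggregate_runs <- function(reports) {
  if (length(reports) < 2) stop("need at least 2 reports to aggregate")
  dfs <- lapply(reports, as.data.frame)
  types <- dfs[[1]]$type
  if (!all(vapply(dfs, function(d) identical(d$type, types), TRUE))) {
    stop("reports have differing type sets")
  }
  out <- expand.grid(type = types, metric = c("precision", "recall", "f1"),
                     stringsAsFactors = FALSE)
  vals <- mapply(function(ty, me) {
    sapply(dfs, function(d) d[d$type == ty, me])
  }, out$type, out$metric, SIMPLIFY = FALSE)
  out$mean <- vapply(vals, mean, 0)
  out$sd <- vapply(vals, stats::sd, 0)
  out$formatted <- sprintf("%.1f (%.2f)", 100 * out$mean, 100 * out$sd)
  class(out) <- c("run_aggregate", "data.frame")
  out
}

#' Man-machine comparison of candidate annotation sets
#'
#' Scores several candidate annotation sets (e.g. model predictions and
#' manual extractions) against the same gold standard with the same strict
#' metric, side by side, and lists per-document disagreements.
#'
#' @param gold List of gold [ann_doc()].
#' @param candidates Named list; each element a list of [ann_doc()] covering
#'   the gold ids.
#' @return A `comparison_table`: data.frame with one row per candidate and
#'   type (plus micro); attribute `disagreements` holds, per candidate, a
#'   data.frame of spans missed (`fn`) or spuriously produced (`fp`) per
#'   document.
#' @export
compare_candidates <- function(gold, candidates) {
  stopifnot(length(candidates) >= 1, !is.null(names(candidates)),
            all(nzchar(names(candidates))))
  rows <- list()
  disagreements <- list()
  for (nm in names(candidates)) {
    rep_ <- strict_match_score(gold, candidates[[nm]])
    d <- as.data.frame(rep_)
    d <- cbind(candidate = nm, d, stringsAsFactors = FALSE)
    rows[[nm]] <- d
    disagreements[[nm]] <- candidate_disagreements(gold, candidates[[nm]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "disagreements") <- disagreements
  class(out) <- c("comparison_table", "data.frame")
  out
}

candidate_disagreements <- function(gold, pred) {
  gids <- vapply(gold, `[[`, "", "doc_id")
  pred <- pred[match(gids, vapply(pred, `[[`, "", "doc_id"))]
  recs <- list()
  for (i in seq_along(gold)) {
    gk <- span_keys(gold[[i]]); pk <- span_keys(pred[[i]])
    miss <- setdiff(gk, pk); spur <- setdiff(pk, gk)
    if (length(miss) + length(spur) == 0) next
    recs[[length(recs) + 1L]] <- data.frame(
      doc_id = gids[i],
      kind = c(rep("fn", length(miss)), rep("fp", length(spur))),
      span = c(miss, spur), stringsAsFactors = FALSE)
  }
  if (length(recs) == 0) {
    data.frame(doc_id = character(0), kind = character(0), span = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, recs)
  }
}

#' Write a comparison (or evaluation) report to disk
#'
#' Emits both a human-readable text table and a machine-readable JSON file
#' (one record per candidate per type).
#'
#' @param comparison A [compare_candidates()] result.
#' @param path Output path stem; writes `<path>.txt` and `<path>.json`.
#' @return Invisibly, the two paths written.
#' @export
write_comparison <- function(comparison, path) {
  stopifnot(inherits(comparison, "comparison_table"))
  txt <- paste0(path, ".txt"); js <- paste0(path, ".json")
  df <- comparison
  class(df) <- "data.frame"
  attr(df, "disagreements") <- NULL
  con <- file(txt, "w", encoding = "UTF-8")
  sink(con); print(df, digits = 4); sink()
  close(con)
  jsonlite::write_json(
    df[, c("candidate", "type", "tp", "fp", "fn", "precision", "recall", "f1")],
    js, digits = NA)
  invisible(c(txt, js))
}
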