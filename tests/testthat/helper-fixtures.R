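# Shared fixtures for property-style tests. All randomness is locally seeded.

# A random annotated document: non-overlapping typed spans over a synthetic
# character sequence (Latin filler keeps these independent of the radical
# table and lexicons).
random_doc <- function(n_chars = 20L, n_spans = 3L, id = "doc") {
  text <- paste(sample(letters, n_chars, replace = TRUE), collapse = "")
  # draw non-overlapping spans by splitting the index range
  cuts <- sort(sample(0:n_chars, size = min(2L * n_spans, n_chars + 1L)))
  etype <- character(0); start <- integer(0); end <- integer(0)
  i <- 1L
  while (i + 1L <= length(cuts) && length(start) < n_spans) {
    if (cuts[i] < cuts[i + 1L]) {
      etype <- c(etype, sample(entity_types(), 1))
      start <- c(start, cuts[i]); end <- c(end, cuts[i + 1L])
    }
    i <- i + 2L
  }
  ann_doc(id, text, entity_spans(etype, start, end))
}

# Brute-force CRF oracle: enumerate all K^T paths.
enumerate_paths <- function(T_, K) {
  if (T_ == 1L) return(matrix(seq_len(K), ncol = 1))
  as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
}

enum_log_partition <- function(e, params) {
  paths <- enumerate_paths(nrow(e), params$K)
  scores <- apply(paths, 1, function(y) path_score(e, params, y))
  m <- max(scores)
  m + log(sum(exp(scores - m)))
}

enum_best_path <- function(e, params) {
  paths <- enumerate_paths(nrow(e), params$K)
  scores <- apply(paths, 1, function(y) path_score(e, params, y))
  list(score = max(scores), paths = paths[scores == max(scores), , drop = FALSE])
}

random_crf_instance <- function(T_, K) {
  labels <- paste0("t", seq_len(K))
  e <- matrix(rnorm(T_ * K), T_, K)
  params <- crf_params(labels,
                       transitions = matrix(rnorm(K * K), K, K),
                       start = rnorm(K), end = rnorm(K))
  list(e = e, params = params)
}
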