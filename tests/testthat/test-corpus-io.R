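test_that("spans_to_tags encodes spans per the BIO definition", {
  doc <- ann_doc("d", "abcde", entity_spans("Drug", 1, 3))
  expect_equal(spans_to_tags(doc), c("O", "B-Drug", "I-Drug", "O", "O"))

  expect_equal(spans_to_tags(ann_doc("d", "abcde")), rep("O", 5))

  doc2 <- ann_doc("d", "abcde", entity_spans(c("Reason", "ADR"), c(0, 3), c(1, 5)))
  expect_equal(spans_to_tags(doc2), c("B-Reason", "O", "O", "B-ADR", "I-ADR"))
})

test_that("annotated documents reject invalid spans", {
  expect_error(ann_doc("d", "abc", entity_spans("Drug", 1, 5)), "out of bounds")
  expect_error(ann_doc("d", "abc", entity_spans("Drug", 2, 2)), "out of bounds")
  expect_error(ann_doc("d", "abcde", entity_spans(c("Drug", "ADR"), c(0, 1), c(3, 4))),
               "overlapping")
  expect_error(entity_spans("Gene", 0, 1), "unknown entity type")
})

test_that("tags_to_spans inverts spans_to_tags and repairs stray I- tags", {
  expect_equal(tags_to_spans(c("O", "B-Drug", "I-Drug", "O", "O")),
               entity_spans("Drug", 1, 3))
  expect_equal(tags_to_spans(c("I-ADR", "I-ADR")), entity_spans("ADR", 0, 2))
  expect_equal(tags_to_spans(c("B-Drug", "I-ADR")),
               entity_spans(c("Drug", "ADR"), c(0, 1), c(1, 2)))
  expect_error(tags_to_spans(c("B-Gene")), "unknown tag")
})

test_that("span -> tag -> span round-trip is the identity (property)", {
  set.seed(42)
  for (rep in 1:50) {
    doc <- random_doc(n_chars = sample(5:40, 1), n_spans = sample(0:5, 1))
    got <- tags_to_spans(spans_to_tags(doc))
    want <- doc$entities[order(doc$entities$start), , drop = FALSE]
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("read_bio parses two-column files and validates labels", {
  path <- withr::local_tempfile(fileext = ".bio")
  writeLines(c("头\tB-ADR", "痛\tI-ADR", ""), path, useBytes = FALSE)
  docs <- read_bio(path)
  expect_length(docs, 1)
  expect_equal(nchar(docs[[1]]$text), 2)
  expect_equal(spans_to_tags(docs[[1]]), c("B-ADR", "I-ADR"))

  writeLines(character(0), path)
  expect_length(read_bio(path), 0)

  writeLines(c("头\tB-Gene", ""), path)
  expect_error(read_bio(path), "line 1.*unknown tag", perl = TRUE)

  writeLines(c("no tab here", ""), path)
  expect_error(read_bio(path), "line 1.*malformed")
})

test_that("write_bio / read_bio round-trip is exact, ids included", {
  set.seed(7)
  docs <- lapply(1:5, function(i) random_doc(n_chars = 15, n_spans = 2,
                                             id = paste0("report-", i)))
  path <- withr::local_tempfile(fileext = ".bio")
  write_bio(docs, path)
  back <- read_bio(path)
  expect_length(back, 5)
  for (i in 1:5) {
    expect_equal(back[[i]]$doc_id, docs[[i]]$doc_id)
    expect_equal(back[[i]]$text, docs[[i]]$text)
    got <- back[[i]]$entities[order(back[[i]]$entities$start), ]
    want <- docs[[i]]$entities[order(docs[[i]]$entities$start), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
  # and the file itself survives a second round-trip byte-exactly
  path2 <- withr::local_tempfile(fileext = ".bio")
  write_bio(back, path2)
  expect_identical(readLines(path2, encoding = "UTF-8"),
                   readLines(path, encoding = "UTF-8"))
})

test_that("split_long preserves text and entities with shifted offsets", {
  # no-op below the limit
  doc <- ann_doc("d", strrep("a", 100), entity_spans("Drug", 10, 15))
  frags <- split_long(doc, 512L)
  expect_length(frags, 1)
  expect_equal(frags[[1]]$text, doc$text)

  # plain split without entities
  long <- ann_doc("d", strrep("x", 600))
  frags <- split_long(long, 512L)
  expect_length(frags, 2)
  expect_equal(paste(vapply(frags, `[[`, "", "text"), collapse = ""), long$text)
  expect_true(all(vapply(frags, function(f) nchar(f$text), 1L) <= 512L))

  # split point moves left so the entity stays whole
  doc <- ann_doc("d", "abcdefgHIJ", entity_spans("Drug", 7, 10))
  frags <- split_long(doc, 8L)
  expect_equal(paste(vapply(frags, `[[`, "", "text"), collapse = ""), doc$text)
  in_frag <- vapply(frags, function(f) nrow(f$entities), 1L)
  expect_equal(sum(in_frag), 1L)
  k <- which(in_frag == 1L)
  f <- frags[[k]]
  ch <- chars_of(f$text)
  expect_equal(paste(ch[(f$entities$start + 1):f$entities$end], collapse = ""), "HIJ")

  # an entity wider than the window is rejected
  expect_error(split_long(ann_doc("d", strrep("x", 20),
                                  entity_spans("Drug", 2, 15)), 8L),
               "entity longer")
})

test_that("split_long prefers sentence-final punctuation", {
  text <- paste0(strrep("一", 5), "。", strrep("二", 6))  # 5 chars, 。, 6 chars
  doc <- ann_doc("d", text)
  frags <- split_long(doc, 8L)
  expect_equal(nchar(frags[[1]]$text), 6L)  # cut right after 。
  expect_equal(paste(vapply(frags, `[[`, "", "text"), collapse = ""), text)
})

test_that("split_long preserves the multiset of typed entity texts (property)", {
  set.seed(99)
  for (rep in 1:30) {
    doc <- random_doc(n_chars = sample(30:120, 1), n_spans = sample(1:6, 1))
    ok <- all(doc$entities$end - doc$entities$start <= 12L)
    if (!ok) next
    frags <- split_long(doc, 12L)
    orig <- sort(paste(doc$entities$etype, entity_text(doc)))
    got <- sort(unlist(lapply(frags, function(f)
      if (nrow(f$entities)) paste(f$entities$etype, entity_text(f)) else character(0))))
    expect_equal(got, orig)
    # offsets recorded on fragments reconstruct the original coordinates
    for (f in frags) {
      off <- attr(f, "origin_offset")
      for (i in seq_len(nrow(f$entities))) {
        s <- f$entities$start[i] + off; e <- f$entities$end[i] + off
        ch <- chars_of(doc$text)
        expect_equal(paste(ch[(s + 1):e], collapse = ""), entity_text(f)[i])
      }
    }
  }
})

test_that("to_model_sequence wraps fragments in control tokens", {
  doc <- ann_doc("d", "头痛")
  ms <- to_model_sequence(doc, max_len = 6L)
  expect_equal(ms$tokens, c("[CLS]", "头", "痛", "[SEP]", "[PAD]", "[PAD]"))
  expect_equal(ms$mask, c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE))

  expect_error(to_model_sequence(ann_doc("d", ""), 6L), "empty")
  expect_error(to_model_sequence(ann_doc("d", strrep("a", 10)), 6L), "split")

  # boundary: text of length max_len - 2 has zero [PAD]s
  ms2 <- to_model_sequence(ann_doc("d", "abcd"), max_len = 6L)
  expect_false(any(ms2$tokens == "[PAD]"))
  expect_equal(length(ms2$tokens), 6L)
})

test_that("model sequences always have length max_len and mask = fragment length", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(1:30, 1)
    doc <- random_doc(n_chars = n, n_spans = 0)
    ms <- to_model_sequence(doc, max_len = 32L)
    expect_length(ms$tokens, 32L)
    expect_equal(sum(ms$mask), n)
    expect_equal(ms$tokens[1], "[CLS]")
    expect_equal(sum(ms$tokens == "[SEP]"), 1L)
    sep_at <- which(ms$tokens == "[SEP]")
    if (sep_at < 32L) expect_true(all(ms$tokens[(sep_at + 1):32] == "[PAD]"))
  }
})
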