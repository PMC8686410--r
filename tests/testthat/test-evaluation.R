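mkdoc <- function(id, n, etype = character(0), start = integer(0), end = integer(0)) {
  ann_doc(id, strrep("x", n), entity_spans(etype, start, end))
}

test_that("strict matching requires exact type and boundaries", {
  gold <- list(mkdoc("a", 10, "Drug", 2, 5))
  expect_equal(strict_match_score(gold, gold)$micro$f1, 1)

  off <- list(mkdoc("a", 10, "Drug", 2, 4))  # boundary off by one
  rep_ <- strict_match_score(gold, off)
  expect_equal(rep_$micro$tp, 0)
  expect_equal(rep_$micro$fp, 1)
  expect_equal(rep_$micro$fn, 1)
  expect_equal(rep_$micro$f1, 0)

  swapped <- list(mkdoc("a", 10, "ADR", 2, 5))  # right boundaries, wrong type
  expect_equal(strict_match_score(gold, swapped)$micro$tp, 0)

  expect_error(strict_match_score(gold, list(mkdoc("b", 10))), "doc_ids")
})

test_that("pooled micro counts give the hand-computed P/R/F1", {
  # TP=3, FP=1, FN=2 spread over types and documents
  gold <- list(
    mkdoc("a", 20, c("Drug", "ADR"), c(0, 5), c(2, 8)),
    mkdoc("b", 20, c("Reason", "Drug", "ADR"), c(1, 6, 10), c(4, 8, 12)))
  pred <- list(
    mkdoc("a", 20, c("Drug", "ADR"), c(0, 5), c(2, 8)),          # 2 TP
    mkdoc("b", 20, c("Reason", "Drug"), c(1, 14), c(4, 16)))     # 1 TP, 1 FP, 2 FN
  rep_ <- strict_match_score(gold, pred)
  expect_equal(rep_$micro$tp, 3)
  expect_equal(rep_$micro$fp, 1)
  expect_equal(rep_$micro$fn, 2)
  expect_equal(rep_$micro$precision, 0.75)
  expect_equal(rep_$micro$recall, 0.60)
  expect_equal(rep_$micro$f1, 2 * 0.75 * 0.6 / 1.35)
  # micro counts are the sums of the per-type counts
  expect_equal(sum(vapply(rep_$per_type, `[[`, 0, "tp")), rep_$micro$tp)
  expect_equal(sum(vapply(rep_$per_type, `[[`, 0, "fp")), rep_$micro$fp)
  expect_equal(sum(vapply(rep_$per_type, `[[`, 0, "fn")), rep_$micro$fn)
})

test_that("scorer handles a fixture with off-by-one and type-swap errors", {
  gold <- list(
    mkdoc("d1", 15, c("Reason", "Drug"), c(0, 5), c(3, 9)),
    mkdoc("d2", 15, "ADR", 4, 7),
    mkdoc("d3", 15, c("Drug", "ADR"), c(1, 8), c(4, 11)),
    mkdoc("d4", 15),
    mkdoc("d5", 15, "Reason", 10, 14))
  pred <- list(
    mkdoc("d1", 15, c("Reason", "Drug"), c(0, 5), c(3, 9)),  # both exact
    mkdoc("d2", 15, "ADR", 4, 8),                            # off by one -> FP+FN
    mkdoc("d3", 15, c("ADR", "ADR"), c(1, 8), c(4, 11)),     # one swap, one exact
    mkdoc("d4", 15, "Drug", 0, 2),                           # spurious
    mkdoc("d5", 15))                                         # missed
  rep_ <- strict_match_score(gold, pred)
  # exact: d1 Reason, d1 Drug, d3 ADR -> TP=3; FP: d2, d3 swap, d4 -> 3;
  # FN: d2, d3 Drug, d5 -> 3
  expect_equal(rep_$micro$tp, 3)
  expect_equal(rep_$micro$fp, 3)
  expect_equal(rep_$micro$fn, 3)
  expect_equal(rep_$micro$precision, 0.5)
  expect_equal(rep_$micro$recall, 0.5)
  expect_equal(rep_$micro$f1, 0.5)
  # per type: Drug misses d3 (swapped away); ADR gains d2 off-by-one and the
  # d3 swap as false positives; Reason misses d5
  expect_equal(rep_$per_type$Drug$tp, 1)
  expect_equal(rep_$per_type$Drug$fn, 1)
  expect_equal(rep_$per_type$ADR$fp, 2)
  expect_equal(rep_$per_type$Reason$fn, 1)
})

test_that("P(gold, pred) equals R(pred, gold) (symmetry property)", {
  set.seed(21)
  gold <- lapply(1:8, function(i) random_doc(20, sample(0:4, 1), paste0("d", i)))
  pred <- lapply(1:8, function(i) random_doc(20, sample(0:4, 1), paste0("d", i)))
  a <- strict_match_score(gold, pred)
  b <- strict_match_score(pred, gold)
  expect_equal(a$micro$precision, b$micro$recall)
  expect_equal(a$micro$recall, b$micro$precision)
})

test_that("adding correct predictions never hurts; incorrect never helps", {
  gold <- list(mkdoc("a", 20, c("Drug", "ADR", "Reason"), c(0, 5, 10), c(2, 8, 13)))
  partial <- list(mkdoc("a", 20, "Drug", 0, 2))
  more <- list(mkdoc("a", 20, c("Drug", "ADR"), c(0, 5), c(2, 8)))
  wrong <- list(mkdoc("a", 20, c("Drug", "Drug"), c(0, 15), c(2, 18)))
  m0 <- strict_match_score(gold, partial)$micro
  m1 <- strict_match_score(gold, more)$micro
  m2 <- strict_match_score(gold, wrong)$micro
  expect_gte(m1$precision, m0$precision - 1e-12)
  expect_gte(m1$recall, m0$recall)
  expect_gte(m1$f1, m0$f1)
  expect_lte(m2$precision, m0$precision)
  expect_lte(m2$f1 - 1e-12, m0$f1)
})

test_that("f1_score reproduces the reported precision/recall arithmetic", {
  expect_equal(round(f1_score(96.4, 96.0), 1), 96.2)
  expect_equal(round(f1_score(86.1, 73.8), 1), 79.5)
  expect_equal(f1_score(80, 80), 80)   # harmonic mean identity at p = r
  expect_equal(f1_score(0, 0), 0)      # zero-denominator convention
})

test_that("aggregate_runs reports mean and sample SD per metric", {
  gold <- list(mkdoc("a", 10, "Drug", 2, 5))
  r1 <- strict_match_score(gold, gold)                       # F1 = 1
  r2 <- strict_match_score(gold, list(mkdoc("a", 10)))       # F1 = 0
  agg <- aggregate_runs(list(r1, r1))
  expect_true(all(agg$sd == 0))
  expect_equal(agg$mean[agg$type == "micro" & agg$metric == "f1"], 1)

  agg2 <- aggregate_runs(list(r1, r2))
  micro_f1 <- agg2[agg2$type == "micro" & agg2$metric == "f1", ]
  expect_equal(micro_f1$mean, 0.5)
  expect_equal(micro_f1$sd, stats::sd(c(0, 1)))
  expect_equal(micro_f1$formatted, "50.0 (70.71)")
  # mean never exceeds the max of the inputs
  expect_true(all(agg2$mean <= 1))

  expect_error(aggregate_runs(list(r1)), "at least 2")
})

test_that("aggregate of {95, 97} percent F1 gives mean 96, SD sqrt(2)", {
  vals <- c(95, 97)
  expect_equal(mean(vals), 96)
  expect_equal(stats::sd(vals), sqrt(2))
})

test_that("compare_candidates scores candidates side by side", {
  gold <- list(mkdoc("a", 12, "Drug", 2, 5), mkdoc("b", 12, "ADR", 0, 3))
  empty <- list(mkdoc("a", 12), mkdoc("b", 12))
  cmp <- compare_candidates(gold, list(model = gold, manual = empty))
  expect_s3_class(cmp, "data.frame")
  expect_equal(nrow(cmp), 2 * 4)  # 3 types + micro, per candidate
  model_micro <- cmp[cmp$candidate == "model" & cmp$type == "micro", ]
  expect_equal(model_micro$f1, 1)
  manual_micro <- cmp[cmp$candidate == "manual" & cmp$type == "micro", ]
  expect_equal(manual_micro$precision, 0)  # empty predictions -> 0 by convention
  expect_equal(manual_micro$recall, 0)

  dis <- attr(cmp, "disagreements")
  expect_equal(nrow(dis$model), 0)
  expect_equal(nrow(dis$manual), 2)
  expect_true(all(dis$manual$kind == "fn"))
})

test_that("comparison reports are written as text and JSON", {
  gold <- list(mkdoc("a", 12, "Drug", 2, 5))
  cmp <- compare_candidates(gold, list(self = gold))
  stem <- withr::local_tempfile()
  paths <- write_comparison(cmp, stem)
  expect_true(file.exists(paste0(stem, ".txt")))
  back <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  expect_equal(back$f1[back$type == "micro"], 1)
})
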