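stmt_df <- function(ids, stmts) {
  data.frame(sentence_id = ids, statement = stmts, stringsAsFactors = FALSE)
}

test_that("identical gold and prediction score perfectly at all levels", {
  g <- stmt_df(c("s1", "s1", "s2"),
               c("p(HGNC:A) increases tscript(p(HGNC:B))",
                 "a(CHEBI:x) decreases p(HGNC:C)",
                 'bp(GOBP:"cell cycle") increases p(HGNC:D)'))
  for (lv in c("term", "function", "relation", "bel")) {
    r <- score(g, g, lv)
    expect_equal(r$precision, 1)
    expect_equal(r$recall, 1)
    expect_equal(r$f1, 1)
    expect_equal(r$fp, 0L)
    expect_equal(r$fn, 0L)
  }
})

test_that("the hand-counted {s1,s2} vs {s1,s3} case gives 0.5 at bel level", {
  gold <- stmt_df(c("x", "x"), c("p(HGNC:A) increases p(HGNC:B)",
                                 "p(HGNC:A) decreases p(HGNC:C)"))
  pred <- stmt_df(c("x", "x"), c("p(HGNC:A) increases p(HGNC:B)",
                                 "p(HGNC:A) increases p(HGNC:D)"))
  r <- score(gold, pred, "bel")
  expect_equal(r$tp, 1L)
  expect_equal(r$fp, 1L)
  expect_equal(r$fn, 1L)
  expect_equal(r$precision, 0.5)
  expect_equal(r$recall, 0.5)
  expect_equal(r$f1, 0.5)
})

test_that("correct identifiers with wrong relation split across levels", {
  gold <- stmt_df("x", "p(HGNC:A) increases p(HGNC:B)")
  pred <- stmt_df("x", "p(HGNC:A) decreases p(HGNC:B)")
  rt <- score(gold, pred, "term")
  expect_equal(rt$tp, 2L)       # both identifiers match
  rr <- score(gold, pred, "relation")
  expect_equal(rr$tp, 0L)
  expect_equal(rr$fp, 1L)
  expect_equal(rr$fn, 1L)
})

test_that("function level is restricted to wrapped terms", {
  gold <- stmt_df("x", "act(p(HGNC:A)) increases p(HGNC:B)")
  pred_same <- stmt_df("x", "act(p(HGNC:A)) increases p(HGNC:B)")
  pred_miss <- stmt_df("x", "p(HGNC:A) increases p(HGNC:B)")
  expect_equal(score(gold, pred_same, "function")$f1, 1)
  r <- score(gold, pred_miss, "function")
  expect_equal(r$tp, 0L)
  expect_equal(r$fn, 1L)   # the gold act-wrap is missed
  expect_equal(r$fp, 0L)   # unwrapped predictions are not counted
})

test_that("matching is per sentence: same statement in another sentence is wrong", {
  gold <- stmt_df("s1", "p(HGNC:A) increases p(HGNC:B)")
  pred <- stmt_df("s2", "p(HGNC:A) increases p(HGNC:B)")
  r <- score(gold, pred, "bel")
  expect_equal(r$tp, 0L)
  expect_equal(r$fp, 1L)
  expect_equal(r$fn, 1L)
})

test_that("bag semantics: duplicate statements consume gold at most once", {
  gold <- stmt_df("x", "p(HGNC:A) increases p(HGNC:B)")
  pred <- stmt_df(c("x", "x"), rep("p(HGNC:A) increases p(HGNC:B)", 2))
  r <- score(gold, pred, "bel")
  expect_equal(r$tp, 1L)
  expect_equal(r$fp, 1L)
})

test_that("score invariants hold on random statement pairs", {
  set.seed(61)
  for (i in 1:200) {
    gold <- replicate(sample(0:3, 1), rand_statement("s"),
                      simplify = FALSE)
    pred <- c(
      if (length(gold)) gold[seq_len(sample(0:length(gold), 1))] else
        list(),
      replicate(sample(0:3, 1), rand_statement("s"), simplify = FALSE))
    rt <- score(gold, pred, "term")
    rb <- score(gold, pred, "bel")
    for (r in list(rt, rb)) {
      expect_gte(r$precision, 0); expect_lte(r$precision, 1)
      expect_gte(r$recall, 0); expect_lte(r$recall, 1)
      if (r$precision > 0 && r$recall > 0) {
        expect_lte(r$f1, max(r$precision, r$recall) + 1e-12)
        expect_gte(r$f1, min(r$precision, r$recall) - 1e-12)
      }
    }
    # level-projection monotonicity: a full-statement match implies its
    # term leaves match, so term tp can never be below bel tp
    expect_gte(rt$tp, rb$tp)
    # self-score is perfect for any nonempty set
    if (length(gold)) expect_equal(score(gold, gold, "bel")$f1, 1)
  }
})

test_that("recover_gold_spans maps synonyms and falls back to nearest id", {
  lex <- lexicon_from_entries(
    dictionary_entries("EGID", c("3308", "3309"),
                       c("heat shock protein family A (Hsp70) member 4",
                         "heat shock protein family A (Hsp70) member 5"),
                       c("Hsp70|HSPA4", "Hsp70|HSPA5"), "protein"),
    "protein")
  s <- "Hsp70 was strongly induced by heat stress."
  out <- recover_gold_spans("EGID:3308", s, lex)
  expect_identical(out$method, "synonym")
  expect_identical(out$text, "Hsp70")
  expect_identical(substr(s, out$start + 1, out$end), "Hsp70")

  # gene id absent from the lexicon: nearest numeric candidate wins
  out2 <- recover_gold_spans("EGID:3310", s, lex)
  expect_identical(out2$method, "nearest_id")
  expect_identical(out2$text, "Hsp70")

  # identifier absent from sentence and lexicon, non-numeric: unmapped
  out3 <- recover_gold_spans("HGNC:TP53", s, lex)
  expect_identical(out3$method, "unmapped")
  expect_true(is.na(out3$start))
})

test_that("preferred name appearing verbatim maps to its exact span", {
  lex <- lexicon_from_entries(
    dictionary_entries("HGNC", "GK", "glycerol kinase", "", "protein"),
    "protein")
  s <- "We measured glycerol kinase levels."
  out <- recover_gold_spans("HGNC:GK", s, lex)
  expect_identical(substr(s, out$start + 1, out$end), "glycerol kinase")
})
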