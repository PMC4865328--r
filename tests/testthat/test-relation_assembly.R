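fig2_setup <- function() {
  b <- worked_examples()
  cfg <- bundle_config(b)
  s <- b$sentences$text[b$sentences$id == "fig2"]
  tr <- read_ptb(b$trees[["fig2"]], s)
  svo <- pas_to_svo(rule_srl(tr, "reduced"))
  per <- lapply(names(cfg$lexicons), function(t)
    max_match(s, cfg$lexicons[[t]], "fig2", max_ngram = cfg$max_ngram))
  ents <- ground_mentions(merge_mentions(per), cfg$lexicons)
  list(bundle = b, cfg = cfg, sentence = s, svo = svo, entities = ents)
}

test_that("map_relation follows the regulation-event polarity convention", {
  kmap <- default_resources()$relation_verbs
  expect_identical(map_relation("stimulate", kmap), "increases")
  expect_identical(map_relation("reduce", kmap), "decreases")
  expect_null(map_relation("discuss", kmap))
})

test_that("relation-verb file loader rejects malformed rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("stimulate\tincreases", "reduce\tshrinks"), f)
  expect_error(load_relation_verbs(f), class = "belpipe_format_error")
})

test_that("assemble builds the subject x object cross product", {
  x <- fig2_setup()
  stmts <- assemble(x$svo, x$entities, list(), "decreases", "fig2")
  expect_setequal(vapply(stmts, canonicalize, character(1)),
                  c("p(HGNC:PTGS2) decreases p(HGNC:IL1B)",
                    "p(HGNC:PTGS2) decreases p(HGNC:IL6)"))
})

test_that("assemble skips unresolved entities and empty sides", {
  x <- fig2_setup()
  ents <- x$entities
  ents$resolution[ents$text == "COX2"] <- "unresolved"
  expect_length(assemble(x$svo, ents, list(), "decreases"), 0L)
})

test_that("cross product size is |subjects| x |objects| pre-deduplication", {
  set.seed(51)
  s <- "AA1 and AA2 stimulated BB1 and BB2."
  lex <- lexicon_from_entries(
    dictionary_entries("HGNC", c("A1", "A2", "B1", "B2"),
                       c("AA1", "AA2", "BB1", "BB2"), "", "protein"),
    "protein")
  ents <- ground_mentions(max_match(s, lex, "s"), list(protein = lex))
  svo <- structure(list(subject_start = 0L, subject_end = 11L,
                        subject_text = "AA1 and AA2",
                        verb = "stimulated", verb_start = 12L,
                        verb_end = 22L,
                        object_start = 23L, object_end = 34L,
                        object_text = "BB1 and BB2"),
                   class = "bel_svo")
  stmts <- assemble(svo, ents, list(), "increases")
  expect_length(stmts, 4L)
})

test_that("adjust flips on odd keyword parity only", {
  adj <- default_resources()$adjustment
  x <- fig2_setup()
  st <- assemble(x$svo, x$entities, list(), "decreases", "fig2")[[1]]
  flipped <- adjust(st, x$svo, x$sentence, adj)
  expect_identical(flipped$relation, "increases")
  expect_true(flipped$adjusted)
  # applying the flip logic twice returns to the original relation
  back <- adjust(flipped, x$svo, x$sentence, adj)
  expect_identical(back$relation, "decreases")

  # no keyword in either span: unchanged
  clean <- "COX2 reduced IL-6 levels."
  svo2 <- structure(list(subject_start = 0L, subject_end = 4L,
                         subject_text = "COX2", verb = "reduced",
                         verb_start = 5L, verb_end = 12L,
                         object_start = 13L, object_end = 17L,
                         object_text = "IL-6"),
                    class = "bel_svo")
  same <- adjust(st, svo2, clean, adj)
  expect_identical(same$relation, "decreases")
  expect_false(same$adjusted)
})

test_that("two keywords across subject and object spans cancel", {
  adj <- default_resources()$adjustment
  s <- "Inhibition of AAA increased inactivation of BBB."
  svo <- structure(list(subject_start = 0L, subject_end = 17L,
                        subject_text = "Inhibition of AAA",
                        verb = "increased", verb_start = 18L,
                        verb_end = 27L,
                        object_start = 28L, object_end = 47L,
                        object_text = "inactivation of BBB"),
                   class = "bel_svo")
  st <- bel_statement(bel_term("protein", "HGNC", "AAA"), "increases",
                      bel_term("protein", "HGNC", "BBB"))
  out <- adjust(st, svo, s, adj)
  expect_identical(out$relation, "increases")
  expect_false(out$adjusted)
})

test_that("extract_statements reproduces the worked examples end to end", {
  b <- worked_examples()
  cfg <- bundle_config(b)
  fig1 <- extract_statements(
    b$sentences$text[b$sentences$id == "fig1"], b$trees[["fig1"]], cfg,
    "fig1")
  expect_identical(vapply(fig1, canonicalize, character(1)),
                   "p(HGNC:MAP3K1) increases tscript(p(HGNC:AR))")

  fig2 <- extract_statements(
    b$sentences$text[b$sentences$id == "fig2"], b$trees[["fig2"]], cfg,
    "fig2")
  expect_setequal(vapply(fig2, canonicalize, character(1)),
                  c("p(HGNC:PTGS2) increases p(HGNC:IL1B)",
                    "p(HGNC:PTGS2) increases p(HGNC:IL6)"))
  expect_true(all(vapply(fig2, function(s) s$adjusted, logical(1))))

  # sentence without a relation verb yields nothing
  none <- extract_statements(
    b$sentences$text[b$sentences$id == "gapdh"], b$trees[["gapdh"]], cfg,
    "gapdh")
  expect_length(none, 0L)

  # per-stage counts are reported
  expect_named(attr(fig2, "counts"),
               c("mentions", "grounded", "wrapped", "pas", "statements",
                 "flips"))
})

test_that("emitted statement identifiers come from in-sentence mentions", {
  b <- generate_synthetic(25, seed = 99)
  cfg <- bundle_config(b)
  for (i in seq_len(nrow(b$sentences))) {
    s <- b$sentences$text[[i]]
    stmts <- extract_statements(s, b$trees[[i]], cfg,
                                b$sentences$id[[i]])
    lexidx <- cfg$lexicons$protein$entries
    for (st in stmts) {
      for (term in list(st$subject, st$object)) {
        surf <- lexidx$name[lexidx$identifier == term$value]
        expect_true(grepl(surf, s, fixed = TRUE))
      }
    }
  }
})
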