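simple_tree <- function() {
  read_ptb("(S (NP (NN A)) (VP (VBD reduced) (NP (NN B))))", "A reduced B")
}

test_that("read_ptb parses and aligns leaves to character spans", {
  tr <- simple_tree()
  leaves <- tree_leaves(tr)
  expect_length(leaves, 3L)
  expect_identical(vapply(leaves, function(l) l$token, character(1)),
                   c("A", "reduced", "B"))
  expect_equal(leaves[[2]]$start, 2L)
  expect_equal(leaves[[2]]$end, 9L)
  # node spans are unions of child spans
  expect_equal(tr$start, 0L)
  expect_equal(tr$end, 11L)

  expect_error(read_ptb("(S (NP A)", "A"), "unbalanced",
               class = "belpipe_parse_error")
  expect_error(read_ptb("(S (NP (NN A)))", "B"),
               class = "belpipe_alignment_error")
})

test_that("read_ptb handles PTB bracket escapes", {
  s <- "GAPDH (TPI) rose."
  tr <- read_ptb(
    "(S (NP (NN GAPDH) (-LRB- -LRB-) (NN TPI) (-RRB- -RRB-)) (VP (VBD rose)) (. .))",
    s)
  toks <- vapply(tree_leaves(tr), function(l) l$token, character(1))
  expect_identical(toks, c("GAPDH", "(", "TPI", ")", "rose", "."))
})

test_that("rule_srl recovers agent and patient in the canonical case", {
  pas <- rule_srl(simple_tree(), "reduced")
  expect_identical(pas$args$ARG0$text, "A")
  expect_identical(pas$args$ARG1$text, "B")
})

test_that("rule_srl recovers the agent missed on the two-verb fixture", {
  b <- worked_examples()
  tr <- read_ptb(b$trees[["fig4"]],
                 b$sentences$text[b$sentences$id == "fig4"])
  pas <- rule_srl(tr, "upregulated")
  expect_identical(pas$args$ARG0$text, "IL-5 or GM-CSF")
  pas2 <- rule_srl(tr, "downregulated")
  expect_identical(pas2$args$ARG0$text, "Dexamethasone")
  expect_identical(pas2$args$ARG1$text, "eotaxin expression")
})

test_that("roles are omitted when no candidate exists", {
  tr <- read_ptb("(S (VP (VBD reduced) (NP (NN B))))", "reduced B")
  pas <- rule_srl(tr, "reduced")
  expect_null(pas$args$ARG0)
  expect_identical(pas$args$ARG1$text, "B")
  expect_error(rule_srl(tr, "increased"),
               class = "belpipe_contract_violation")
})

test_that("rule_srl agrees with the span-arithmetic oracle on random trees", {
  set.seed(41)
  for (i in 1:60) {
    rt <- rand_srl_tree()
    tr <- read_ptb(rt$tree_text, rt$sentence)
    pas <- rule_srl(tr, "reduced")
    want <- oracle_rule_srl(tr, "reduced")
    got_a0 <- if (is.null(pas$args$ARG0)) NULL else
      c(pas$args$ARG0$start, pas$args$ARG0$end)
    got_a1 <- if (is.null(pas$args$ARG1)) NULL else
      c(pas$args$ARG1$start, pas$args$ARG1$end)
    expect_identical(got_a0, want$ARG0)
    expect_identical(got_a1, want$ARG1)
  }
})

test_that("pas_to_svo needs both core roles and ignores modifiers", {
  b <- worked_examples()
  tr <- read_ptb(b$trees[["fig2"]],
                 b$sentences$text[b$sentences$id == "fig2"])
  pas <- rule_srl(tr, "reduced")
  svo <- pas_to_svo(pas)
  expect_identical(svo$subject_text, "Inhibition of COX2")
  expect_identical(svo$verb, "reduced")
  expect_identical(svo$object_text, "both IL-1 beta and IL-6 release")

  pas$args$`ARGM-TMP` <- list(start = 0L, end = 3L, text = "now")
  expect_identical(pas_to_svo(pas)[], svo[])

  pas$args$ARG1 <- NULL
  expect_null(pas_to_svo(pas))
})

test_that("label_sentence covers relation verbs and honors external PAS", {
  b <- worked_examples()
  verbs <- b$resources$relation_verbs
  tr <- read_ptb(b$trees[["fig4"]],
                 b$sentences$text[b$sentences$id == "fig4"])
  pas <- label_sentence(tr, verbs)
  expect_length(pas, 2L)
  expect_setequal(vapply(pas, function(p) p$predicate, character(1)),
                  c("downregulated", "upregulated"))

  # external PAS passes through and suppresses the rule for its predicate
  tr2 <- read_ptb("(S (NP (NN A)) (VP (VBD reduced) (NP (NN B))))",
                  "A reduced B")
  ext <- structure(list(predicate = "reduced", pred_start = 2L,
                        pred_end = 9L,
                        args = list(ARG0 = list(start = 0L, end = 1L,
                                                text = "A"))),
                   class = "bel_pas")
  out <- label_sentence(tr2, verbs, external_pas = list(ext))
  expect_length(out, 1L)
  expect_null(out[[1]]$args$ARG1)   # the external record, not the rule's

  # no relation verbs, no external records
  tr3 <- read_ptb("(S (NP (NN A)) (VP (VBD discussed) (NP (NN B))))",
                  "A discussed B")
  expect_length(label_sentence(tr3, verbs), 0L)
})

test_that("external PAS records read from JSON Lines", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(paste0(
    '{"sentence_id":"s1","predicate":"reduced","predicate_span":[2,9],',
    '"roles":{"ARG0":[0,1],"ARG1":[10,11]}}'), f)
  recs <- read_pas_records(f, "A reduced B", "s1")
  expect_length(recs, 1L)
  expect_identical(recs[[1]]$args$ARG0$text, "A")
  expect_identical(recs[[1]]$args$ARG1$text, "B")
})

test_that("verb lemmatization strips inflection against the lemma set", {
  lemmas <- c("stimulate", "reduce", "upregulate", "block")
  expect_identical(verb_lemma("stimulates", lemmas), "stimulate")
  expect_identical(verb_lemma("reduced", lemmas), "reduce")
  expect_identical(verb_lemma("upregulated", lemmas), "upregulate")
  expect_identical(verb_lemma("blocked", lemmas), "block")
  expect_identical(verb_lemma("Discusses", lemmas), "discusses")
})
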