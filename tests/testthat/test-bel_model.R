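test_that("serialization matches the published statement forms", {
  fig1 <- bel_statement(
    bel_term("protein", "HGNC", "MAP3K1"), "increases",
    bel_term("protein", "HGNC", "AR", wrap = "tscript"))
  expect_identical(serialize_statement(fig1),
                   "p(HGNC:MAP3K1) increases tscript(p(HGNC:AR))")

  gapdh <- bel_statement(
    bel_term("protein", "HGNC", "GAPDH", wrap = "act"), "increases",
    bel_term("bioprocess", "GOBP", "glycolysis"))
  expect_identical(serialize_statement(gapdh),
                   "act(p(HGNC:GAPDH)) increases bp(GOBP:glycolysis)")

  mbd3 <- bel_statement(
    bel_term("bioprocess", "GOBP", "cell cycle"), "increases",
    bel_term("protein", "HGNC", "MBD3"))
  expect_identical(serialize_statement(mbd3),
                   'bp(GOBP:"cell cycle") increases p(HGNC:MBD3)')
})

test_that("pmod serializes as an argument inside the protein term", {
  t <- bel_term("protein", "HGNC", "AKT1", wrap = "pmod", pmod_type = "P")
  expect_identical(serialize_term(t), "p(HGNC:AKT1,pmod(P))")
  rt <- parse_statement("p(HGNC:AKT1,pmod(P)) increases p(HGNC:GSK3B)")
  expect_identical(rt$subject$wrap, "pmod")
  expect_identical(rt$subject$pmod_type, "P")
})

test_that("type invariants are enforced with field-named errors", {
  expect_error(bel_term("protein", "HGNC", ""), "value",
               class = "belpipe_validation_error")
  expect_error(bel_term("enzyme", "HGNC", "X"), "kind",
               class = "belpipe_validation_error")
  expect_error(
    bel_term(NULL, wrap = "complex",
             members = list(bel_term("protein", "HGNC", "A"))),
    "members", class = "belpipe_validation_error")
  expect_error(
    bel_term("chemical", "CHEBI", "x", wrap = "pmod", pmod_type = "P"),
    "pmod", class = "belpipe_validation_error")
  expect_error(
    bel_statement(bel_term("protein", "HGNC", "A"), "resembles",
                  bel_term("protein", "HGNC", "A")),
    "relation", class = "belpipe_validation_error")
})

test_that("parser reads published forms and rejects unsupported constructs", {
  s <- parse_statement("a(CHEBI:testosterone) increases act(p(HGNC:AR))")
  expect_identical(s$subject$kind, "chemical")
  expect_identical(s$object$wrap, "act")
  expect_identical(s$object$value, "AR")

  expect_error(parse_statement("p(HGNC:AR) resembles p(HGNC:AR)"),
               "resembles", class = "belpipe_unsupported_construct")
  expect_error(parse_statement("g(HGNC:AR) increases p(HGNC:AR)"),
               class = "belpipe_unsupported_construct")
  err <- tryCatch(parse_statement("p(HGNC:AR increases p(HGNC:AR)"),
                  error = function(e) e)
  expect_s3_class(err, "belpipe_parse_error")
  expect_match(conditionMessage(err), "character \\d+")
})

test_that("canonicalize normalizes spacing, quoting and member order", {
  a <- parse_statement("p(HGNC:A)   increases   p( HGNC : B )")
  b <- parse_statement("p(HGNC:A) increases p(HGNC:B)")
  expect_identical(canonicalize(a), canonicalize(b))

  c1 <- "complex(p(HGNC:B),p(HGNC:A)) increases p(HGNC:C)"
  c2 <- "complex(p(HGNC:A),p(HGNC:B)) increases p(HGNC:C)"
  expect_identical(canonicalize(c1), canonicalize(c2))

  fig1 <- "p(HGNC:MAP3K1) increases tscript(p(HGNC:AR))"
  expect_identical(canonicalize(fig1), fig1)
})

test_that("parse/serialize round-trip is the identity under canonicalize", {
  set.seed(11)
  for (i in 1:50) {
    s <- rand_statement()
    txt <- serialize_statement(s)
    expect_identical(serialize_statement(parse_statement(txt)), txt)
    expect_identical(canonicalize(parse_statement(txt)), canonicalize(s))
  }
})

test_that("canonical equality is an equivalence relation on generated statements", {
  set.seed(12)
  for (i in 1:20) {
    s <- rand_statement()
    k <- canonicalize(s)
    expect_identical(k, canonicalize(s))                     # reflexive
    shuffled <- s
    if (identical(s$subject$wrap, "complex"))
      shuffled$subject$members <- rev(shuffled$subject$members)
    k2 <- canonicalize(shuffled)
    expect_identical(k2 == k, k == k2)                       # symmetric
    expect_identical(canonicalize(parse_statement(k2)), k)   # transitive
  }
})

test_that("BEL script files round-trip with ids and skip comments", {
  f <- withr::local_tempfile(fileext = ".bel")
  writeLines(c("# comment", "s1\tp(HGNC:A) increases p(HGNC:B)", "",
               "p(HGNC:C) decreases p(HGNC:D)"), f)
  df <- read_bel(f)
  expect_equal(nrow(df), 2L)
  expect_identical(df$sentence_id, c("s1", NA_character_))
  f2 <- withr::local_tempfile(fileext = ".bel")
  write_bel(df, f2)
  expect_identical(read_bel(f2)$canonical, df$canonical)

  f3 <- withr::local_tempfile(fileext = ".bel")
  writeLines(c("s1\tp(HGNC:A) increases p(HGNC:B)", "s2\tnot a statement"),
             f3)
  err <- tryCatch(read_bel(f3), error = function(e) e)
  expect_s3_class(err, "belpipe_parse_error")
  expect_match(conditionMessage(err), "2")
})
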