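# Packaged worked-example fixtures (sentences, hand-built parse trees,
# mini-dictionaries, gold statements) and a synthetic corpus generator with
# known gold structure, so every stage is testable offline. The
# mini-dictionaries contain only the entries the example sentences need -
# no licensed vocabulary is redistributed.

.res_path <- function(name) {
  system.file("extdata", name, package = "belpipe", mustWork = TRUE)
}

#' Default pipeline resources shipped with the package
#'
#' @return list with `patterns` (data.frame), `relation_verbs` (named
#'   character) and `adjustment` (character).
#' @export
default_resources <- function() {
  list(patterns = load_function_patterns(.res_path("function_patterns.tsv")),
       relation_verbs = load_relation_verbs(.res_path("relation_verbs.tsv")),
       adjustment = load_adjustment_keywords(
         .res_path("adjustment_keywords.txt")))
}

.we_protein_entries <- function() {
  dictionary_entries(
    namespace = c(rep("HGNC", 17), rep("EGID", 4)),
    identifier = c("MAP3K1", "AR", "PTGS2", "IL1B", "IL6", "IL5", "CSF2",
                   "CCL11", "LCP1", "GAPDH", "TPI1", "GK", "AQP7", "MBD3",
                   "MBD2", "DNMT1", "C5AR1",
                   "3308", "3309", "3553", "16176"),
    name = c("MAP3K1", "AR", "PTGS2", "IL1B", "IL6", "IL5", "CSF2",
             "CCL11", "LCP1", "GAPDH", "TPI1", "GK", "AQP7", "MBD3",
             "MBD2", "DNMT1", "C5AR1",
             "heat shock protein family A (Hsp70) member 4",
             "heat shock protein family A (Hsp70) member 5",
             "interleukin 1 beta", "interleukin 1 beta"),
    synonyms = c("MEKK1", "androgen receptor", "COX2|COX-2|cyclooxygenase-2",
                 "IL-1 beta|IL1 beta", "IL-6|interleukin 6", "IL-5",
                 "GM-CSF", "eotaxin|eotaxin-1", "L-plastin",
                 "Glyceraldehyde-3-phosphate dehydrogenase",
                 "TPI|triosephosphateisomerase", "glycerol kinase",
                 "Aqp7", "MBD3", "MBD2", "DNMT1", "C5aR",
                 "Hsp70|HSPA4", "Hsp70|HSPA5", "", ""),
    entity_type = "protein")
}

.we_chemical_entries <- function() {
  dictionary_entries(
    namespace = "CHEBI",
    identifier = c("testosterone", "dexamethasone", "lipopolysaccharide"),
    name = c("testosterone", "dexamethasone", "lipopolysaccharide"),
    synonyms = c("", "", "LPS"),
    entity_type = "chemical")
}

.we_bioprocess_entries <- function() {
  dictionary_entries(
    namespace = "GOBP",
    identifier = c("glycolysis", "cell cycle"),
    name = c("glycolysis", "cell cycle"),
    synonyms = c("", ""),
    entity_type = "bioprocess")
}

.we_disease_entries <- function() {
  dictionary_entries(
    namespace = "MESHD", identifier = "D001943", name = "breast cancer",
    synonyms = "breast cancer cells", entity_type = "disease")
}

.we_sentences <- function() {
  data.frame(
    id = c("fig1", "fig2", "fig4", "lplastin", "gapdh", "aqp7", "mbd3",
           "c5ar"),
    text = c(
      "MEKK1 also stimulates the transcription of the androgen receptor.",
      "Inhibition of COX2 markedly reduced both IL-1 beta and IL-6 release.",
      paste("Dexamethasone downregulated eotaxin expression, whereas IL-5",
            "or GM-CSF upregulated eotaxin expression."),
      paste("L-plastin gene expression was positively regulated by",
            "testosterone in AR-positive prostate and breast cancer cells."),
      paste("Glyceraldehyde-3-phosphate dehydrogenase (GAPDH) and",
            "triosephosphateisomerase (TPI) are essential to glycolysis."),
      paste("We demonstrated the enhanced glycerol kinase enzymatic",
            "activity in Aqp7-KO and -knockdown adipocytes."),
      paste("Finally, the abundance of MBD3 was highest in the late S",
            "phase when the DNMT1 is also most abundant, whereas the MBD2",
            "level was largely constant throughout the cell cycle."),
      paste("Following i.v. infusion of LPS into mice, up-regulation of",
            "C5aR occurred in the capillary endothelium of mouse lung.")),
    noise = FALSE,
    stringsAsFactors = FALSE)
}

.we_trees <- function() {
  c(
    fig1 = paste0(
      "(S (NP (NN MEKK1)) (ADVP (RB also)) (VP (VBZ stimulates) ",
      "(NP (NP (DT the) (NN transcription)) (PP (IN of) ",
      "(NP (DT the) (JJ androgen) (NN receptor))))) (. .))"),
    fig2 = paste0(
      "(S (NP (NP (NN Inhibition)) (PP (IN of) (NP (NN COX2)))) ",
      "(VP (ADVP (RB markedly)) (VBD reduced) (NP (DT both) ",
      "(NP (NN IL-1) (NN beta)) (CC and) (NP (NN IL-6) (NN release)))) ",
      "(. .))"),
    # deliberately flat-ish tree: the inner clause hangs off the first VP,
    # exercising agent recovery under an imperfect parse
    fig4 = paste0(
      "(S (NP (NN Dexamethasone)) (VP (VBD downregulated) ",
      "(NP (NN eotaxin) (NN expression)) (, ,) (SBAR (IN whereas) ",
      "(S (NP (NP (NN IL-5)) (CC or) (NP (NN GM-CSF))) ",
      "(VP (VBD upregulated) (NP (NN eotaxin) (NN expression)))))) (. .))"),
    lplastin = paste0(
      "(S (NP (NN L-plastin) (NN gene) (NN expression)) (VP (VBD was) ",
      "(VP (ADVP (RB positively)) (VBN regulated) (PP (IN by) ",
      "(NP (NN testosterone))) (PP (IN in) (NP (JJ AR-positive) ",
      "(NN prostate) (CC and) (NN breast) (NN cancer) (NNS cells))))) ",
      "(. .))"),
    gapdh = paste0(
      "(S (NP (NP (NN Glyceraldehyde-3-phosphate) (NN dehydrogenase) ",
      "(-LRB- -LRB-) (NN GAPDH) (-RRB- -RRB-)) (CC and) ",
      "(NP (NN triosephosphateisomerase) (-LRB- -LRB-) (NN TPI) ",
      "(-RRB- -RRB-))) (VP (VBP are) (ADJP (JJ essential) (PP (TO to) ",
      "(NP (NN glycolysis))))) (. .))"),
    aqp7 = paste0(
      "(S (NP (PRP We)) (VP (VBD demonstrated) (NP (NP (DT the) ",
      "(JJ enhanced) (NN glycerol) (NN kinase) (JJ enzymatic) ",
      "(NN activity)) (PP (IN in) (NP (NN Aqp7-KO) (CC and) ",
      "(NN -knockdown) (NNS adipocytes))))) (. .))"),
    mbd3 = paste0(
      "(S (ADVP (RB Finally)) (, ,) (NP (NP (DT the) (NN abundance)) ",
      "(PP (IN of) (NP (NN MBD3)))) (VP (VBD was) (ADJP (JJS highest)) ",
      "(PP (IN in) (NP (DT the) (JJ late) (NN S) (NN phase))) ",
      "(SBAR (WHADVP (WRB when)) (S (NP (DT the) (NN DNMT1)) (VP (VBZ is) ",
      "(ADVP (RB also)) (ADJP (RBS most) (JJ abundant))))) (, ,) ",
      "(SBAR (IN whereas) (S (NP (DT the) (NN MBD2) (NN level)) ",
      "(VP (VBD was) (ADJP (RB largely) (JJ constant)) ",
      "(PP (IN throughout) (NP (DT the) (NN cell) (NN cycle))))))) (. .))"),
    c5ar = paste0(
      "(S (PP (VBG Following) (NP (NP (NN i.v.) (NN infusion)) ",
      "(PP (IN of) (NP (NN LPS))) (PP (IN into) (NP (NNS mice))))) (, ,) ",
      "(NP (NP (NN up-regulation)) (PP (IN of) (NP (NN C5aR)))) ",
      "(VP (VBD occurred) (PP (IN in) (NP (NP (DT the) (JJ capillary) ",
      "(NN endothelium)) (PP (IN of) (NP (NN mouse) (NN lung)))))) (. .))")
  )
}

.we_gold <- function() {
  data.frame(
    sentence_id = c("fig1", "fig2", "fig2", "fig4", "fig4", "fig4",
                    "lplastin", "gapdh", "gapdh", "aqp7", "mbd3", "c5ar"),
    statement = c(
      "p(HGNC:MAP3K1) increases tscript(p(HGNC:AR))",
      "p(HGNC:PTGS2) increases p(HGNC:IL1B)",
      "p(HGNC:PTGS2) increases p(HGNC:IL6)",
      "a(CHEBI:dexamethasone) decreases p(HGNC:CCL11)",
      "p(HGNC:IL5) increases p(HGNC:CCL11)",
      "p(HGNC:CSF2) increases p(HGNC:CCL11)",
      "a(CHEBI:testosterone) increases act(p(HGNC:AR))",
      "act(p(HGNC:GAPDH)) increases bp(GOBP:glycolysis)",
      "act(p(HGNC:TPI1)) increases bp(GOBP:glycolysis)",
      "p(HGNC:AQP7) decreases act(p(HGNC:GK))",
      'bp(GOBP:"cell cycle") increases p(HGNC:MBD3)',
      "a(CHEBI:lipopolysaccharide) increases p(HGNC:C5AR1)"),
    stringsAsFactors = FALSE)
}

#' Worked-example fixture bundle
#'
#' Eight example sentences with hand-authored constituency parses,
#' mini-dictionaries covering exactly their entities, a small homolog map,
#' the default keyword/pattern resources and the gold statements as
#' published. The gold of the harder sentences (passive voice, temporal
#' and location arguments, keyword-free functions) is deliberately beyond
#' what the rule pipeline extracts - they exercise the scorer's false
#' negative/positive accounting, not end-to-end recovery.
#'
#' @return a `bel_bundle`: `sentences`, `trees`, `dictionaries`,
#'   `homolog_map`, `gold`, `resources`.
#' @export
worked_examples <- function() {
  structure(
    list(sentences = .we_sentences(),
         trees = .we_trees(),
         dictionaries = list(protein = .we_protein_entries(),
                             chemical = .we_chemical_entries(),
                             bioprocess = .we_bioprocess_entries(),
                             disease = .we_disease_entries()),
         homolog_map = c("16176" = "3553", "3553" = "3553"),
         gold = .we_gold(),
         resources = default_resources()),
    class = "bel_bundle")
}

#' Build per-type lexicons from a bundle
#'
#' @param bundle a `bel_bundle`.
#' @return named list of `bel_lexicon` objects (the homolog map is
#'   attached to the protein lexicon).
#' @export
build_lexicons <- function(bundle) {
  out <- list()
  for (type in names(bundle$dictionaries)) {
    hm <- if (identical(type, "protein")) bundle$homolog_map else
      character(0)
    out[[type]] <- lexicon_from_entries(bundle$dictionaries[[type]], type,
                                        homolog_map = hm)
  }
  out
}

#' Pipeline config of a bundle
#'
#' @param bundle a `bel_bundle`.
#' @return a `bel_config` combining the bundle's lexicons and resources.
#' @export
bundle_config <- function(bundle) {
  pipeline_config(lexicons = build_lexicons(bundle),
                  patterns = bundle$resources$patterns,
                  relation_verbs = bundle$resources$relation_verbs,
                  adjustment = bundle$resources$adjustment)
}

#' Run the extraction pipeline over a bundle
#'
#' @param bundle a `bel_bundle`.
#' @param verbose log per-sentence stage counts.
#' @return data.frame with columns `sentence_id`, `statement`, `adjusted`,
#'   `canonical`, in sentence order then canonical statement order.
#' @export
run_pipeline <- function(bundle, verbose = FALSE) {
  config <- bundle_config(bundle)
  rows <- lapply(seq_len(nrow(bundle$sentences)), function(i) {
    id <- bundle$sentences$id[[i]]
    stmts <- extract_statements(bundle$sentences$text[[i]],
                                bundle$trees[[id]], config,
                                sentence_id = id, verbose = verbose)
    if (!length(stmts))
      return(data.frame(sentence_id = character(0),
                        statement = character(0), adjusted = logical(0),
                        canonical = character(0), stringsAsFactors = FALSE))
    data.frame(sentence_id = id,
               statement = vapply(stmts, serialize_statement, character(1)),
               adjusted = vapply(stmts, function(s) isTRUE(s$adjusted),
                                 logical(1)),
               canonical = vapply(stmts, canonicalize, character(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- synthetic corpus ------------------------------------------------------

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv()) else
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a synthetic fixture bundle with known gold structure
#'
#' Sentences follow the template
#' `[Inhibition of] <A> <relation-verb> <B> [and <C>].` over a
#' programmatically generated protein dictionary with opaque identifiers
#' (`HGNC:SYN0001`, ...). Gold statements are computed from the template
#' semantics, including the parity-correct polarity flip when the
#' `Inhibition of` trigger is present. A fraction of sentences can use an
#' unknown (non-relation) verb: their gold is still recorded (the template
#' defines it as `increases`), so they depress recall but never precision.
#' Same seed, same bundle.
#'
#' @param n number of sentences (>= 1).
#' @param seed RNG seed; the generator restores the caller's RNG state.
#' @param params list overriding `n_entities` (dictionary size, default
#'   30), `p_trigger` (probability of the polarity trigger, default 0.3),
#'   `p_second_object` (probability of a two-entity object, default 0.3),
#'   `noise_frac` (fraction of unknown-verb sentences, default 0).
#' @return a `bel_bundle`; `sentences$noise` marks the unknown-verb
#'   sentences.
#' @export
generate_synthetic <- function(n, seed = 1L, params = list()) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 ||
      n != round(n))
    bel_abort("belpipe_validation_error", "field 'n': need an integer >= 1")
  p <- utils::modifyList(
    list(n_entities = 30L, p_trigger = 0.3, p_second_object = 0.3,
         noise_frac = 0), params)
  if (p$noise_frac < 0 || p$noise_frac >= 1)
    bel_abort("belpipe_validation_error",
              "field 'noise_frac': need a value in [0, 1)")
  if (p$n_entities < 3L)
    bel_abort("belpipe_validation_error",
              "field 'n_entities': need at least 3 entities")
  resources <- default_resources()
  verbs <- resources$relation_verbs
  past <- function(lemma) if (grepl("e$", lemma)) paste0(lemma, "d") else
    paste0(lemma, "ed")
  noise_verbs <- c("examined", "discussed", "measured", "observed")
  surfaces <- sprintf("SYNPR%dA", seq_len(p$n_entities))
  ids <- sprintf("SYN%04d", seq_len(p$n_entities))
  entries <- dictionary_entries("HGNC", ids, surfaces, "", "protein")
  .with_seed(seed, {
    n_noise <- floor(n * p$noise_frac)
    noise <- seq_len(n) <= n_noise     # fixed positions: reproducible
    sent <- character(n); tree <- character(n)
    gold_id <- list(); gold_st <- list()
    for (i in seq_len(n)) {
      ent <- sample(p$n_entities, 3L)
      a <- surfaces[ent[1]]; b <- surfaces[ent[2]]; c3 <- surfaces[ent[3]]
      two_obj <- stats::runif(1) < p$p_second_object
      trig <- stats::runif(1) < p$p_trigger
      if (noise[i]) {
        v <- sample(noise_verbs, 1L)
        rel <- "increases"                 # template semantics for noise
      } else {
        lemma <- sample(names(verbs), 1L)
        v <- past(lemma)
        rel <- unname(verbs[[lemma]])
        if (trig) rel <- setdiff(BEL_RELATIONS, rel)
      }
      subj_txt <- if (trig) paste0("Inhibition of ", a) else a
      obj_txt <- if (two_obj) paste(b, "and", c3) else b
      sent[i] <- paste0(subj_txt, " ", v, " ", obj_txt, ".")
      subj_tree <- if (trig)
        sprintf("(NP (NP (NN Inhibition)) (PP (IN of) (NP (NN %s))))", a)
      else sprintf("(NP (NN %s))", a)
      obj_tree <- if (two_obj)
        sprintf("(NP (NP (NN %s)) (CC and) (NP (NN %s)))", b, c3)
      else sprintf("(NP (NN %s))", b)
      tree[i] <- sprintf("(S %s (VP (VBD %s) %s) (. .))", subj_tree, v,
                         obj_tree)
      objs <- if (two_obj) c(ent[2], ent[3]) else ent[2]
      for (o in objs) {
        gold_id[[length(gold_id) + 1L]] <- sprintf("syn%04d", i)
        gold_st[[length(gold_st) + 1L]] <- sprintf(
          "p(HGNC:%s) %s p(HGNC:%s)", ids[ent[1]], rel, ids[o])
      }
    }
    sid <- sprintf("syn%04d", seq_len(n))
    structure(
      list(sentences = data.frame(id = sid, text = sent, noise = noise,
                                  stringsAsFactors = FALSE),
           trees = stats::setNames(tree, sid),
           dictionaries = list(protein = entries),
           homolog_map = character(0),
           gold = data.frame(sentence_id = unlist(gold_id),
                             statement = unlist(gold_st),
                             stringsAsFactors = FALSE),
           resources = resources),
      class = "bel_bundle")
  })
}

# ---- bundle I/O ------------------------------------------------------------

#' Write a fixture bundle to a directory
#'
#' Materializes `sentences.jsonl`, `trees.ptb`, `dict_<type>.tsv`,
#' `homologs.tsv`, `gold.bel` and `config/` (keyword/pattern resources plus
#' a `pipeline.dcf` the command-line `extract` can consume directly).
#'
#' @param bundle a `bel_bundle`.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg_dir <- file.path(dir, "config")
  dir.create(cfg_dir, showWarnings = FALSE)
  sent_lines <- vapply(seq_len(nrow(bundle$sentences)), function(i)
    jsonlite::toJSON(list(id = bundle$sentences$id[[i]],
                          text = bundle$sentences$text[[i]],
                          noise = isTRUE(bundle$sentences$noise[[i]])),
                     auto_unbox = TRUE), character(1))
  writeLines(sent_lines, file.path(dir, "sentences.jsonl"),
             useBytes = TRUE)
  writeLines(unname(bundle$trees[bundle$sentences$id]),
             file.path(dir, "trees.ptb"), useBytes = TRUE)
  dict_keys <- character(0)
  for (type in names(bundle$dictionaries)) {
    f <- sprintf("dict_%s.tsv", type)
    utils::write.table(
      bundle$dictionaries[[type]][, c("namespace", "identifier", "name",
                                      "synonyms")],
      file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    dict_keys <- c(dict_keys, sprintf("dict_%s: %s", type, f))
  }
  hm_ids <- names(bundle$homolog_map)
  if (is.null(hm_ids)) hm_ids <- character(0)
  utils::write.table(
    data.frame(identifier = hm_ids,
               human_identifier = unname(bundle$homolog_map),
               stringsAsFactors = FALSE),
    file.path(dir, "homologs.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeLines(paste0(bundle$gold$sentence_id, "\t", bundle$gold$statement),
             file.path(dir, "gold.bel"), useBytes = TRUE)
  pat <- bundle$resources$patterns
  writeLines(paste(pat$fun, pat$template, pat$max_gap,
                   ifelse(is.na(pat$pmod_type), "-", pat$pmod_type),
                   sep = "\t"),
             file.path(cfg_dir, "function_patterns.tsv"), useBytes = TRUE)
  writeLines(paste(names(bundle$resources$relation_verbs),
                   unname(bundle$resources$relation_verbs), sep = "\t"),
             file.path(cfg_dir, "relation_verbs.tsv"), useBytes = TRUE)
  writeLines(bundle$resources$adjustment,
             file.path(cfg_dir, "adjustment_keywords.txt"),
             useBytes = TRUE)
  dcf <- c(dict_keys,
           "homologs: homologs.tsv",
           "patterns: config/function_patterns.tsv",
           "relation_verbs: config/relation_verbs.tsv",
           "adjustment: config/adjustment_keywords.txt",
           "precedence: protein,chemical,disease,bioprocess",
           "max_ngram: 8")
  writeLines(dcf, file.path(dir, "pipeline.dcf"), useBytes = TRUE)
  invisible(dir)
}

#' Read a fixture bundle back from a directory
#'
#' @param dir directory written by [write_bundle()].
#' @return a `bel_bundle`.
#' @export
read_bundle <- function(dir) {
  sent_lines <- readLines(file.path(dir, "sentences.jsonl"), warn = FALSE)
  sent_lines <- sent_lines[nzchar(trimws(sent_lines))]
  recs <- lapply(sent_lines, jsonlite::fromJSON)
  sentences <- data.frame(
    id = vapply(recs, function(r) as.character(r$id), character(1)),
    text = vapply(recs, function(r) as.character(r$text), character(1)),
    noise = vapply(recs, function(r) isTRUE(r$noise), logical(1)),
    stringsAsFactors = FALSE)
  trees <- readLines(file.path(dir, "trees.ptb"), warn = FALSE)
  trees <- stats::setNames(trees[seq_len(nrow(sentences))], sentences$id)
  dict_files <- list.files(dir, pattern = "^dict_.*\\.tsv$")
  dictionaries <- list()
  for (f in dict_files) {
    type <- sub("^dict_(.*)\\.tsv$", "\\1", f)
    raw <- utils::read.delim(file.path(dir, f), colClasses = "character",
                             quote = "", stringsAsFactors = FALSE)
    dictionaries[[type]] <- dictionary_entries(
      raw$namespace, raw$identifier, raw$name, raw$synonyms, type)
  }
  gold <- read_bel(file.path(dir, "gold.bel"))
  structure(
    list(sentences = sentences, trees = trees,
         dictionaries = dictionaries,
         homolog_map = load_homolog_map(file.path(dir, "homologs.tsv")),
         gold = data.frame(sentence_id = gold$sentence_id,
                           statement = gold$statement,
                           stringsAsFactors = FALSE),
         resources = list(
           patterns = load_function_patterns(
             file.path(dir, "config", "function_patterns.tsv")),
           relation_verbs = load_relation_verbs(
             file.path(dir, "config", "relation_verbs.tsv")),
           adjustment = load_adjustment_keywords(
             file.path(dir, "config", "adjustment_keywords.txt")))),
    class = "bel_bundle")
}

#' @export
print.bel_bundle <- function(x, ...) {
  cat(sprintf("<bel_bundle: %d sentences, %d gold statements, dicts: %s>\n",
              nrow(x$sentences), nrow(x$gold),
              paste(names(x$dictionaries), collapse = "/")))
  invisible(x)
}
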