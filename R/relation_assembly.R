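# Map SVO tuples plus grounded, function-wrapped entities to BEL
# statements, and apply the keyword polarity adjustment. Also hosts the
# full-pipeline composition extract_statements().

.KIND_OF_TYPE <- c(protein = "protein", chemical = "chemical",
                   bioprocess = "bioprocess", disease = "pathology")

#' Load the relation-verb resource
#'
#' One lemma per line, `lemma<TAB>increases|decreases` (`#` comments and
#' blank lines ignored). The polarity mirrors the regulation event-type
#' convention: regulation and positive regulation triggers map to
#' `increases`, negative regulation triggers to `decreases`.
#'
#' @param path resource file path.
#' @return named character vector `lemma -> relation`.
#' @export
load_relation_verbs <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (!length(lines)) return(character(0))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2L |
                 !vapply(parts, function(p) p[2] %in% BEL_RELATIONS,
                         logical(1)))
  if (length(bad))
    bel_abort("belpipe_format_error",
              sprintf("relation-verb file '%s': bad line(s) %s", path,
                      paste(bad, collapse = ", ")))
  lemma <- tolower(vapply(parts, `[[`, character(1), 1L))
  rel <- vapply(parts, `[[`, character(1), 2L)
  if (anyDuplicated(lemma))
    bel_abort("belpipe_format_error",
              sprintf("relation-verb file '%s': duplicate lemma(s)", path))
  stats::setNames(rel, lemma)
}

#' Load the polarity-adjustment keyword resource
#'
#' One keyword per line; stored lowercase with hyphens/periods removed so
#' matching is insensitive to those.
#'
#' @param path resource file path.
#' @return character vector of keywords.
#' @export
load_adjustment_keywords <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)])
  unique(gsub("[-.]", "", tolower(lines)))
}

#' Map a verb lemma to a relation type
#'
#' @param verb_lemma lowercase lemma.
#' @param kmap named character vector from [load_relation_verbs()].
#' @return `"increases"`, `"decreases"`, or `NULL` for unknown verbs (no
#'   statement is emitted for those).
#' @export
map_relation <- function(verb_lemma, kmap) {
  if (verb_lemma %in% names(kmap)) unname(kmap[[verb_lemma]]) else NULL
}

# Build the renderable term units (term + covering span) from grounded
# entities and wrap assignments. Unresolved entities are skipped; a complex
# group with fewer than two resolved members degrades to unwrapped singles.
.term_units <- function(entities, wraps) {
  units <- list()
  in_wrap <- logical(nrow(entities))
  mk_term <- function(i, wrap = NULL, pmod_type = NULL) {
    bel_term(kind = .KIND_OF_TYPE[[entities$entity_type[[i]]]],
             namespace = entities$namespace[[i]],
             value = entities$identifier[[i]],
             wrap = wrap,
             pmod_type = if (!is.null(pmod_type) && !is.na(pmod_type))
               pmod_type else NULL)
  }
  resolved <- entities$resolution != "unresolved"
  for (w in wraps) {
    idx <- w$entities
    in_wrap[idx] <- TRUE
    ok <- idx[resolved[idx]]
    if (identical(w$fun, "complex")) {
      if (length(ok) >= 2L) {
        members <- lapply(ok, mk_term)
        units[[length(units) + 1L]] <- list(
          term = bel_term(kind = NULL, wrap = "complex", members = members),
          start = min(entities$start[ok]), end = max(entities$end[ok]))
      } else {
        for (i in ok)
          units[[length(units) + 1L]] <- list(
            term = mk_term(i), start = entities$start[[i]],
            end = entities$end[[i]])
      }
    } else {
      pm <- if (identical(w$fun, "pmod")) w$pmod_type else NULL
      for (i in ok)
        units[[length(units) + 1L]] <- list(
          term = mk_term(i, wrap = w$fun, pmod_type = pm),
          start = entities$start[[i]], end = entities$end[[i]])
    }
  }
  for (i in which(resolved & !in_wrap))
    units[[length(units) + 1L]] <- list(
      term = mk_term(i), start = entities$start[[i]],
      end = entities$end[[i]])
  units
}

#' Assemble BEL statements from an SVO tuple
#'
#' Resolved entities whose span lies inside the subject phrase form the
#' subject set, likewise for the object phrase; the output is the cross
#' product subject x object (deduplicated on the canonical key), each side
#' rendered with its function wrap when assigned. Unresolved entities are
#' skipped silently; an empty side yields no statements.
#'
#' @param svo a `bel_svo` from [pas_to_svo()].
#' @param entities grounded mention data.frame.
#' @param wraps wrap assignments from [classify_functions()].
#' @param relation `"increases"` or `"decreases"` (pre-adjustment).
#' @param sentence_id provenance id.
#' @return list of `bel_statement` objects.
#' @export
assemble <- function(svo, entities, wraps, relation,
                     sentence_id = NA_character_) {
  if (is.null(relation)) return(list())
  units <- .term_units(entities, wraps)
  inside <- function(u, lo, hi) u$start >= lo && u$end <= hi
  subj <- Filter(function(u) inside(u, svo$subject_start, svo$subject_end),
                 units)
  obj <- Filter(function(u) inside(u, svo$object_start, svo$object_end),
                units)
  out <- list()
  seen <- character(0)
  for (s in subj) for (o in obj) {
    st <- bel_statement(s$term, relation, o$term,
                        sentence_id = sentence_id)
    key <- canonicalize(st)
    if (!key %in% seen) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- st
    }
  }
  out
}

.count_adjust_keywords <- function(sentence, spans, adjustment) {
  toks <- bel_tokenize(sentence)
  total <- 0L
  for (sp in spans) {
    inside <- toks$start >= sp[1] & toks$end <= sp[2]
    norm <- gsub("[-.]", "", tolower(toks$text[inside]))
    total <- total + sum(norm %in% adjustment)
  }
  total
}

#' Polarity adjustment of a statement
#'
#' Counts adjustment keywords (case-insensitive, token-level, hyphens and
#' periods ignored) inside the subject and object phrases of the SVO the
#' statement came from. An odd count flips the relation
#' (increases <-> decreases) and sets the `adjusted` provenance flag; an
#' even count leaves the statement unchanged (iterated negation cancels).
#'
#' @param statement a `bel_statement` produced by [assemble()].
#' @param svo the `bel_svo` it was assembled from.
#' @param sentence the sentence text.
#' @param adjustment keyword vector from [load_adjustment_keywords()].
#' @return the (possibly flipped) `bel_statement`.
#' @export
adjust <- function(statement, svo, sentence, adjustment) {
  n <- .count_adjust_keywords(
    sentence,
    list(c(svo$subject_start, svo$subject_end),
         c(svo$object_start, svo$object_end)),
    adjustment)
  if (n %% 2L == 1L) {
    statement$relation <- setdiff(BEL_RELATIONS, statement$relation)
    statement$adjusted <- TRUE
  }
  statement
}

#' Bundle pipeline resources into a config object
#'
#' @param lexicons named list of `bel_lexicon` objects keyed by entity type
#'   (`protein`, `chemical`, `bioprocess`, `disease`; any subset).
#' @param patterns function-pattern table ([load_function_patterns()]).
#' @param relation_verbs named vector ([load_relation_verbs()]).
#' @param adjustment keyword vector ([load_adjustment_keywords()]).
#' @param precedence mention-merge precedence order.
#' @param max_ngram longest dictionary match in tokens.
#' @return a `bel_config` list.
#' @export
pipeline_config <- function(lexicons, patterns, relation_verbs, adjustment,
                            precedence = c("protein", "chemical", "disease",
                                           "bioprocess"),
                            max_ngram = 8L) {
  structure(
    list(lexicons = lexicons, patterns = patterns,
         relation_verbs = relation_verbs, adjustment = adjustment,
         precedence = precedence, max_ngram = max_ngram),
    class = "bel_config"
  )
}

#' Extract BEL statements from one sentence
#'
#' Full pipeline composition: dictionary recognition per entity type (plus
#' optional plug-in mentions), mention merging, grounding, function
#' classification, semantic role labeling of every relation verb, SVO
#' reduction, relation mapping, assembly and polarity adjustment.
#' Deterministic for fixed inputs and config; statements are deduplicated
#' on the canonical key and returned in canonical order.
#'
#' @param sentence sentence text.
#' @param tree its `bel_parse_tree` (or a bracketed PTB string).
#' @param config a `bel_config`.
#' @param sentence_id provenance id.
#' @param external_pas optional list of `bel_pas` records.
#' @param plugin_mentions optional mention data.frame from [run_plugin()].
#' @param verbose log per-stage counts to stderr.
#' @return list of `bel_statement` objects; per-stage counts are attached
#'   as attribute `"counts"`.
#' @export
extract_statements <- function(sentence, tree, config,
                               sentence_id = NA_character_,
                               external_pas = NULL, plugin_mentions = NULL,
                               verbose = FALSE) {
  if (is.character(tree)) tree <- read_ptb(tree, sentence)
  per <- lapply(names(config$lexicons), function(type)
    max_match(sentence, config$lexicons[[type]], sentence_id,
              max_ngram = config$max_ngram))
  if (!is.null(plugin_mentions) && nrow(plugin_mentions))
    per <- c(per, list(plugin_mentions))
  mentions <- merge_mentions(per, precedence = config$precedence)
  entities <- ground_mentions(mentions, config$lexicons)
  wraps <- classify_functions(sentence, entities, config$patterns)
  pas_list <- label_sentence(tree, config$relation_verbs, external_pas)
  out <- list()
  seen <- character(0)
  n_flip <- 0L
  for (pas in pas_list) {
    svo <- pas_to_svo(pas)
    if (is.null(svo)) next
    relation <- map_relation(
      verb_lemma(svo$verb, names(config$relation_verbs)),
      config$relation_verbs)
    if (is.null(relation)) next
    for (st in assemble(svo, entities, wraps, relation, sentence_id)) {
      st <- adjust(st, svo, sentence, config$adjustment)
      if (isTRUE(st$adjusted)) n_flip <- n_flip + 1L
      key <- canonicalize(st)
      if (!key %in% seen) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- st
      }
    }
  }
  if (length(out))
    out <- out[order(vapply(out, canonicalize, character(1)),
                     method = "radix")]
  counts <- c(mentions = nrow(mentions),
              grounded = sum(entities$resolution != "unresolved"),
              wrapped = length(wraps), pas = length(pas_list),
              statements = length(out), flips = n_flip)
  if (verbose)
    message(sprintf(
      "[%s] mentions=%d grounded=%d wrapped=%d pas=%d statements=%d flips=%d",
      sentence_id, counts[["mentions"]], counts[["grounded"]],
      counts[["wrapped"]], counts[["pas"]], counts[["statements"]],
      counts[["flips"]]))
  attr(out, "counts") <- counts
  out
}
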