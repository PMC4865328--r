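# Scoring of predicted against gold BEL statements at four granularities
# (term, function, relation, full statement), plus recovery of gold mention
# boundaries from identifiers for diagnostics.
#
# Matching is per-sentence bag (multiset) matching: a corpus sentence may
# carry several statements, and each gold item is consumed at most once.

EVAL_LEVELS <- c("term", "function", "relation", "bel")

# leaves of a statement side: (namespace, identifier, wrap, pmod_type),
# complex members each reported with wrap "complex"
.leaf_records <- function(term) {
  if (identical(term$wrap, "complex")) {
    return(do.call(c, lapply(term$members, function(m) {
      list(list(namespace = m$namespace, identifier = m$value,
                wrap = "complex", pmod_type = NA_character_))
    })))
  }
  list(list(namespace = term$namespace, identifier = term$value,
            wrap = if (is.null(term$wrap)) NA_character_ else term$wrap,
            pmod_type = if (is.null(term$pmod_type)) NA_character_ else
              term$pmod_type))
}

.id_key <- function(term) {
  if (identical(term$wrap, "complex")) {
    ids <- sort(vapply(term$members, function(m)
      paste0(m$namespace, ":", m$value), character(1)), method = "radix")
    return(paste0("complex[", paste(ids, collapse = "&"), "]"))
  }
  paste0(term$namespace, ":", term$value)
}

.project <- function(statement, level) {
  st <- statement
  switch(level,
    term = {
      leaves <- c(.leaf_records(st$subject), .leaf_records(st$object))
      vapply(leaves, function(l) paste0(l$namespace, ":", l$identifier),
             character(1))
    },
    "function" = {
      leaves <- c(.leaf_records(st$subject), .leaf_records(st$object))
      keys <- vapply(leaves, function(l) {
        if (is.na(l$wrap)) return(NA_character_)
        w <- if (!is.na(l$pmod_type)) paste0(l$wrap, ":", l$pmod_type) else
          l$wrap
        paste0(l$namespace, ":", l$identifier, "|", w)
      }, character(1))
      keys[!is.na(keys)]
    },
    relation = paste(.id_key(st$subject), st$relation, .id_key(st$object)),
    bel = canonicalize(st),
    bel_abort("belpipe_validation_error",
              sprintf("unknown evaluation level '%s'", level))
  )
}

.as_statement_df <- function(x) {
  if (is.data.frame(x)) {
    parsed <- lapply(seq_len(nrow(x)), function(i)
      parse_statement(x$statement[[i]],
                      sentence_id = x$sentence_id[[i]]))
    ids <- as.character(x$sentence_id)
  } else {
    parsed <- x
    ids <- vapply(x, function(s) as.character(s$sentence_id), character(1))
  }
  ids[is.na(ids)] <- ""
  list(statements = parsed, ids = ids)
}

.bag_tp <- function(gold_keys, pred_keys) {
  if (!length(gold_keys) || !length(pred_keys)) return(0L)
  tg <- table(gold_keys)
  tp <- table(pred_keys)
  common <- intersect(names(tg), names(tp))
  if (!length(common)) return(0L)
  sum(pmin(as.integer(tg[common]), as.integer(tp[common])))
}

#' Score predicted against gold BEL statements
#'
#' Level projections: `term` compares the bag of `(namespace, identifier)`
#' leaves per sentence; `function` the bag of `(identifier, wrap)` pairs
#' restricted to wrapped terms; `relation` the
#' `(subject id, relation, object id)` triple; `bel` the full canonical
#' statement. Projections are matched greedily one-to-one within each
#' sentence.
#'
#' @param gold,pred either data.frames with columns `sentence_id` and
#'   `statement` (e.g. from [read_bel()]) or lists of `bel_statement`
#'   objects.
#' @param level one of `"term"`, `"function"`, `"relation"`, `"bel"`.
#' @return a `bel_eval` report: `level`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @export
score <- function(gold, pred, level = "bel") {
  level <- match.arg(level, EVAL_LEVELS)
  g <- .as_statement_df(gold)
  p <- .as_statement_df(pred)
  gkeys <- lapply(g$statements, .project, level = level)
  pkeys <- lapply(p$statements, .project, level = level)
  ids <- unique(c(g$ids, p$ids))
  tp <- 0L; n_gold <- 0L; n_pred <- 0L
  for (id in ids) {
    gk <- unlist(gkeys[g$ids == id])
    pk <- unlist(pkeys[p$ids == id])
    n_gold <- n_gold + length(gk)
    n_pred <- n_pred + length(pk)
    tp <- tp + .bag_tp(gk, pk)
  }
  fp <- n_pred - tp
  fn <- n_gold - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(
    list(level = level, tp = tp, fp = fp, fn = fn, precision = precision,
         recall = recall, f1 = f1),
    class = "bel_eval"
  )
}

#' @export
print.bel_eval <- function(x, ...) {
  cat(sprintf("%s-level: TP=%d FP=%d FN=%d  P=%.4f R=%.4f F1=%.4f\n",
              x$level, x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Score at all four levels
#'
#' @inheritParams score
#' @return data.frame with one row per level.
#' @export
score_all_levels <- function(gold, pred) {
  do.call(rbind, lapply(EVAL_LEVELS, function(lv) {
    r <- score(gold, pred, lv)
    data.frame(level = r$level, tp = r$tp, fp = r$fp, fn = r$fn,
               precision = r$precision, recall = r$recall, f1 = r$f1,
               stringsAsFactors = FALSE)
  }))
}

#' Recover gold mention boundaries from identifiers
#'
#' Maps each gold identifier to a sentence span by searching its dictionary
#' synonyms (variant-expanded) in the sentence. Gene identifiers that
#' cannot be mapped this way fall back to the recognized mention whose
#' candidate identifier has the smallest absolute numeric distance to the
#' gold identifier. Identifiers with neither a synonym hit nor a fallback
#' candidate are reported unmapped.
#'
#' @param gold_terms character vector of `"NS:identifier"` strings, or a
#'   data.frame with columns `namespace` and `identifier`.
#' @param sentence sentence text.
#' @param lexicon a `bel_lexicon` covering the identifiers.
#' @return data.frame with columns `namespace`, `identifier`, `start`,
#'   `end`, `text`, `method` (`"synonym"`, `"nearest_id"` or
#'   `"unmapped"`); spans are `NA` when unmapped.
#' @export
recover_gold_spans <- function(gold_terms, sentence, lexicon) {
  if (is.character(gold_terms)) {
    parts <- strsplit(gold_terms, ":", fixed = TRUE)
    gold_terms <- data.frame(
      namespace = vapply(parts, `[[`, character(1), 1L),
      identifier = vapply(parts, function(p)
        paste(p[-1], collapse = ":"), character(1)),
      stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(gold_terms)), function(i) {
    ns <- gold_terms$namespace[[i]]
    id <- gold_terms$identifier[[i]]
    hit <- lexicon$entries$namespace == ns &
      lexicon$entries$identifier == id
    if (any(hit)) {
      single <- lexicon_from_entries(
        lexicon$entries[hit, , drop = FALSE], lexicon$entity_type)
      m <- max_match(sentence, single)
      if (nrow(m))
        return(data.frame(namespace = ns, identifier = id,
                          start = m$start[[1]], end = m$end[[1]],
                          text = m$text[[1]], method = "synonym",
                          stringsAsFactors = FALSE))
    }
    # numeric-identifier fallback: nearest recognized candidate id
    gold_num <- suppressWarnings(as.numeric(id))
    if (!is.na(gold_num)) {
      m <- max_match(sentence, lexicon)
      best <- NULL; best_d <- Inf
      for (j in seq_len(nrow(m))) {
        cand <- lexicon_lookup(lexicon, m$text[[j]])
        d <- suppressWarnings(
          min(abs(as.numeric(cand$identifier) - gold_num), na.rm = TRUE))
        if (is.finite(d) && d < best_d) {
          best_d <- d
          best <- m[j, , drop = FALSE]
        }
      }
      if (!is.null(best))
        return(data.frame(namespace = ns, identifier = id,
                          start = best$start[[1]], end = best$end[[1]],
                          text = best$text[[1]], method = "nearest_id",
                          stringsAsFactors = FALSE))
    }
    data.frame(namespace = ns, identifier = id, start = NA_integer_,
               end = NA_integer_, text = NA_character_,
               method = "unmapped", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
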