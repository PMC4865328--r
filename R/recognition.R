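# Maximum-matching dictionary recognition, mention merging across
# recognizers, and the plug-in seam for external statistical NER output.
#
# Offsets are 0-based half-open character spans into the sentence, so
# text == substr(sentence, start + 1, end) for every mention.

#' Tokenize a sentence
#'
#' Splits on whitespace and punctuation boundaries while retaining hyphens
#' and apostrophes inside tokens, so "IL-1" is one token.
#'
#' @param sentence a single string.
#' @return data.frame with columns `start`, `end` (0-based half-open) and
#'   `text`.
#' @export
bel_tokenize <- function(sentence) {
  m <- gregexpr("[[:alnum:]]+(?:['-][[:alnum:]]+)*", sentence)[[1]]
  if (m[1] == -1L)
    return(data.frame(start = integer(0), end = integer(0),
                      text = character(0), stringsAsFactors = FALSE))
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(start = start, end = start + len,
             text = substring(sentence, start + 1L, start + len),
             stringsAsFactors = FALSE)
}

empty_mentions <- function() {
  data.frame(sentence_id = character(0), start = integer(0),
             end = integer(0), text = character(0),
             entity_type = character(0), source = character(0),
             stringsAsFactors = FALSE)
}

.mention_row <- function(sentence_id, start, end, text, entity_type,
                         source) {
  data.frame(sentence_id = sentence_id, start = as.integer(start),
             end = as.integer(end), text = text, entity_type = entity_type,
             source = source, stringsAsFactors = FALSE)
}

#' Maximum-matching dictionary recognition
#'
#' Greedy left-to-right longest match over token n-grams whose
#' variant-expanded key hits the lexicon index. Matched tokens are consumed,
#' so one recognizer never emits overlapping mentions. Matching is done on
#' normalized keys but the reported span is the original character span of
#' the covered tokens. A candidate span may not begin or end on a stop-word
#' or general-word token (those are droppable during key expansion and
#' would otherwise get absorbed into mention boundaries).
#'
#' @param sentence a single string.
#' @param lexicon a `bel_lexicon`.
#' @param sentence_id id recorded on the mentions.
#' @param max_ngram longest candidate span in tokens.
#' @return mention data.frame (columns `sentence_id`, `start`, `end`,
#'   `text`, `entity_type`, `source`), sorted by `start`.
#' @export
max_match <- function(sentence, lexicon, sentence_id = NA_character_,
                      max_ngram = 8L) {
  toks <- bel_tokenize(sentence)
  n <- nrow(toks)
  if (n == 0L || !length(lexicon_keys(lexicon))) return(empty_mentions())
  droppable <- tolower(toks$text) %in% c(bel_stop_words(),
                                         bel_general_words())
  out <- list()
  i <- 1L
  while (i <= n) {
    hit <- 0L
    if (!droppable[i]) for (j in seq(min(n, i + max_ngram - 1L), i)) {
      if (droppable[j]) next
      txt <- substr(sentence, toks$start[i] + 1L, toks$end[j])
      if (nrow(lexicon_lookup(lexicon, txt)) > 0L) {
        hit <- j
        break
      }
    }
    if (hit > 0L) {
      out[[length(out) + 1L]] <- .mention_row(
        sentence_id, toks$start[i], toks$end[hit],
        substr(sentence, toks$start[i] + 1L, toks$end[hit]),
        lexicon$entity_type, "dictionary")
      i <- hit + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) return(empty_mentions())
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' Merge mentions from several recognizers
#'
#' Overlaps are resolved by (1) longer span wins, (2) tie broken by the
#' entity-type precedence order, (3) earlier start. The result is
#' non-overlapping, sorted by start, and merging is idempotent.
#'
#' @param per_recognizer list of mention data.frames.
#' @param precedence entity types from highest to lowest priority.
#' @return a single non-overlapping mention data.frame.
#' @export
merge_mentions <- function(per_recognizer,
                           precedence = c("protein", "chemical", "disease",
                                          "bioprocess")) {
  per_recognizer <- per_recognizer[vapply(per_recognizer, nrow,
                                          integer(1)) > 0L]
  if (!length(per_recognizer)) return(empty_mentions())
  all <- do.call(rbind, per_recognizer)
  ids <- unique(all$sentence_id[!is.na(all$sentence_id)])
  if (length(ids) > 1L)
    bel_abort("belpipe_contract_violation",
              "merge_mentions(): mentions reference different sentences")
  prio <- match(all$entity_type, precedence)
  prio[is.na(prio)] <- length(precedence) + 1L
  src <- ifelse(all$source == "dictionary", 0L, 1L)
  ord <- order(-(all$end - all$start), prio, all$start, src)
  all <- all[ord, , drop = FALSE]
  kept <- empty_mentions()
  for (i in seq_len(nrow(all))) {
    row <- all[i, , drop = FALSE]
    overlaps <- nrow(kept) > 0L &&
      any(row$start < kept$end & kept$start < row$end)
    dup <- nrow(kept) > 0L &&
      any(kept$start == row$start & kept$end == row$end &
            kept$entity_type == row$entity_type)
    if (!overlaps && !dup) kept <- rbind(kept, row)
  }
  kept <- kept[order(kept$start), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' Ingest external NER plug-in records
#'
#' The plug-in record format is JSON Lines with fields `sentence_id`,
#' `start`, `end`, `type`, `score` (0-based half-open character offsets).
#' Records whose offsets fall outside the sentence are skipped with a
#' warning and counted.
#'
#' @param sentence the sentence text.
#' @param plugin_path path to a JSON Lines file, or a data.frame with the
#'   same fields.
#' @param sentence_id only records with this id are used (ignored when
#'   `NA`).
#' @return mention data.frame with `source = "plugin"`.
#' @export
run_plugin <- function(sentence, plugin_path, sentence_id = NA_character_) {
  if (is.data.frame(plugin_path)) {
    recs <- plugin_path
  } else {
    lines <- readLines(plugin_path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(empty_mentions())
    recs <- do.call(rbind, lapply(lines, function(l) {
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
    }))
  }
  if (!nrow(recs)) return(empty_mentions())
  if (!is.na(sentence_id) && "sentence_id" %in% names(recs))
    recs <- recs[recs$sentence_id == sentence_id, , drop = FALSE]
  if (!nrow(recs)) return(empty_mentions())
  len <- nchar(sentence)
  ok <- !is.na(recs$start) & !is.na(recs$end) & recs$start >= 0 &
    recs$start < recs$end & recs$end <= len
  skipped <- sum(!ok)
  if (skipped > 0L)
    warning(sprintf("run_plugin(): skipped %d record(s) with invalid offsets",
                    skipped), call. = FALSE)
  recs <- recs[ok, , drop = FALSE]
  if (!nrow(recs)) return(empty_mentions())
  out <- .mention_row(
    if ("sentence_id" %in% names(recs)) recs$sentence_id else sentence_id,
    recs$start, recs$end,
    substring(sentence, recs$start + 1L, recs$end),
    recs$type, "plugin")
  out[order(out$start), , drop = FALSE]
}
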