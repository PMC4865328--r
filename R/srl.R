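# Constituency-parse ingestion and the rule-based syntactic labeler (SBL):
# produce predicate-argument structures for relation verbs and reduce them
# to subject-verb-object tuples.
#
# Agent rule: climb from the verb to the nearest S ancestor at or above
# grandparent level whose left-side children contain an NP; the nearest
# (rightmost) such NP is the agent. Patient rule: the first NP or S sibling
# following the verb inside its verb phrase.

.PTB_UNESCAPE <- c("-LRB-" = "(", "-RRB-" = ")", "-LSB-" = "[",
                   "-RSB-" = "]", "-LCB-" = "{", "-RCB-" = "}",
                   "``" = "\"", "''" = "\"")

.ptb_tokens <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

.ptb_build <- function(toks, pos) {
  if (pos > length(toks) || toks[[pos]] != "(")
    bel_abort("belpipe_parse_error",
              sprintf("expected '(' at tree token %d", pos))
  pos <- pos + 1L
  if (pos > length(toks))
    bel_abort("belpipe_parse_error", "unbalanced brackets in parse tree")
  label <- toks[[pos]]
  pos <- pos + 1L
  children <- list()
  token <- NULL
  repeat {
    if (pos > length(toks))
      bel_abort("belpipe_parse_error", "unbalanced brackets in parse tree")
    if (toks[[pos]] == ")") {
      pos <- pos + 1L
      break
    }
    if (toks[[pos]] == "(") {
      sub <- .ptb_build(toks, pos)
      children[[length(children) + 1L]] <- sub$node
      pos <- sub$pos
    } else {
      token <- toks[[pos]]
      pos <- pos + 1L
    }
  }
  if (!is.null(token) && length(children))
    bel_abort("belpipe_parse_error",
              sprintf("node '%s' mixes a token with child nodes", label))
  list(node = list(label = label, children = children, token = token),
       pos = pos)
}

.collect_leaves <- function(node) {
  if (!is.null(node$token)) return(list(node))
  do.call(c, lapply(node$children, .collect_leaves))
}

.align_node <- function(node, sentence, state) {
  if (!is.null(node$token)) {
    raw <- node$token
    surf <- if (raw %in% names(.PTB_UNESCAPE)) .PTB_UNESCAPE[[raw]] else raw
    state$leaf_i <- state$leaf_i + 1L
    rest <- substring(sentence, state$pos + 1L)
    esc <- gsub("([][{}()*+?.\\^$|])", "\\\\\\1", surf)
    r <- regexpr(paste0("(?<![[:alnum:]])", esc, "(?![[:alnum:]])"), rest,
                 perl = TRUE)
    if (r == -1L) r <- regexpr(surf, rest, fixed = TRUE)
    if (r == -1L)
      bel_abort("belpipe_alignment_error",
                sprintf("token %d ('%s') not found in sentence after offset %d",
                        state$leaf_i, surf, state$pos))
    node$token <- surf
    node$start <- state$pos + as.integer(r) - 1L
    node$end <- node$start + nchar(surf)
    state$pos <- node$end
    return(node)
  }
  node$children <- lapply(node$children, .align_node, sentence = sentence,
                          state = state)
  node$start <- node$children[[1]]$start
  node$end <- node$children[[length(node$children)]]$end
  node
}

#' Read a Penn Treebank bracketed parse tree
#'
#' Parses the bracketed string and aligns every leaf token to a character
#' span of `sentence` by left-to-right search (PTB bracket escapes such as
#' `-LRB-` are unescaped first). Spans are 0-based half-open.
#'
#' @param text one bracketed tree string.
#' @param sentence the sentence the tree describes.
#' @return nested-list tree of class `bel_parse_tree`; every node has
#'   `label`, `children`, `start`, `end`, and leaves carry `token`.
#' @export
read_ptb <- function(text, sentence) {
  toks <- .ptb_tokens(text)
  built <- .ptb_build(toks, 1L)
  if (built$pos <= length(toks))
    bel_abort("belpipe_parse_error",
              "unbalanced brackets in parse tree (trailing material)")
  state <- new.env(parent = emptyenv())
  state$pos <- 0L
  state$leaf_i <- 0L
  root <- .align_node(built$node, sentence, state)
  structure(root, class = "bel_parse_tree", sentence = sentence)
}

#' Leaves of a parse tree
#' @param tree a `bel_parse_tree` (or any node).
#' @return list of leaf nodes in sentence order.
#' @export
tree_leaves <- function(tree) .collect_leaves(tree)

# Path from the root to the n-th leaf whose token equals `token`.
.leaf_path <- function(node, token, occurrence, counter) {
  if (!is.null(node$token)) {
    if (identical(node$token, token)) {
      counter$n <- counter$n + 1L
      if (counter$n == occurrence) return(list(node))
    }
    return(NULL)
  }
  for (ch in node$children) {
    sub <- .leaf_path(ch, token, occurrence, counter)
    if (!is.null(sub)) return(c(list(node), sub))
  }
  NULL
}

.span_role <- function(node, sentence) {
  list(start = node$start, end = node$end,
       text = substr(sentence, node$start + 1L, node$end))
}

#' Rule-based semantic role labeling for one predicate
#'
#' Implements the syntactic agent/patient rules: the patient (ARG1) is the
#' first NP or S sibling following the verb inside its verb phrase; the
#' agent (ARG0) is the nearest NP among the left-side children of the
#' verb's nearest S ancestor at or above grandparent level, climbing
#' further up when that S has no left NP. Roles are omitted when no
#' candidate exists.
#'
#' @param tree a `bel_parse_tree`.
#' @param predicate verb token to label.
#' @param occurrence which occurrence of the token (1-based) when it
#'   appears several times.
#' @return a `bel_pas`: `list(predicate, pred_start, pred_end, args)` where
#'   `args` maps role names (`ARG0`, `ARG1`) to spans.
#' @export
rule_srl <- function(tree, predicate, occurrence = 1L) {
  sentence <- attr(tree, "sentence")
  counter <- new.env(parent = emptyenv()); counter$n <- 0L
  path <- .leaf_path(tree, predicate, occurrence, counter)
  if (is.null(path))
    bel_abort("belpipe_contract_violation",
              sprintf("predicate '%s' (occurrence %d) not found in tree",
                      predicate, occurrence))
  n <- length(path)
  verb <- path[[n]]
  args <- list()
  # patient: first NP/S sibling after the verb within its parent phrase
  if (n >= 2L) {
    parent <- path[[n - 1L]]
    idx <- which(vapply(parent$children, function(ch)
      !is.null(ch$token) && ch$start == verb$start && ch$end == verb$end,
      logical(1)))[1]
    if (!is.na(idx) && idx < length(parent$children)) {
      for (ch in parent$children[(idx + 1L):length(parent$children)]) {
        if (startsWith(ch$label, "NP") || ch$label %in% c("S", "SBAR")) {
          args$ARG1 <- .span_role(ch, sentence)
          break
        }
      }
    }
  }
  # agent: nearest left NP under the nearest S ancestor >= grandparent
  if (n >= 3L) {
    for (ai in seq(n - 2L, 1L)) {
      anc <- path[[ai]]
      if (!identical(anc$label, "S")) next
      below <- path[[ai + 1L]]
      k <- which(vapply(anc$children, function(ch)
        ch$start == below$start && ch$end == below$end &&
          identical(ch$label, below$label), logical(1)))[1]
      if (is.na(k) || k == 1L) next
      lefts <- anc$children[seq_len(k - 1L)]
      np <- rev(Filter(function(ch) startsWith(ch$label, "NP"), lefts))
      if (length(np)) {
        args$ARG0 <- .span_role(np[[1]], sentence)
        break
      }
    }
  }
  structure(list(predicate = verb$token, pred_start = verb$start,
                 pred_end = verb$end, args = args),
            class = "bel_pas")
}

#' Reduce a predicate-argument structure to an SVO tuple
#'
#' The predicate, agent and patient map to verb, subject and object;
#' `ARGM-*` modifier roles are ignored. Returns `NULL` unless both ARG0 and
#' ARG1 are present.
#'
#' @param pas a `bel_pas`.
#' @return a `bel_svo` (`subject`/`verb`/`object` spans) or `NULL`.
#' @export
pas_to_svo <- function(pas) {
  a0 <- pas$args$ARG0
  a1 <- pas$args$ARG1
  if (is.null(a0) || is.null(a1)) return(NULL)
  structure(
    list(subject_start = a0$start, subject_end = a0$end,
         subject_text = a0$text,
         verb = pas$predicate, verb_start = pas$pred_start,
         verb_end = pas$pred_end,
         object_start = a1$start, object_end = a1$end,
         object_text = a1$text),
    class = "bel_svo"
  )
}

# suffix-stripping lemma candidates; no external lexical resources
.lemma_candidates <- function(token) {
  x <- tolower(token)
  unique(c(x,
           sub("s$", "", x),
           sub("es$", "", x),
           sub("ed$", "", x),
           sub("ed$", "e", x),
           sub("([a-z])\\1ed$", "\\1", x),
           sub("d$", "", x),
           sub("ing$", "", x),
           sub("ing$", "e", x),
           sub("([a-z])\\1ing$", "\\1", x)))
}

#' Lemmatize a verb token against a lemma set
#'
#' @param token inflected verb surface form.
#' @param lemmas character vector of known lemmas.
#' @return the first suffix-stripping candidate found in `lemmas`, or the
#'   lowercased token when none matches.
#' @export
verb_lemma <- function(token, lemmas) {
  cand <- .lemma_candidates(token)
  hit <- cand[cand %in% lemmas]
  if (length(hit)) hit[[1]] else tolower(token)
}

#' Read external predicate-argument records
#'
#' JSON Lines, one record per line with fields `sentence_id`, `predicate`,
#' `predicate_span` (`[start, end]`, 0-based half-open) and `roles`, a map
#' from role name to `[start, end]` spans.
#'
#' @param path JSON Lines file.
#' @param sentence sentence text (used to fill role text).
#' @param sentence_id only records with this id are kept (ignored when
#'   `NA`).
#' @return list of `bel_pas` objects.
#' @export
read_pas_records <- function(path, sentence, sentence_id = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (l in lines) {
    rec <- jsonlite::fromJSON(l)
    if (!is.na(sentence_id) && !is.null(rec$sentence_id) &&
        !identical(as.character(rec$sentence_id), sentence_id)) next
    args <- list()
    for (role in names(rec$roles)) {
      sp <- as.integer(rec$roles[[role]])
      args[[role]] <- list(start = sp[1], end = sp[2],
                           text = substr(sentence, sp[1] + 1L, sp[2]))
    }
    sp <- as.integer(rec$predicate_span)
    out[[length(out) + 1L]] <- structure(
      list(predicate = rec$predicate, pred_start = sp[1], pred_end = sp[2],
           args = args),
      class = "bel_pas")
  }
  out
}

#' Label every relation-verb predicate of a sentence
#'
#' Externally supplied predicate-argument structures are used for their
#' predicates; the rule-based labeler fills in every relation-verb token
#' (leaves with a `VB*` tag whose lemma is in `relation_verbs`) not covered
#' by an external record. One structure per predicate occurrence.
#'
#' @param tree a `bel_parse_tree`.
#' @param relation_verbs named character vector `lemma -> relation` (see
#'   [load_relation_verbs()]); only the names are used here.
#' @param external_pas optional list of `bel_pas` records.
#' @return list of `bel_pas`.
#' @export
label_sentence <- function(tree, relation_verbs, external_pas = NULL) {
  out <- list()
  covered <- character(0)
  for (p in external_pas) {
    out[[length(out) + 1L]] <- p
    covered <- c(covered, paste(p$predicate, p$pred_start, sep = "@"))
  }
  leaves <- tree_leaves(tree)
  occ <- new.env(parent = emptyenv())
  for (leaf in leaves) {
    if (is.null(leaf$token)) next
    n_prev <- if (is.null(occ[[leaf$token]])) 0L else occ[[leaf$token]]
    occ[[leaf$token]] <- n_prev + 1L
    if (!startsWith(leaf$label, "VB")) next
    if (!verb_lemma(leaf$token, names(relation_verbs)) %in%
        names(relation_verbs)) next
    key <- paste(leaf$token, leaf$start, sep = "@")
    if (key %in% covered) next
    out[[length(out) + 1L]] <- rule_srl(tree, leaf$token,
                                        occurrence = n_prev + 1L)
  }
  out
}
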