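# Shared generators and independent oracles for property-style tests.
# Tokens used in randomized recognition tests always carry a digit so they
# can never collide with the stop-word / general-word inventories.

new_token_factory <- function() {
  n <- 0L
  function() {
    n <<- n + 1L
    paste0(paste(sample(letters, sample(2:5, 1), replace = TRUE),
                 collapse = ""), n)
  }
}

rand_value <- function() {
  w <- function() paste(sample(LETTERS, sample(2:6, 1), replace = TRUE),
                        collapse = "")
  if (stats::runif(1) < 0.2) paste(w(), w()) else w()
}

rand_simple_term <- function() {
  kind <- sample(c("protein", "chemical", "bioprocess", "pathology"), 1)
  ns <- switch(kind, protein = "HGNC", chemical = "CHEBI",
               bioprocess = "GOBP", pathology = "MESHD")
  wrap <- if (kind == "protein")
    sample(c(NA, "act", "tscript", "deg", "pmod", "tloc"), 1)
  else sample(c(NA, "act", "deg"), 1)
  bel_term(kind, ns, rand_value(),
           wrap = if (is.na(wrap)) NULL else wrap,
           pmod_type = if (identical(wrap, "pmod")) "P" else NULL)
}

rand_term <- function() {
  if (stats::runif(1) < 0.2) {
    k <- sample(2:3, 1)
    members <- replicate(k, bel_term("protein", "HGNC", rand_value()),
                         simplify = FALSE)
    bel_term(kind = NULL, wrap = "complex", members = members)
  } else rand_simple_term()
}

rand_statement <- function(sentence_id = NA_character_) {
  bel_statement(rand_term(), sample(c("increases", "decreases"), 1),
                rand_term(), sentence_id = sentence_id)
}

# Brute-force maximum-matching oracle: enumerate every token span whose
# lookup hits the index (subject to the same boundary rule as the
# contract: spans never begin/end on a droppable stop/general word), then
# select the leftmost-longest non-overlapping subset.
oracle_max_match <- function(sentence, lexicon, max_ngram = 8L) {
  toks <- bel_tokenize(sentence)
  n <- nrow(toks)
  if (n == 0L) return(data.frame(start = integer(0), end = integer(0)))
  droppable <- tolower(toks$text) %in% c(bel_stop_words(),
                                         bel_general_words())
  hits <- list()
  for (i in seq_len(n)) for (j in i:min(n, i + max_ngram - 1L)) {
    if (droppable[i] || droppable[j]) next
    txt <- substr(sentence, toks$start[i] + 1L, toks$end[j])
    if (nrow(lexicon_lookup(lexicon, txt)) > 0L)
      hits[[length(hits) + 1L]] <- c(i, j)
  }
  sel <- list()
  cur <- 1L
  repeat {
    cand <- Filter(function(h) h[1] >= cur, hits)
    if (!length(cand)) break
    starts <- vapply(cand, `[`, integer(1), 1L)
    m <- min(starts)
    ends <- vapply(cand[starts == m], `[`, integer(1), 2L)
    j <- max(ends)
    sel[[length(sel) + 1L]] <- c(m, j)
    cur <- j + 1L
  }
  if (!length(sel)) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(
    start = vapply(sel, function(h) toks$start[h[1]], integer(1)),
    end = vapply(sel, function(h) toks$end[h[2]], integer(1)))
}

# random (dictionary, sentence) pair for the max-match oracle property
rand_dict_sentence <- function() {
  tok <- new_token_factory()
  pool <- replicate(12, tok())
  n_entries <- sample(3:6, 1)
  names_ <- vapply(seq_len(n_entries), function(i) {
    paste(sample(pool, sample(1:3, 1)), collapse = " ")
  }, character(1))
  entries <- dictionary_entries("HGNC", sprintf("G%03d", seq_len(n_entries)),
                                names_, "", "protein")
  lex <- lexicon_from_entries(entries, "protein")
  pieces <- character(0)
  for (k in seq_len(sample(4:8, 1))) {
    pieces <- c(pieces, if (stats::runif(1) < 0.4)
      names_[sample(n_entries, 1)] else sample(pool, 1))
  }
  list(sentence = paste0(paste(pieces, collapse = " "), "."), lexicon = lex)
}

# ---- rule_srl oracle: span arithmetic over a flattened node table -------

flatten_nodes <- function(node, depth = 0L) {
  row <- data.frame(label = node$label, start = node$start,
                    end = node$end, depth = depth,
                    leaf = !is.null(node$token), stringsAsFactors = FALSE)
  kids <- lapply(node$children, flatten_nodes, depth = depth + 1L)
  do.call(rbind, c(list(row), kids))
}

oracle_rule_srl <- function(tree, verb_token) {
  nodes <- flatten_nodes(tree)
  leaves <- tree_leaves(tree)
  v <- NULL
  for (l in leaves) if (identical(l$token, verb_token)) v <- l
  stopifnot(!is.null(v))
  contains <- nodes$start <= v$start & nodes$end >= v$end & !nodes$leaf
  anc <- nodes[contains, , drop = FALSE]
  anc <- anc[order(anc$depth, decreasing = TRUE), , drop = FALSE]
  # anc[1] = parent phrase, anc[2] = grandparent, ...
  out <- list()
  if (nrow(anc) >= 1L) {
    parent <- anc[1, ]
    sib <- nodes[nodes$depth == parent$depth + 1L &
                   nodes$start >= parent$start & nodes$end <= parent$end &
                   nodes$start >= v$end, , drop = FALSE]
    sib <- sib[grepl("^NP", sib$label) | sib$label %in% c("S", "SBAR"), ,
               drop = FALSE]
    if (nrow(sib)) {
      best <- sib[which.min(sib$start), ]
      out$ARG1 <- c(best$start, best$end)
    }
  }
  if (nrow(anc) >= 2L) {
    for (k in 2:nrow(anc)) {
      a <- anc[k, ]
      if (!identical(a$label, "S")) next
      ch <- nodes[nodes$depth == a$depth + 1L & nodes$start >= a$start &
                    nodes$end <= a$end & nodes$end <= v$start, ,
                  drop = FALSE]
      ch <- ch[grepl("^NP", ch$label), , drop = FALSE]
      if (nrow(ch)) {
        best <- ch[which.max(ch$start), ]
        out$ARG0 <- c(best$start, best$end)
        break
      }
    }
  }
  out
}

# random sentence + tree with a single verb "reduced" at nesting `depth`
rand_srl_tree <- function(depth = sample(0:2, 1)) {
  tok <- new_token_factory()
  left_elem <- function() {
    switch(sample(3, 1),
           sprintf("(NP (NN %s))", tok()),
           sprintf("(ADVP (RB %s))", tok()),
           sprintf("(PP (IN %s) (NP (NN %s)))", tok(), tok()))
  }
  build <- function(d) {
    lefts <- paste(replicate(sample(0:2, 1), left_elem()), collapse = " ")
    core <- if (d == 0L) {
      obj <- if (stats::runif(1) < 0.8) sprintf(" (NP (NN %s))", tok())
      else ""
      sprintf("(VP (VBD reduced)%s)", obj)
    } else build(d - 1L)
    trimws(sprintf("(S %s %s)", lefts, core))
  }
  text <- build(depth)
  leaves <- regmatches(text,
                       gregexpr("\\([A-Z]+ ([^()]+)\\)", text))[[1]]
  words <- sub("^\\([A-Z]+ ", "", sub("\\)$", "", leaves))
  list(tree_text = text, sentence = paste(words, collapse = " "))
}
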