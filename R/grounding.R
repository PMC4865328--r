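# Normalization of mentions to namespace identifiers, with the
# disambiguation ladder for proteins: exact single hit first, then
# homolog-to-human collapse; anything still ambiguous stays unresolved
# (unresolved entities are simply never emitted in statements).

#' Ground a single mention surface
#'
#' A single index hit grounds exactly. For proteins with several candidate
#' identifiers, each candidate is mapped through the homolog map
#' (identifiers absent from the map stand for themselves); if exactly one
#' human identifier survives, the mention is grounded to it with
#' `resolution = "homolog_to_human"`. Multiple survivors, multi-candidate
#' non-protein hits and zero hits are all `"unresolved"` - a value, not an
#' error.
#'
#' @param lexicon a `bel_lexicon` whose type matches the mention type.
#' @param text mention surface string.
#' @param entity_type mention type; must equal the lexicon's type.
#' @return list with `namespace`, `identifier` (`""` when unresolved),
#'   `resolution` and `ambiguity_count`.
#' @export
ground_mention <- function(lexicon, text,
                           entity_type = lexicon$entity_type) {
  if (!identical(entity_type, lexicon$entity_type))
    bel_abort("belpipe_contract_violation",
              sprintf("mention type '%s' does not match lexicon type '%s'",
                      entity_type, lexicon$entity_type))
  cand <- lexicon_lookup(lexicon, text)
  n <- nrow(cand)
  if (n == 0L)
    return(list(namespace = "", identifier = "", resolution = "unresolved",
                ambiguity_count = 1L))
  if (n == 1L)
    return(list(namespace = cand$namespace[[1]],
                identifier = cand$identifier[[1]],
                resolution = "exact", ambiguity_count = 1L))
  if (identical(entity_type, "protein") && length(lexicon$homolog_map)) {
    mapped <- ifelse(cand$identifier %in% names(lexicon$homolog_map),
                     unname(lexicon$homolog_map[cand$identifier]),
                     cand$identifier)
    survivors <- unique(mapped)
    if (length(survivors) == 1L) {
      # prefer the candidate row that already carries the human identifier
      hit <- which(cand$identifier == survivors)
      ns <- if (length(hit)) cand$namespace[[hit[1]]] else
        cand$namespace[[1]]
      return(list(namespace = ns, identifier = survivors,
                  resolution = "homolog_to_human",
                  ambiguity_count = as.integer(n)))
    }
  }
  list(namespace = "", identifier = "", resolution = "unresolved",
       ambiguity_count = as.integer(n))
}

#' Ground a mention table
#'
#' Applies [ground_mention()] row-wise, picking the lexicon matching each
#' mention's `entity_type`.
#'
#' @param mentions mention data.frame (see [max_match()]).
#' @param lexicons named list of `bel_lexicon` objects keyed by entity
#'   type.
#' @return the mentions with columns `namespace`, `identifier`,
#'   `resolution`, `ambiguity_count` appended.
#' @export
ground_mentions <- function(mentions, lexicons) {
  ns <- character(nrow(mentions)); id <- character(nrow(mentions))
  res <- character(nrow(mentions)); amb <- integer(nrow(mentions))
  for (i in seq_len(nrow(mentions))) {
    type <- mentions$entity_type[[i]]
    lex <- lexicons[[type]]
    if (is.null(lex)) {
      ns[i] <- ""; id[i] <- ""; res[i] <- "unresolved"; amb[i] <- 1L
      next
    }
    g <- ground_mention(lex, mentions$text[[i]], type)
    ns[i] <- g$namespace; id[i] <- g$identifier
    res[i] <- g$resolution; amb[i] <- g$ambiguity_count
  }
  mentions$namespace <- ns
  mentions$identifier <- id
  mentions$resolution <- res
  mentions$ambiguity_count <- amb
  mentions
}
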