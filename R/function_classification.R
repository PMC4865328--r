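# Pattern-based assignment of molecular-activity function wraps to grounded
# entities. A pattern is a token template mixing literal keywords and typed
# slots (<Protein>, <Chemical>, <Bioprocess>, <Disease>), with a bounded
# token gap allowed between consecutive template elements.

.SLOT_TYPES <- c(Protein = "protein", Chemical = "chemical",
                 Bioprocess = "bioprocess", Disease = "disease")

.parse_template <- function(template) {
  # "/" marks adjacency between two slots ("<Protein>/<Protein> complex")
  parts <- strsplit(gsub("/", " ", template), "\\s+")[[1]]
  parts <- parts[nzchar(parts)]
  lapply(parts, function(p) {
    m <- regmatches(p, regexec("^<([A-Za-z]+)>$", p))[[1]]
    if (length(m) == 2L) {
      type <- .SLOT_TYPES[[m[2]]]
      if (is.null(type))
        bel_abort("belpipe_format_error",
                  sprintf("unknown slot type '%s' in pattern template", p))
      list(slot = type)
    } else {
      list(literal = tolower(p))
    }
  })
}

#' Load a function-pattern resource file
#'
#' Plain text, one pattern per line:
#' `function<TAB>template<TAB>max_gap[<TAB>pmod_type]`, `#` comments and
#' blank lines ignored. Pattern-file order is the tie-break order during
#' matching.
#'
#' @param path resource file path.
#' @return data.frame with columns `fun`, `template`, `max_gap`,
#'   `pmod_type` plus a parsed `elements` list-column.
#' @export
load_function_patterns <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      bel_abort("belpipe_format_error",
                sprintf("pattern file '%s' line %d: need 3+ tab-separated fields",
                        path, i))
    fun <- f[[1]]
    if (!fun %in% BEL_WRAPS)
      bel_abort("belpipe_format_error",
                sprintf("pattern file '%s' line %d: unknown function '%s'",
                        path, i, fun))
    data.frame(fun = fun, template = f[[2]],
               max_gap = as.integer(f[[3]]),
               pmod_type = if (length(f) >= 4L && nzchar(f[[4]]) &&
                               f[[4]] != "-") f[[4]] else NA_character_,
               stringsAsFactors = FALSE)
  })
  pat <- do.call(rbind, rows)
  pat$elements <- lapply(pat$template, .parse_template)
  nslots <- vapply(pat$elements, function(e)
    sum(vapply(e, function(x) !is.null(x$slot), logical(1))), integer(1))
  if (any(nslots < 1L))
    bel_abort("belpipe_format_error",
              "every pattern template needs at least one slot")
  if (any(pat$fun == "complex" & nslots < 2L))
    bel_abort("belpipe_format_error",
              "complex pattern templates need at least two slots")
  pat
}

# Build the unit stream: consecutive tokens covered by one entity collapse
# into a single entity unit; all other tokens are literal units.
.unit_stream <- function(sentence, entities) {
  toks <- bel_tokenize(sentence)
  if (!nrow(toks)) return(list())
  ent_of <- rep(NA_integer_, nrow(toks))
  if (nrow(entities)) {
    for (e in seq_len(nrow(entities))) {
      cover <- toks$start >= entities$start[e] & toks$end <= entities$end[e]
      ent_of[cover & is.na(ent_of)] <- e
    }
  }
  units <- list()
  i <- 1L
  while (i <= nrow(toks)) {
    if (!is.na(ent_of[i])) {
      e <- ent_of[i]
      j <- i
      while (j < nrow(toks) && !is.na(ent_of[j + 1L]) &&
             ent_of[j + 1L] == e) j <- j + 1L
      units[[length(units) + 1L]] <- list(
        entity = e, type = entities$entity_type[[e]])
      i <- j + 1L
    } else {
      units[[length(units) + 1L]] <- list(literal = tolower(toks$text[[i]]))
      i <- i + 1L
    }
  }
  units
}

.match_at <- function(units, elements, start, max_gap) {
  bound <- integer(0)
  u <- start
  for (k in seq_along(elements)) {
    el <- elements[[k]]
    gap_allowed <- if (k == 1L) 0L else max_gap
    found <- FALSE
    for (g in 0:gap_allowed) {
      pos <- u + g
      if (pos > length(units)) break
      unit <- units[[pos]]
      ok <- if (!is.null(el$slot)) {
        !is.null(unit$entity) && identical(unit$type, el$slot) &&
          !unit$entity %in% bound
      } else {
        !is.null(unit$literal) && identical(unit$literal, el$literal)
      }
      if (ok) {
        if (!is.null(el$slot)) bound <- c(bound, unit$entity)
        u <- pos + 1L
        found <- TRUE
        break
      }
    }
    if (!found) return(NULL)
  }
  list(bound = bound, next_unit = u)
}

#' Classify molecular functions of grounded entities
#'
#' Each pattern is matched against the sentence token stream with slots
#' bound to entities of the slot type, allowing up to `max_gap` skipped
#' tokens between consecutive template elements. An entity receives at most
#' one wrap; the first match in pattern-file order wins. A `complex` match
#' binds two or more entities into a single wrap group.
#'
#' @param sentence sentence text.
#' @param entities grounded mention data.frame (see [ground_mentions()]).
#' @param patterns pattern table from [load_function_patterns()].
#' @return list of wrap assignments, each
#'   `list(entities = <row indices>, fun = <wrap>, pmod_type = <code|NA>)`.
#'   Empty list when nothing matches.
#' @export
classify_functions <- function(sentence, entities, patterns) {
  units <- .unit_stream(sentence, entities)
  if (!length(units) || !nrow(entities) || is.null(patterns) ||
      !nrow(patterns))
    return(list())
  wrapped <- logical(nrow(entities))
  out <- list()
  for (p in seq_len(nrow(patterns))) {
    elements <- patterns$elements[[p]]
    u <- 1L
    while (u <= length(units)) {
      m <- .match_at(units, elements, u, patterns$max_gap[[p]])
      if (is.null(m)) {
        u <- u + 1L
        next
      }
      bound <- m$bound
      if (identical(patterns$fun[[p]], "complex")) {
        if (length(bound) >= 2L && !any(wrapped[bound])) {
          wrapped[bound] <- TRUE
          out[[length(out) + 1L]] <- list(
            entities = bound, fun = "complex", pmod_type = NA_character_)
        }
      } else {
        free <- bound[!wrapped[bound]]
        for (e in free) {
          wrapped[e] <- TRUE
          out[[length(out) + 1L]] <- list(
            entities = e, fun = patterns$fun[[p]],
            pmod_type = patterns$pmod_type[[p]])
        }
      }
      u <- m$next_unit
    }
  }
  out
}
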