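# Dictionary loading and the heuristic surface-normalization rule engine
# used both to expand dictionary keys and to normalize mention text.
#
# Rules fall into families: basic (always applied, in fixed order), and
# optional families (parenthesis rewrite, space removal, general-word
# removal, stop-word removal) whose closure generates lookup variants.

# Printed seed inventories; the full expert lists were never published, so
# these ship as editable config (see inst/extdata) seeded with the printed
# words only.
.DEFAULT_GENERAL_WORDS <- c("group", "residue", "protein", "atom")
.DEFAULT_STOP_WORDS <- c("of", "the", "a", "an", "in", "on", "at", "by",
                         "for", "with", "to")

#' Default general-word and stop-word inventories
#'
#' @return character vector of lowercase words removed by the optional
#'   variant-expansion rules.
#' @export
bel_general_words <- function() .DEFAULT_GENERAL_WORDS

#' @rdname bel_general_words
#' @export
bel_stop_words <- function() .DEFAULT_STOP_WORDS

.norm1 <- function(x, keep_hyphen = FALSE) {
  if (is.na(x)) return("")
  s <- x
  # leading "human " (any case), applied to a fixpoint
  repeat {
    s2 <- sub("^\\s*[Hh][Uu][Mm][Aa][Nn]\\s+", "", s)
    if (identical(s2, s)) break
    s <- s2
  }
  # leading standalone "h" on gene-like tokens (hTERT, hIL6): only when the
  # remainder starts uppercase followed by uppercase/digit, judged on the
  # original casing, so "heat shock" is never rewritten
  s <- sub("^h(?=[A-Z][A-Z0-9])", "", s, perl = TRUE)
  s <- tolower(s)
  s <- gsub(if (keep_hyphen) "[.]" else "[-.]", "", s)
  s <- gsub("\\s+", " ", trimws(s))
  # strip one trailing plural "s" (never "ss", never on <= 2 chars); the
  # loop re-trims so the result is a fixpoint of the whole rule chain
  repeat {
    s <- trimws(s)
    if (nchar(s) > 2L && grepl("[^s]s$", s)) {
      s <- substr(s, 1L, nchar(s) - 1L)
    } else break
  }
  s
}

#' Normalize a surface string
#'
#' Applies the basic normalization rules in fixed order: lowercase; strip a
#' leading "human " and a leading standalone "h" on gene-like tokens; remove
#' hyphens and periods; strip one trailing plural "s" (skipped for strings
#' of length <= 2 and for "ss" endings); collapse whitespace. Total and
#' idempotent.
#'
#' @param x character vector.
#' @return character vector of normalized strings.
#' @export
normalize_surface <- function(x) {
  vapply(as.character(x), .norm1, character(1), USE.NAMES = FALSE)
}

.paren_rewrites <- function(text) {
  out <- character(0)
  if (grepl("(", text, fixed = TRUE)) {
    # "AAA(A)" -> "AAA-A" (hyphen insertion; the hyphen-removal basic rule
    # then also yields the fused "aaaa" key)
    out <- c(out, gsub("\\(([^()]*)\\)", "-\\1", text))
    # and the parenthetical dropped entirely
    out <- c(out, gsub("\\s*\\([^()]*\\)", "", text))
  }
  out
}

.drop_words <- function(s, words) {
  toks <- strsplit(s, " ", fixed = TRUE)[[1]]
  kept <- toks[!toks %in% words]
  paste(kept, collapse = " ")
}

#' Expand lookup variants of a string
#'
#' Returns the closure of the optional rule families (parenthesis rewrite,
#' space removal, general-word removal, stop-word removal) on top of
#' [normalize_surface()]. The result always contains
#' `normalize_surface(text)`; hyphen-kept lowercase forms are also emitted
#' so keys like `"aaa-a"` and `"aaaa"` both resolve.
#'
#' @param text a single string.
#' @param general_words,stop_words word inventories for the removal rules.
#' @return character vector (a set) of variant keys.
#' @export
expand_variants <- function(text, general_words = bel_general_words(),
                            stop_words = bel_stop_words()) {
  text <- as.character(text)[1]
  if (is.na(text)) text <- ""
  raws <- unique(c(text, .paren_rewrites(text)))
  base <- character(0)
  for (r in raws)
    base <- c(base, .norm1(r), .norm1(r, keep_hyphen = TRUE))
  out <- unique(base)
  repeat {
    grown <- unique(c(
      out,
      gsub(" ", "", out, fixed = TRUE),
      vapply(out, .drop_words, character(1), words = general_words,
             USE.NAMES = FALSE),
      vapply(out, .drop_words, character(1), words = stop_words,
             USE.NAMES = FALSE)
    ))
    grown <- grown[nzchar(grown)]
    if (length(grown) == length(out) && all(grown %in% out)) break
    out <- grown
  }
  unique(c(.norm1(text), out))
}

# ---- lexicon ---------------------------------------------------------------

new_lexicon <- function(entries, entity_type, homolog_map = character(0)) {
  index <- new.env(parent = emptyenv(), hash = TRUE)
  if (nrow(entries)) {
    for (i in seq_len(nrow(entries))) {
      syns <- entries$synonyms[[i]]
      names_i <- unique(c(entries$name[[i]],
                          if (nzchar(syns)) strsplit(syns, "|",
                                                     fixed = TRUE)[[1]]))
      keys <- unique(unlist(lapply(names_i, expand_variants)))
      keys <- keys[nzchar(keys)]
      for (k in keys) {
        hit <- c(paste(entries$namespace[[i]], entries$identifier[[i]],
                       sep = "\r"))
        index[[k]] <- unique(c(index[[k]], hit))
      }
    }
  }
  structure(
    list(entries = entries, index = index, entity_type = entity_type,
         homolog_map = homolog_map),
    class = "bel_lexicon"
  )
}

#' Load an entity dictionary
#'
#' The TSV format is 4 columns with a header row:
#' `namespace<TAB>identifier<TAB>name<TAB>synonyms`, synonyms
#' pipe-separated (may be empty). A zero-byte file yields an empty lexicon.
#'
#' @param path TSV file path.
#' @param entity_type one of `"protein"`, `"chemical"`, `"bioprocess"`,
#'   `"disease"`.
#' @param homolog_map named character vector mapping identifiers to human
#'   identifiers (see [load_homolog_map()]); used by protein grounding.
#' @param verbose log entry/key counts to stderr.
#' @return a `bel_lexicon`: the entries plus an index from every normalized
#'   variant key to its `(namespace, identifier)` candidates.
#' @export
load_dictionary <- function(path, entity_type, homolog_map = character(0),
                            verbose = FALSE) {
  if (!entity_type %in% c("protein", "chemical", "bioprocess", "disease"))
    bel_abort("belpipe_validation_error",
              sprintf("unknown entity_type '%s'", entity_type))
  if (file.size(path) == 0)
    return(new_lexicon(.empty_entries(entity_type), entity_type,
                       homolog_map))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character",
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("namespace", "identifier", "name", "synonyms")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    bel_abort("belpipe_format_error",
              sprintf("dictionary '%s' line 1: missing column(s) %s",
                      path, paste(missing, collapse = ", ")))
  entries <- dictionary_entries(raw$namespace, raw$identifier, raw$name,
                                raw$synonyms, entity_type)
  lex <- new_lexicon(entries, entity_type, homolog_map)
  if (verbose)
    message(sprintf("loaded %s dictionary: %d entries, %d keys",
                    entity_type, nrow(entries),
                    length(ls(lex$index, all.names = TRUE))))
  lex
}

.empty_entries <- function(entity_type) {
  data.frame(namespace = character(0), identifier = character(0),
             name = character(0), synonyms = character(0),
             entity_type = character(0), stringsAsFactors = FALSE)
}

#' Build dictionary entries in memory
#'
#' Programmatic equivalent of [load_dictionary()]'s file format; duplicate
#' `(namespace, identifier)` rows are merged (synonym union) with a warning.
#'
#' @param namespace,identifier,name,synonyms character vectors (synonyms
#'   pipe-separated, `""` for none).
#' @param entity_type single type tag applied to all rows.
#' @return data.frame of entries.
#' @export
dictionary_entries <- function(namespace, identifier, name, synonyms,
                               entity_type) {
  df <- data.frame(namespace = as.character(namespace),
                   identifier = as.character(identifier),
                   name = as.character(name),
                   synonyms = as.character(synonyms),
                   entity_type = entity_type, stringsAsFactors = FALSE)
  if (any(!nzchar(df$identifier)))
    bel_abort("belpipe_format_error", "empty identifier in dictionary rows")
  key <- paste(df$namespace, df$identifier, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (namespace, identifier) dictionary rows merged",
            call. = FALSE)
    merged <- lapply(split(seq_len(nrow(df)), key), function(idx) {
      syns <- unlist(strsplit(df$synonyms[idx], "|", fixed = TRUE))
      row <- df[idx[1], , drop = FALSE]
      row$synonyms <- paste(unique(syns[nzchar(syns)]), collapse = "|")
      row
    })
    df <- do.call(rbind, merged)
    df <- df[order(match(paste(df$namespace, df$identifier, sep = "\r"),
                         unique(key))), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Build a lexicon from in-memory entries
#'
#' @param entries data.frame from [dictionary_entries()].
#' @param entity_type type tag.
#' @param homolog_map named character vector.
#' @return a `bel_lexicon`.
#' @export
lexicon_from_entries <- function(entries, entity_type,
                                 homolog_map = character(0)) {
  new_lexicon(entries, entity_type, homolog_map)
}

#' Load a homolog identifier map
#'
#' Two tab-separated columns `identifier<TAB>human_identifier`, header row
#' required.
#'
#' @param path TSV file path.
#' @return named character vector: `identifier -> human identifier`.
#' @export
load_homolog_map <- function(path) {
  if (file.size(path) == 0) return(character(0))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  required <- c("identifier", "human_identifier")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    bel_abort("belpipe_format_error",
              sprintf("homolog map '%s': missing column(s) %s", path,
                      paste(missing, collapse = ", ")))
  stats::setNames(raw$human_identifier, raw$identifier)
}

#' Look up candidate identifiers for a surface string
#'
#' Expands the query through [expand_variants()] and unions all index hits.
#'
#' @param lexicon a `bel_lexicon`.
#' @param text surface string.
#' @return data.frame with columns `namespace`, `identifier` (zero rows for
#'   no hit).
#' @export
lexicon_lookup <- function(lexicon, text) {
  keys <- expand_variants(text)
  keys <- keys[nzchar(keys)]
  hits <- character(0)
  for (k in keys) {
    v <- lexicon$index[[k]]
    if (!is.null(v)) hits <- c(hits, v)
  }
  hits <- unique(hits)
  if (!length(hits))
    return(data.frame(namespace = character(0), identifier = character(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(hits, "\r", fixed = TRUE)
  data.frame(namespace = vapply(parts, `[[`, character(1), 1L),
             identifier = vapply(parts, `[[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Number of index keys in a lexicon
#' @param lexicon a `bel_lexicon`.
#' @return integer count.
#' @export
lexicon_keys <- function(lexicon) {
  ls(lexicon$index, all.names = TRUE)
}

#' @export
print.bel_lexicon <- function(x, ...) {
  cat(sprintf("<bel_lexicon: %s, %d entries, %d keys>\n", x$entity_type,
              nrow(x$entries), length(lexicon_keys(x))))
  invisible(x)
}
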