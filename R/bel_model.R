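# Core BEL data types, validation, serialization, parsing and canonical keys.
#
# The dialect is short-form BEL 1.0 restricted to what the pipeline emits:
# abundance heads p/a/bp/path, function wraps act/tscript/complex/deg/pmod/
# tloc, and the two causal predicates increases/decreases. pmod is modeled
# internally as a wrap (the scorer compares functions at that abstraction)
# but serializes as an argument inside the protein term, BEL 1.0 style.

BEL_HEADS <- c(protein = "p", chemical = "a", bioprocess = "bp",
               pathology = "path")
BEL_KINDS <- stats::setNames(names(BEL_HEADS), BEL_HEADS)
BEL_WRAPS <- c("act", "tscript", "complex", "deg", "pmod", "tloc")
BEL_RELATIONS <- c("increases", "decreases")

# Structured condition helper: every package error carries a subclass so
# callers (and tests) can distinguish validation from parse failures.
bel_abort <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "belpipe_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' Construct a BEL term
#'
#' A term is an abundance (protein `p`, chemical `a`, biological process
#' `bp`, pathology `path`) optionally wrapped in a molecular function
#' (`act`, `tscript`, `complex`, `deg`, `pmod`, `tloc`). A `complex` wrap
#' carries two or more member terms instead of its own abundance; a `pmod`
#' wrap carries a modification code such as `"P"` for phosphorylation.
#'
#' @param kind abundance kind: `"protein"`, `"chemical"`, `"bioprocess"` or
#'   `"pathology"`. Ignored (may be `NULL`) when `wrap = "complex"`.
#' @param namespace identifier authority, e.g. `"HGNC"`, `"EGID"`,
#'   `"CHEBI"`, `"GOBP"`, `"MESHD"`.
#' @param value identifier or symbol string; values containing whitespace
#'   are double-quoted on serialization.
#' @param wrap optional function wrap name.
#' @param members list of `bel_term` objects; required (length >= 2) when
#'   `wrap = "complex"`, must be empty otherwise.
#' @param pmod_type modification code, only when `wrap = "pmod"`.
#' @return an object of class `bel_term`.
#' @export
bel_term <- function(kind, namespace = NULL, value = NULL, wrap = NULL,
                     members = NULL, pmod_type = NULL) {
  t <- structure(
    list(kind = kind, namespace = namespace, value = value, wrap = wrap,
         members = if (is.null(members)) list() else members,
         pmod_type = pmod_type),
    class = "bel_term"
  )
  validate_term(t)
  t
}

validate_term <- function(t) {
  if (!is.null(t$wrap) && !t$wrap %in% BEL_WRAPS)
    bel_abort("belpipe_validation_error",
              sprintf("field 'wrap': unknown function wrap '%s'", t$wrap))
  if (identical(t$wrap, "complex")) {
    if (length(t$members) < 2L)
      bel_abort("belpipe_validation_error",
                "field 'members': complex requires >= 2 member terms")
    for (m in t$members) {
      if (!inherits(m, "bel_term"))
        bel_abort("belpipe_validation_error",
                  "field 'members': members must be bel_term objects")
      validate_term(m)
    }
    return(invisible(t))
  }
  if (length(t$members) > 0L)
    bel_abort("belpipe_validation_error",
              "field 'members': only complex terms carry members")
  if (is.null(t$kind) || !t$kind %in% names(BEL_HEADS))
    bel_abort("belpipe_validation_error",
              sprintf("field 'kind': unknown abundance kind '%s'",
                      if (is.null(t$kind)) "NULL" else t$kind))
  if (is.null(t$value) || !nzchar(t$value))
    bel_abort("belpipe_validation_error", "field 'value': must be nonempty")
  if (is.null(t$namespace) || !nzchar(t$namespace))
    bel_abort("belpipe_validation_error",
              "field 'namespace': must be nonempty")
  if (identical(t$wrap, "pmod")) {
    if (!identical(t$kind, "protein"))
      bel_abort("belpipe_validation_error",
                "field 'wrap': pmod applies to protein terms only")
    if (is.null(t$pmod_type) || !nzchar(t$pmod_type))
      bel_abort("belpipe_validation_error",
                "field 'pmod_type': required for pmod terms")
  } else if (!is.null(t$pmod_type)) {
    bel_abort("belpipe_validation_error",
              "field 'pmod_type': only valid with wrap = 'pmod'")
  }
  invisible(t)
}

#' Construct a BEL statement
#'
#' @param subject,object `bel_term` objects.
#' @param relation `"increases"` or `"decreases"` (the two causal predicates
#'   the pipeline models).
#' @param adjusted logical provenance flag: `TRUE` when the polarity was
#'   flipped by the keyword adjustment step.
#' @param sentence_id optional source-sentence reference.
#' @return an object of class `bel_statement`.
#' @export
bel_statement <- function(subject, relation, object, adjusted = FALSE,
                          sentence_id = NA_character_) {
  if (!inherits(subject, "bel_term"))
    bel_abort("belpipe_validation_error",
              "field 'subject': must be a bel_term")
  if (!inherits(object, "bel_term"))
    bel_abort("belpipe_validation_error",
              "field 'object': must be a bel_term")
  if (!is.character(relation) || length(relation) != 1L ||
      !relation %in% BEL_RELATIONS)
    bel_abort("belpipe_validation_error",
              sprintf("field 'relation': must be one of %s",
                      paste(BEL_RELATIONS, collapse = "/")))
  validate_term(subject); validate_term(object)
  structure(
    list(subject = subject, relation = relation, object = object,
         adjusted = isTRUE(adjusted), sentence_id = sentence_id),
    class = "bel_statement"
  )
}

.quote_value <- function(value) {
  if (grepl("\\s", value)) paste0('"', value, '"') else value
}

#' Serialize a BEL term
#'
#' @param term a `bel_term`.
#' @return one-line BEL text for the term.
#' @export
serialize_term <- function(term) {
  validate_term(term)
  if (identical(term$wrap, "complex")) {
    inner <- vapply(term$members, serialize_term, character(1))
    return(paste0("complex(", paste(inner, collapse = ","), ")"))
  }
  head <- BEL_HEADS[[term$kind]]
  core <- paste0(head, "(", term$namespace, ":", .quote_value(term$value))
  if (identical(term$wrap, "pmod"))
    core <- paste0(core, ",pmod(", term$pmod_type, ")")
  core <- paste0(core, ")")
  if (is.null(term$wrap) || identical(term$wrap, "pmod")) return(core)
  paste0(term$wrap, "(", core, ")")
}

#' Serialize a BEL statement
#'
#' @param statement a `bel_statement`.
#' @return one-line BEL text `subject relation object`.
#' @export
serialize_statement <- function(statement) {
  if (!inherits(statement, "bel_statement"))
    bel_abort("belpipe_validation_error",
              "serialize_statement() expects a bel_statement")
  paste(serialize_term(statement$subject), statement$relation,
        serialize_term(statement$object))
}

# ---- parser ----------------------------------------------------------------

.pstate <- function(text) {
  e <- new.env(parent = emptyenv())
  e$text <- text
  e$pos <- 1L          # 1-based cursor into text
  e
}

.p_skip_ws <- function(st) {
  while (st$pos <= nchar(st$text) &&
         grepl("^\\s$", substr(st$text, st$pos, st$pos)))
    st$pos <- st$pos + 1L
}

.p_fail <- function(st, msg) {
  bel_abort("belpipe_parse_error",
            sprintf("%s at character %d of %s", msg, st$pos,
                    deparse(st$text)),
            position = st$pos)
}

.p_expect <- function(st, ch) {
  .p_skip_ws(st)
  if (st$pos > nchar(st$text) || substr(st$text, st$pos, st$pos) != ch)
    .p_fail(st, sprintf("expected '%s'", ch))
  st$pos <- st$pos + 1L
}

.p_word <- function(st) {
  .p_skip_ws(st)
  m <- regmatches(substr(st$text, st$pos, nchar(st$text)),
                  regexpr("^[A-Za-z][A-Za-z_]*", substr(st$text, st$pos,
                                                        nchar(st$text))))
  if (length(m) == 0L) .p_fail(st, "expected a word")
  st$pos <- st$pos + nchar(m)
  m
}

.p_value <- function(st) {
  .p_skip_ws(st)
  rest <- substr(st$text, st$pos, nchar(st$text))
  if (startsWith(rest, '"')) {
    m <- regmatches(rest, regexpr('^"[^"]*"', rest))
    if (length(m) == 0L) .p_fail(st, "unterminated quoted value")
    st$pos <- st$pos + nchar(m)
    return(substr(m, 2L, nchar(m) - 1L))
  }
  m <- regmatches(rest, regexpr("^[^\\s(),\"]+", rest, perl = TRUE))
  if (length(m) == 0L) .p_fail(st, "expected a value")
  st$pos <- st$pos + nchar(m)
  m
}

.p_term <- function(st) {
  head <- .p_word(st)
  .p_expect(st, "(")
  if (head %in% setdiff(BEL_WRAPS, c("complex", "pmod"))) {
    inner <- .p_term(st)
    if (!is.null(inner$wrap))
      .p_fail(st, "nested function wraps are not supported")
    inner$wrap <- head
    .p_expect(st, ")")
    validate_term(inner)
    return(inner)
  }
  if (identical(head, "complex")) {
    members <- list(.p_term(st))
    repeat {
      .p_skip_ws(st)
      if (st$pos <= nchar(st$text) &&
          substr(st$text, st$pos, st$pos) == ",") {
        st$pos <- st$pos + 1L
        members <- c(members, list(.p_term(st)))
      } else break
    }
    .p_expect(st, ")")
    return(bel_term(kind = NULL, wrap = "complex", members = members))
  }
  if (!head %in% BEL_HEADS)
    bel_abort("belpipe_unsupported_construct",
              sprintf("unsupported term head '%s' at character %d",
                      head, st$pos))
  kind <- BEL_KINDS[[head]]
  ns <- .p_word(st)
  .p_expect(st, ":")
  value <- .p_value(st)
  pmod_type <- NULL
  .p_skip_ws(st)
  if (st$pos <= nchar(st$text) && substr(st$text, st$pos, st$pos) == ",") {
    st$pos <- st$pos + 1L
    w <- .p_word(st)
    if (!identical(w, "pmod"))
      bel_abort("belpipe_unsupported_construct",
                sprintf("unsupported term argument '%s' at character %d",
                        w, st$pos))
    .p_expect(st, "(")
    pmod_type <- .p_word(st)
    .p_expect(st, ")")
  }
  .p_expect(st, ")")
  bel_term(kind = kind, namespace = ns, value = value,
           wrap = if (is.null(pmod_type)) NULL else "pmod",
           pmod_type = pmod_type)
}

#' Parse one BEL statement line
#'
#' Inverse of [serialize_statement()]. Only the heads, wraps and the two
#' relations of the supported dialect are accepted; anything else raises an
#' unsupported-construct error rather than being silently dropped.
#'
#' @param text a single statement line.
#' @param sentence_id optional provenance to attach.
#' @return a `bel_statement`.
#' @export
parse_statement <- function(text, sentence_id = NA_character_) {
  if (!is.character(text) || length(text) != 1L)
    bel_abort("belpipe_parse_error", "parse_statement() expects one string")
  st <- .pstate(text)
  subject <- .p_term(st)
  rel <- .p_word(st)
  if (!rel %in% BEL_RELATIONS)
    bel_abort("belpipe_unsupported_construct",
              sprintf("unsupported relation '%s' at character %d",
                      rel, st$pos))
  object <- .p_term(st)
  .p_skip_ws(st)
  if (st$pos <= nchar(text))
    .p_fail(st, "trailing characters after statement")
  bel_statement(subject, rel, object, sentence_id = sentence_id)
}

# Recursively sort complex members so member order never affects equality.
.canonical_term <- function(term) {
  if (identical(term$wrap, "complex")) {
    members <- lapply(term$members, .canonical_term)
    keys <- vapply(members, serialize_term, character(1))
    term$members <- members[order(keys, method = "radix")]
  }
  term
}

#' Canonical string key of a BEL statement
#'
#' Deterministic equality key used by the scorer and for deduplication:
#' whitespace- and quoting-normalized serialization with complex members
#' ordered lexicographically.
#'
#' @param statement a `bel_statement` (or a statement string, which is
#'   parsed first).
#' @return a single string.
#' @export
canonicalize <- function(statement) {
  if (is.character(statement)) statement <- parse_statement(statement)
  statement$subject <- .canonical_term(statement$subject)
  statement$object <- .canonical_term(statement$object)
  serialize_statement(statement)
}

# ---- BEL script files ------------------------------------------------------

#' Read a BEL script file
#'
#' One statement per line, UTF-8, `#` comment lines and blank lines ignored.
#' Lines may carry a leading `sentence_id<TAB>` prefix (the scorer's gold
#' and prediction format).
#'
#' @param path file path.
#' @return data.frame with columns `sentence_id`, `statement` (the raw
#'   statement text) and `canonical` (its canonical key). Unparseable lines
#'   raise an error listing the offending line numbers.
#' @export
read_bel <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  ids <- character(0); stmts <- character(0); canon <- character(0)
  bad <- integer(0); bad_msg <- character(0)
  for (i in keep) {
    line <- lines[[i]]
    if (grepl("\t", line, fixed = TRUE)) {
      id <- sub("\t.*$", "", line)
      body <- sub("^[^\t]*\t", "", line)
    } else {
      id <- NA_character_
      body <- line
    }
    ck <- tryCatch(canonicalize(body), error = function(e) e)
    if (inherits(ck, "error")) {
      bad <- c(bad, i)
      bad_msg <- c(bad_msg, conditionMessage(ck))
    } else {
      ids <- c(ids, id); stmts <- c(stmts, body); canon <- c(canon, ck)
    }
  }
  if (length(bad))
    bel_abort("belpipe_parse_error",
              sprintf("unparseable BEL line(s) %s in '%s': %s",
                      paste(bad, collapse = ", "), path, bad_msg[[1]]),
              lines = bad)
  data.frame(sentence_id = ids, statement = stmts, canonical = canon,
             stringsAsFactors = FALSE)
}

#' Write statements as a BEL script file
#'
#' @param statements list of `bel_statement` objects, or a data.frame with
#'   columns `sentence_id` and `statement`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bel <- function(statements, path) {
  if (is.data.frame(statements)) {
    lines <- ifelse(is.na(statements$sentence_id), statements$statement,
                    paste0(statements$sentence_id, "\t",
                           statements$statement))
  } else {
    lines <- vapply(statements, function(s) {
      body <- serialize_statement(s)
      if (is.na(s$sentence_id)) body else paste0(s$sentence_id, "\t", body)
    }, character(1))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.bel_statement <- function(x, ...) {
  cat(serialize_statement(x))
  if (isTRUE(x$adjusted)) cat("  [polarity adjusted]")
  cat("\n")
  invisible(x)
}

#' @export
format.bel_term <- function(x, ...) serialize_term(x)

#' @export
print.bel_term <- function(x, ...) {
  cat(serialize_term(x), "\n")
  invisible(x)
}
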