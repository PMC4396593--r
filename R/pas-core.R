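#' @keywords internal
"_PACKAGE"

## Fixed vocabularies for the parse substrate. The coarse POS enum is the
## granularity the entity POS filter needs (verb/adjective/preposition/number
## classes); everything else collapses to NOUN or OTHER.
POS_TAGS <- c("NOUN", "VERB", "ADJ", "PREP", "NUM", "OTHER")
PRED_KINDS <- c("VERB", "LINKING_VERB", "PREP")
EDGE_ROLES <- c("ARG1", "ARG2")
VOICES <- c("ACTIVE", "PASSIVE", "NA")

PARSE_FORMAT_NAME <- "pasrel-parse"
PARSE_FORMAT_VERSION <- 1L

empty_tokens <- function() {
  data.frame(index = integer(), surface = character(), lemma = character(),
             pos = character(), char_start = integer(), char_end = integer(),
             stringsAsFactors = FALSE)
}

empty_nps <- function() {
  data.frame(id = character(), token_start = integer(), token_end = integer(),
             head = integer(), stringsAsFactors = FALSE)
}

empty_edges <- function() {
  data.frame(predicate = integer(), pred_kind = character(), role = character(),
             arg = integer(), voice = character(), stringsAsFactors = FALSE)
}

#' Token table for a parse graph
#'
#' Builds the token block of a [parse_graph()] from parallel vectors. Character
#' offsets are 0-based half-open into the sentence text.
#'
#' @param surface Token surface forms.
#' @param lemma Lemmas; defaults to lowercased surfaces.
#' @param pos Coarse part-of-speech tags, one of
#'   `"NOUN"`, `"VERB"`, `"ADJ"`, `"PREP"`, `"NUM"`, `"OTHER"`.
#' @param char_start,char_end 0-based half-open character offsets. If omitted,
#'   offsets are computed by joining surfaces with single spaces.
#' @return A data frame with columns `index`, `surface`, `lemma`, `pos`,
#'   `char_start`, `char_end`.
#' @export
pas_tokens <- function(surface, lemma = tolower(surface), pos = "NOUN",
                       char_start = NULL, char_end = NULL) {
  n <- length(surface)
  pos <- rep_len(pos, n)
  lemma <- rep_len(lemma, n)
  if (is.null(char_start)) {
    widths <- nchar(surface)
    char_start <- c(0L, cumsum(widths + 1L))[seq_len(n)]
    char_end <- char_start + widths
  }
  data.frame(index = seq_len(n) - 1L, surface = surface, lemma = lemma,
             pos = pos, char_start = as.integer(char_start),
             char_end = as.integer(char_end), stringsAsFactors = FALSE)
}

#' Base noun-phrase spans
#'
#' @param id NP identifiers (unique within the sentence).
#' @param token_start,token_end 0-based half-open token ranges.
#' @param head Token index of the NP head; defaults to the last token.
#' @return A data frame with columns `id`, `token_start`, `token_end`, `head`.
#' @export
pas_nps <- function(id, token_start, token_end, head = token_end - 1L) {
  data.frame(id = as.character(id), token_start = as.integer(token_start),
             token_end = as.integer(token_end), head = as.integer(head),
             stringsAsFactors = FALSE)
}

#' Predicate-argument edges
#'
#' One row per (predicate, role) pair. A verbal predicate carries at most one
#' ARG1 and one ARG2 edge; a prepositional predicate exactly one of each
#' (ARG1 = modified head, ARG2 = object head). Voice is a property of the
#' ingested parse: pattern matching never re-inspects morphology.
#'
#' @param predicate Token index of the predicate.
#' @param pred_kind `"VERB"`, `"LINKING_VERB"` or `"PREP"`.
#' @param role `"ARG1"` or `"ARG2"`.
#' @param arg Token index of the argument head.
#' @param voice `"ACTIVE"`, `"PASSIVE"` or `"NA"` (non-verbal predicates).
#' @return A data frame with columns `predicate`, `pred_kind`, `role`, `arg`,
#'   `voice`.
#' @export
pas_edges <- function(predicate, pred_kind, role, arg, voice = "NA") {
  n <- length(predicate)
  data.frame(predicate = as.integer(predicate),
             pred_kind = rep_len(pred_kind, n),
             role = rep_len(role, n),
             arg = as.integer(arg),
             voice = rep_len(voice, n),
             stringsAsFactors = FALSE)
}

#' Construct a validated parse graph
#'
#' A `parse_graph` is one sentence's deep-syntax substrate: tokens with lemma
#' and coarse POS, base noun-phrase spans, and predicate-argument edges. All
#' offsets are 0-based half-open. Base NPs are unit noun phrases: no span may
#' strictly contain another.
#'
#' @param sentence_id Sentence identifier.
#' @param text Sentence text.
#' @param tokens Token table from [pas_tokens()].
#' @param nps NP table from [pas_nps()].
#' @param edges Edge table from [pas_edges()].
#' @return An object of class `parse_graph`.
#' @examples
#' g <- parse_graph("s1", "vitronectin in the connective tissue",
#'   tokens = pas_tokens(c("vitronectin", "in", "the", "connective", "tissue"),
#'                       pos = c("NOUN", "PREP", "OTHER", "ADJ", "NOUN")),
#'   nps = pas_nps(c("np1", "np2"), c(0L, 2L), c(1L, 5L), c(0L, 4L)),
#'   edges = pas_edges(c(1L, 1L), "PREP", c("ARG1", "ARG2"), c(0L, 4L)))
#' match_pattern_6(g)
#' @export
parse_graph <- function(sentence_id, text, tokens = empty_tokens(),
                        nps = empty_nps(), edges = empty_edges()) {
  g <- structure(list(sentence_id = as.character(sentence_id),
                      text = as.character(text),
                      tokens = as.data.frame(tokens),
                      nps = as.data.frame(nps),
                      edges = as.data.frame(edges)),
                 class = "parse_graph")
  validate_parse_graph(g)
}

#' @export
print.parse_graph <- function(x, ...) {
  cat(sprintf("<parse_graph %s: %d tokens, %d NPs, %d edges>\n  %s\n",
              x$sentence_id, nrow(x$tokens), nrow(x$nps), nrow(x$edges),
              x$text))
  invisible(x)
}

fail_graph <- function(id, field, msg) {
  stop(sprintf("parse_graph '%s', field '%s': %s", id, field, msg),
       call. = FALSE)
}

#' Validate a parse graph against the type invariants
#'
#' Checks token index contiguity and offset sanity, POS/edge vocabulary
#' membership, edge endpoint resolvability, per-predicate argument arity,
#' and the base-NP non-containment invariant.
#'
#' @param g A `parse_graph`.
#' @return `g`, invisibly unchanged, or an error naming the offending field.
#' @export
validate_parse_graph <- function(g) {
  id <- g$sentence_id
  tk <- g$tokens
  n <- nrow(tk)
  if (n > 0) {
    if (!identical(as.integer(tk$index), seq_len(n) - 1L))
      fail_graph(id, "tokens$index", "indices must be 0..n-1 and contiguous")
    if (any(tk$char_start >= tk$char_end))
      fail_graph(id, "tokens$char_start", "char_start must be < char_end")
    if (!all(tk$pos %in% POS_TAGS))
      fail_graph(id, "tokens$pos", paste("POS must be one of",
                                         paste(POS_TAGS, collapse = "/")))
    if (any(tk$char_end > nchar(g$text)))
      fail_graph(id, "tokens$char_end", "offset beyond sentence text")
  }
  np <- g$nps
  if (nrow(np) > 0) {
    if (anyDuplicated(np$id))
      fail_graph(id, "nps$id", "NP ids must be unique")
    if (any(np$token_start >= np$token_end))
      fail_graph(id, "nps$token_start", "empty NP span")
    if (any(np$token_start < 0L) || any(np$token_end > n))
      fail_graph(id, "nps$token_end", "NP span outside token range")
    if (any(np$head < np$token_start | np$head >= np$token_end))
      fail_graph(id, "nps$head", "head must lie within the span")
    if (nrow(np) > 1) {
      for (i in seq_len(nrow(np))) {
        strict <- (np$token_start >= np$token_start[i] &
                   np$token_end <= np$token_end[i] &
                   !(np$token_start == np$token_start[i] &
                     np$token_end == np$token_end[i]))
        if (any(strict))
          fail_graph(id, "nps", sprintf(
            "base NP '%s' contains NP '%s' (base NPs must not nest)",
            np$id[i], np$id[which(strict)[1]]))
        overlap <- (np$token_start < np$token_end[i] &
                    np$token_end > np$token_start[i])
        overlap[i] <- FALSE
        strict_eq <- np$token_start == np$token_start[i] &
          np$token_end == np$token_end[i]
        if (any(overlap & !strict_eq))
          fail_graph(id, "nps", sprintf(
            "base NPs '%s' and '%s' overlap", np$id[i],
            np$id[which(overlap & !strict_eq)[1]]))
      }
    }
  }
  ed <- g$edges
  if (nrow(ed) > 0) {
    if (!all(ed$pred_kind %in% PRED_KINDS))
      fail_graph(id, "edges$pred_kind", "unknown predicate kind")
    if (!all(ed$role %in% EDGE_ROLES))
      fail_graph(id, "edges$role", "role must be ARG1 or ARG2")
    if (!all(ed$voice %in% VOICES))
      fail_graph(id, "edges$voice", "unknown voice")
    bad <- ed$predicate < 0L | ed$predicate >= n | ed$arg < 0L | ed$arg >= n
    if (any(bad))
      fail_graph(id, "edges", "edge endpoint is not a valid token index")
    key <- paste(ed$predicate, ed$pred_kind, ed$role)
    if (anyDuplicated(key))
      fail_graph(id, "edges", "a predicate may carry at most one edge per role")
    prep <- ed[ed$pred_kind == "PREP", , drop = FALSE]
    if (nrow(prep) > 0) {
      for (p in unique(prep$predicate)) {
        roles <- sort(prep$role[prep$predicate == p])
        if (!identical(roles, c("ARG1", "ARG2")))
          fail_graph(id, "edges", sprintf(
            "PREP predicate %d needs exactly one ARG1 and one ARG2", p))
      }
    }
  }
  invisible(g)
}

graph_to_record <- function(g) {
  list(sentence_id = g$sentence_id, text = g$text,
       tokens = g$tokens, nps = g$nps, edges = g$edges)
}

record_to_graph <- function(rec, where) {
  need <- c("sentence_id", "text", "tokens", "nps", "edges")
  miss <- setdiff(need, names(rec))
  if (length(miss) > 0)
    stop(sprintf("parse record %s: missing field '%s'", where, miss[1]),
         call. = FALSE)
  as_block <- function(x, empty) {
    if (is.null(x) || (is.data.frame(x) && nrow(x) == 0) || length(x) == 0)
      return(empty)
    df <- as.data.frame(x, stringsAsFactors = FALSE)
    # JSON readers deserialize the literal voice value "NA" as missing
    if (!is.null(df$voice)) {
      v <- as.character(df$voice)
      v[is.na(v)] <- "NA"
      df$voice <- v
    }
    df
  }
  tryCatch(
    parse_graph(rec$sentence_id, rec$text,
                tokens = as_block(rec$tokens, empty_tokens()),
                nps = as_block(rec$nps, empty_nps()),
                edges = as_block(rec$edges, empty_edges())),
    error = function(e) stop(sprintf("parse record %s: %s", where,
                                     conditionMessage(e)), call. = FALSE))
}

#' Read parse graphs from the parse-interchange format
#'
#' The interchange format is newline-delimited JSON: a header record
#' `{"format": "pasrel-parse", "version": 1}` followed by one record per
#' sentence with fields `sentence_id`, `text`, `tokens`, `nps`, `edges`.
#' Every record is validated against the `parse_graph` invariants; a
#' violation is reported with the record number and field.
#'
#' @param path Path to a `.jsonl` parse file.
#' @return A list of `parse_graph` objects, input order preserved.
#' @seealso [write_parse_file()], [from_conllu()]
#' @export
read_parse_file <- function(path) {
  if (!file.exists(path)) stop("parse file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(list())
  hdr <- jsonlite::fromJSON(lines[[1]], simplifyVector = TRUE)
  if (is.null(hdr$format) || !identical(hdr$format, PARSE_FORMAT_NAME))
    stop("parse record 1: missing or unknown format header", call. = FALSE)
  if (!identical(as.integer(hdr$version), PARSE_FORMAT_VERSION))
    stop("unsupported parse format version: ", hdr$version, call. = FALSE)
  body <- lines[-1]
  lapply(seq_along(body), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(body[[i]], simplifyVector = TRUE),
                    error = function(e)
                      stop(sprintf("parse record %d: invalid JSON (%s)", i,
                                   conditionMessage(e)), call. = FALSE))
    record_to_graph(rec, as.character(i))
  })
}

#' Write parse graphs in the parse-interchange format
#'
#' @param graphs A list of `parse_graph` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parse_file <- function(graphs, path) {
  hdr <- jsonlite::toJSON(list(format = PARSE_FORMAT_NAME,
                               version = PARSE_FORMAT_VERSION),
                          auto_unbox = TRUE)
  recs <- vapply(graphs, function(g)
    as.character(jsonlite::toJSON(graph_to_record(g), dataframe = "rows",
                                  auto_unbox = TRUE, digits = NA)),
    character(1))
  writeLines(c(as.character(hdr), recs), path)
  invisible(path)
}

## Character span of an NP row, from its token range.
np_char_span <- function(g, np_row) {
  tk <- g$tokens
  c(start = tk$char_start[np_row$token_start + 1L],
    end = tk$char_end[np_row$token_end])
}

np_text <- function(g, np_row) {
  sp <- np_char_span(g, np_row)
  substr(g$text, sp[["start"]] + 1L, sp[["end"]])
}
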