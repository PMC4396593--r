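## Dictionary-based entity recognition and the two noise filters. The
## recognizer is a deterministic greedy longest-match lookup against a
## concept lexicon (surface -> concept id + semantic types), the role a
## Metathesaurus string matcher plays in the full system. String matching
## over-generates, so two post-processing filters follow: a POS filter
## (entities headed by verbs, adjectives, prepositions or numbers are
## dropped) and a corpus-frequency filter that discards overly common noun
## entities such as "study", "result" or "patients".

normalize_surface <- function(x) {
  x <- tolower(x)
  gsub("\\s+", " ", trimws(x))
}

#' Read a concept lexicon from TSV
#'
#' Expected columns: `surface`, `concept_id`, `semantic_types`
#' (pipe-separated) and optionally `source`.
#'
#' @param path Path to a tab-separated lexicon file with a header row.
#' @return A lexicon tibble.
#' @export
read_lexicon <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  need <- c("surface", "concept_id", "semantic_types")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("lexicon file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(df$source)) df$source <- "LOCAL"
  lexicon(df$surface, df$concept_id, df$semantic_types, df$source)
}

#' Build a concept lexicon
#'
#' @param surface Surface forms (matched case-insensitively).
#' @param concept_id Stable concept identifiers; synonymous surfaces share
#'   one identifier.
#' @param semantic_types One or more semantic-type labels per entry,
#'   pipe-separated.
#' @param source Originating vocabulary name.
#' @return A tibble of class `pasrel_lexicon`.
#' @examples
#' lex <- lexicon(c("Chronic Obstructive Lung Disease", "COLD"),
#'                "C0009264", "Disease or Syndrome")
#' @export
lexicon <- function(surface, concept_id, semantic_types, source = "LOCAL") {
  if (any(!nzchar(surface))) stop("lexicon surfaces must be non-empty",
                                  call. = FALSE)
  if (any(!nzchar(semantic_types)))
    stop("every lexicon entry needs at least one semantic type", call. = FALSE)
  out <- tibble::tibble(surface = as.character(surface),
                        norm = normalize_surface(surface),
                        concept_id = rep_len(as.character(concept_id),
                                             length(surface)),
                        semantic_types = rep_len(as.character(semantic_types),
                                                 length(surface)),
                        source = rep_len(as.character(source),
                                         length(surface)))
  class(out) <- c("pasrel_lexicon", class(out))
  out
}

#' Read an entity-frequency table from TSV
#'
#' Expected columns: `surface`, `count`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param threshold Frequency above which an entity counts as highly
#'   frequent; defaults to the 99.9th percentile of the counts.
#' @return A frequency table for [filter_frequency()].
#' @export
read_frequency_table <- function(path, threshold = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (!all(c("surface", "count") %in% names(df)))
    stop("frequency file needs columns surface, count", call. = FALSE)
  frequency_table(df$surface, df$count, threshold)
}

#' Build an entity-frequency table
#'
#' Maps normalized surfaces to corpus frequencies. Entities whose frequency
#' exceeds the threshold are treated as common nouns and removed by
#' [filter_frequency()]; unknown surfaces are kept.
#'
#' @param surface Entity surfaces.
#' @param count Non-negative corpus frequencies.
#' @param threshold Positive cut-off; frequencies strictly above it are
#'   "highly frequent". Defaults to the 99.9th percentile of `count`.
#' @return A tibble of class `pasrel_freq` with a `threshold` attribute.
#' @export
frequency_table <- function(surface, count, threshold = NULL) {
  count <- as.numeric(count)
  if (any(count < 0)) stop("frequencies must be >= 0", call. = FALSE)
  if (is.null(threshold))
    threshold <- if (length(count)) unname(stats::quantile(count, 0.999)) else 1
  if (threshold <= 0) stop("frequency threshold must be > 0", call. = FALSE)
  out <- tibble::tibble(norm = normalize_surface(surface), count = count)
  attr(out, "threshold") <- threshold
  class(out) <- c("pasrel_freq", class(out))
  out
}

empty_entities <- function() {
  data.frame(sentence_id = character(), char_start = integer(),
             char_end = integer(), token_start = integer(),
             token_end = integer(), surface = character(),
             concept_id = character(), semantic_types = character(),
             np_id = character(), head_pos = character(),
             stringsAsFactors = FALSE)
}

#' Detect entities by greedy longest dictionary match
#'
#' Scans left to right over token boundaries, taking at each position the
#' longest case-insensitive lexicon match; matches never overlap. Each
#' entity carries its concept identifier, semantic types, and the id of the
#' base NP containing it (NA when outside every NP).
#'
#' @param g A `parse_graph`.
#' @param lex A lexicon from [lexicon()] or [read_lexicon()].
#' @return An entity tibble with character/token spans, `concept_id`,
#'   `semantic_types`, `np_id` and the head-token POS (`head_pos`).
#' @seealso [filter_pos()], [filter_frequency()]
#' @export
detect_entities <- function(g, lex) {
  tk <- g$tokens
  n <- nrow(tk)
  out <- list()
  if (n > 0 && nrow(lex) > 0) {
    max_len <- max(lengths(strsplit(lex$norm, " ", fixed = TRUE)))
    norms <- lex$norm
    i <- 1L
    while (i <= n) {
      hit <- 0L; hit_len <- 0L
      for (len in seq_len(min(max_len, n - i + 1L))) {
        j <- i + len - 1L
        cand <- normalize_surface(substr(g$text, tk$char_start[i] + 1L,
                                         tk$char_end[j]))
        k <- match(cand, norms)
        if (!is.na(k)) { hit <- k; hit_len <- len }
      }
      if (hit > 0L) {
        j <- i + hit_len - 1L
        npr <- np_row_of_token(g, tk$index[i])
        npr2 <- np_row_of_token(g, tk$index[j])
        np_id <- if (!is.na(npr) && !is.na(npr2) && npr == npr2)
          g$nps$id[npr] else NA_character_
        out[[length(out) + 1L]] <- data.frame(
          sentence_id = g$sentence_id,
          char_start = tk$char_start[i], char_end = tk$char_end[j],
          token_start = tk$index[i], token_end = tk$index[j] + 1L,
          surface = substr(g$text, tk$char_start[i] + 1L, tk$char_end[j]),
          concept_id = lex$concept_id[hit],
          semantic_types = lex$semantic_types[hit],
          np_id = np_id, head_pos = tk$pos[j], stringsAsFactors = FALSE)
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  tibble::as_tibble(do.call(rbind, c(list(empty_entities()), out)))
}

#' Remove entities headed by verbs, adjectives, prepositions or numbers
#'
#' Dictionary matching over free text picks up predicative and numeric
#' surfaces; only noun(-phrase) entities are of interest. The head token of
#' a multi-token entity is its last token.
#'
#' @param entities An entity tibble from [detect_entities()].
#' @param g The `parse_graph` the entities came from; used to (re)resolve
#'   head POS when the `head_pos` column is absent.
#' @return The entity tibble restricted to noun-headed entities.
#' @export
filter_pos <- function(entities, g = NULL) {
  if (nrow(entities) == 0) return(entities)
  hp <- entities$head_pos
  if (is.null(hp)) {
    if (is.null(g)) stop("entities lack head_pos and no parse graph given",
                         call. = FALSE)
    hp <- vapply(entities$token_end, function(te) {
      if (te < 1 || te > nrow(g$tokens))
        stop("entity cannot be aligned to the parse graph tokens",
             call. = FALSE)
      g$tokens$pos[te]
    }, character(1))
  }
  entities[!(hp %in% c("VERB", "ADJ", "PREP", "NUM")), , drop = FALSE]
}

#' Remove highly frequent (common-noun) entities
#'
#' Entities whose normalized surface occurs in the frequency table with a
#' count above the table's threshold are discarded; surfaces absent from the
#' table are kept.
#'
#' @param entities An entity tibble.
#' @param ft A frequency table from [frequency_table()].
#' @return The filtered entity tibble.
#' @export
filter_frequency <- function(entities, ft) {
  if (nrow(entities) == 0 || nrow(ft) == 0) return(entities)
  thr <- attr(ft, "threshold")
  cnt <- ft$count[match(normalize_surface(entities$surface), ft$norm)]
  drop <- !is.na(cnt) & cnt > thr
  entities[!drop, , drop = FALSE]
}

#' Write entities as BRAT-style standoff annotations
#'
#' One `T` line per entity: `Tn<TAB>Type start end<TAB>surface`, using the
#' first semantic type as the annotation type (spaces become underscores).
#'
#' @param entities An entity tibble for a single sentence/document.
#' @param path Output `.ann` path.
#' @return `path`, invisibly.
#' @export
write_ann <- function(entities, path) {
  lines <- character(nrow(entities))
  for (i in seq_len(nrow(entities))) {
    type <- gsub("[ ,]+", "_", strsplit(entities$semantic_types[i], "|",
                                        fixed = TRUE)[[1]][1])
    lines[i] <- sprintf("T%d\t%s %d %d\t%s", i, type,
                        entities$char_start[i], entities$char_end[i],
                        entities$surface[i])
  }
  writeLines(lines, path)
  invisible(path)
}
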