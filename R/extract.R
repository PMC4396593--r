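## Candidate generation and the semantic-network constraint. Extraction is
## deliberately greedy and recall-first: every entity in NP1 is coupled with
## every entity in NP2, and a candidate survives iff some pair of the two
## entities' semantic types is permitted by the type network. Entities within
## a single NP never form a relation with each other.

#' Build a semantic-type network
#'
#' The set of permitted semantic-type pairs used as the final relation
#' filter. By default the check is order-insensitive (a candidate passes if
#' `(s1, s2)` or `(s2, s1)` is listed), maximizing recall; set
#' `directed = TRUE` for a strict ordered check.
#'
#' @param s1,s2 Semantic-type labels, one permitted pair per position.
#' @param directed Require the ordered pair `(s1, s2)` exactly?
#' @return A tibble of class `pasrel_semnet` with a `directed` attribute.
#' @examples
#' net <- semantic_network("Gene or Genome", "Enzyme")
#' semnet_allows("Gene or Genome", "Enzyme", net)
#' @export
semantic_network <- function(s1 = character(), s2 = character(),
                             directed = FALSE) {
  out <- tibble::tibble(s1 = as.character(s1), s2 = as.character(s2))
  out <- out[!duplicated(paste(out$s1, out$s2, sep = "\r")), ]
  attr(out, "directed") <- isTRUE(directed)
  class(out) <- c("pasrel_semnet", class(out))
  out
}

#' Read a semantic-type network from TSV
#'
#' Expected columns: `s1`, `s2` (one permitted pair per row).
#'
#' @param path Path to a tab-separated file with a header row.
#' @param directed Passed to [semantic_network()].
#' @return A `pasrel_semnet`.
#' @export
read_semnet <- function(path, directed = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (!all(c("s1", "s2") %in% names(df)))
    stop("semantic network file needs columns s1, s2", call. = FALSE)
  semantic_network(df$s1, df$s2, directed = directed)
}

split_types <- function(x) strsplit(x, "|", fixed = TRUE)[[1]]

#' Does the semantic network permit an entity pair?
#'
#' True iff some combination of a type of entity 1 and a type of entity 2 is
#' a permitted pair. Entities with multiple semantic types pass if ANY
#' combination is permitted.
#'
#' @param types1,types2 Semantic types of the two entities, as a character
#'   vector or a single pipe-separated string.
#' @param net A `pasrel_semnet`.
#' @return A logical scalar.
#' @export
semnet_allows <- function(types1, types2, net) {
  if (nrow(net) == 0) return(FALSE)
  if (length(types1) == 1 && grepl("|", types1, fixed = TRUE))
    types1 <- split_types(types1)
  if (length(types2) == 1 && grepl("|", types2, fixed = TRUE))
    types2 <- split_types(types2)
  combos <- expand.grid(t1 = types1, t2 = types2, stringsAsFactors = FALSE)
  keys <- paste(net$s1, net$s2, sep = "\r")
  fwd <- paste(combos$t1, combos$t2, sep = "\r") %in% keys
  if (attr(net, "directed")) return(any(fwd))
  rev <- paste(combos$t2, combos$t1, sep = "\r") %in% keys
  any(fwd | rev)
}

empty_relations <- function() {
  data.frame(sentence_id = character(), pattern_ids = character(),
             relation_phrase = character(),
             e1_surface = character(), e1_concept_id = character(),
             e1_types = character(), e1_start = integer(), e1_end = integer(),
             e2_surface = character(), e2_concept_id = character(),
             e2_types = character(), e2_start = integer(), e2_end = integer(),
             stringsAsFactors = FALSE)
}

#' Generate candidate entity pairs for one NP pair
#'
#' Full cross product of the entities assigned to NP1 with those assigned to
#' NP2. Separate entities inside one NP never form a candidate.
#'
#' @param pair A single-row NP-pair tibble (one row of [match_all()] output).
#' @param entities An entity tibble for the same sentence.
#' @return A tibble with one row per candidate, columns `e1_*` and `e2_*`.
#' @export
generate_candidates <- function(pair, entities) {
  stopifnot(nrow(pair) == 1)
  in_np <- function(np_id) entities[!is.na(entities$np_id) &
                                      entities$np_id == np_id, , drop = FALSE]
  e1 <- in_np(pair$np1_id)
  e2 <- in_np(pair$np2_id)
  if (nrow(e1) == 0 || nrow(e2) == 0) {
    out <- empty_relations()
    return(tibble::as_tibble(out))
  }
  grid <- expand.grid(i = seq_len(nrow(e1)), j = seq_len(nrow(e2)))
  tibble::tibble(
    sentence_id = pair$sentence_id,
    pattern_ids = as.character(pair$pattern_id),
    relation_phrase = pair$relation_phrase,
    e1_surface = e1$surface[grid$i], e1_concept_id = e1$concept_id[grid$i],
    e1_types = e1$semantic_types[grid$i],
    e1_start = e1$char_start[grid$i], e1_end = e1$char_end[grid$i],
    e2_surface = e2$surface[grid$j], e2_concept_id = e2$concept_id[grid$j],
    e2_types = e2$semantic_types[grid$j],
    e2_start = e2$char_start[grid$j], e2_end = e2$char_end[grid$j])
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Extract relations end-to-end
#'
#' Composition of the full pipeline: pattern matching over every sentence,
#' dictionary entity recognition, POS and frequency filtering, greedy
#' candidate generation, and the semantic-network check. Output is
#' deduplicated on (entity-1 span, relation phrase, entity-2 span) within a
#' sentence; a relation licensed by several patterns keeps all pattern ids
#' (comma-separated).
#'
#' @param parses A list of `parse_graph` objects (or a single graph).
#' @param lex A lexicon ([lexicon()]).
#' @param freq A frequency table ([frequency_table()]), or `NULL` to skip
#'   the frequency filter.
#' @param net A semantic network ([semantic_network()]).
#' @return A relation tibble: one row per extracted
#'   (entity 1, relation phrase, entity 2) triple with spans, concept ids,
#'   semantic types and provenance.
#' @examples
#' fx <- paper_fixtures()
#' extract_relations(fx$parses$balf, fx$lexicon, fx$freq, fx$semnet)
#' @export
extract_relations <- function(parses, lex, freq, net) {
  if (inherits(parses, "parse_graph")) parses <- list(parses)
  per_sentence <- lapply(parses, function(g) {
    pairs <- with_stage("pattern_matcher", match_all(g))
    ents <- with_stage("entity_layer", {
      e <- detect_entities(g, lex)
      e <- filter_pos(e, g)
      if (!is.null(freq)) e <- filter_frequency(e, freq)
      e
    })
    if (nrow(pairs) == 0 || nrow(ents) == 0) return(empty_relations())
    cands <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
      as.data.frame(generate_candidates(pairs[i, ], ents))))
    if (nrow(cands) == 0) return(empty_relations())
    keep <- vapply(seq_len(nrow(cands)), function(i)
      with_stage("semnet_filter",
                 semnet_allows(cands$e1_types[i], cands$e2_types[i], net)),
      logical(1))
    cands[keep, , drop = FALSE]
  })
  out <- do.call(rbind, c(list(empty_relations()), per_sentence))
  if (nrow(out) == 0) return(tibble::as_tibble(out))
  key <- paste(out$sentence_id, out$e1_start, out$e1_end, out$relation_phrase,
               out$e2_start, out$e2_end, sep = "\r")
  merged <- lapply(split(seq_len(nrow(out)), factor(key, levels = unique(key))),
                   function(ix) {
    row <- out[ix[1], , drop = FALSE]
    row$pattern_ids <- paste(sort(unique(unlist(
      strsplit(out$pattern_ids[ix], ",", fixed = TRUE)))), collapse = ",")
    row
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$sentence_id, out$e1_start, out$e2_start,
                   out$relation_phrase), ]
  rownames(out) <- NULL
  tibble::as_tibble(out)
}

#' Write extracted relations as TSV
#'
#' @param relations A relation tibble from [extract_relations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_relations <- function(relations, path) {
  utils::write.table(relations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
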