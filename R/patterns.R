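## The six predicate-argument patterns. Each matcher walks a parse_graph and
## emits relevant NP pairs <NP1, NP2> together with the relation phrase
## assembled from the licensing predicate tokens. Patterns 1/2 cover
## transitive verbs in active and passive voice, 3 light-verb constructions
## ("play a role in"), 4 linking verb + adjective + preposition, 5
## intransitive verb + preposition, and 6 bare prepositions (localization and
## whole-part expressions). Voice is read off the edges; passivization was
## the ingester's job.

empty_pairs <- function() {
  data.frame(sentence_id = character(), pattern_id = integer(),
             np1_id = character(), np2_id = character(),
             np1_start = integer(), np1_end = integer(), np1_text = character(),
             np2_start = integer(), np2_end = integer(), np2_text = character(),
             relation_phrase = character(), stringsAsFactors = FALSE)
}

## NP row index containing a token index, or NA
np_row_of_token <- function(g, tok) {
  np <- g$nps
  hit <- which(np$token_start <= tok & tok < np$token_end)
  if (length(hit) == 0) NA_integer_ else hit[1]
}

pair_row <- function(g, pattern_id, np1, np2, phrase) {
  np <- g$nps
  s1 <- np_char_span(g, np[np1, ]); s2 <- np_char_span(g, np[np2, ])
  data.frame(sentence_id = g$sentence_id, pattern_id = as.integer(pattern_id),
             np1_id = np$id[np1], np2_id = np$id[np2],
             np1_start = unname(s1[["start"]]), np1_end = unname(s1[["end"]]),
             np1_text = np_text(g, np[np1, ]),
             np2_start = unname(s2[["start"]]), np2_end = unname(s2[["end"]]),
             np2_text = np_text(g, np[np2, ]),
             relation_phrase = phrase, stringsAsFactors = FALSE)
}

bind_pairs <- function(rows) {
  if (length(rows) == 0) return(tibble::as_tibble(empty_pairs()))
  tibble::as_tibble(do.call(rbind, rows))
}

## verbal predicates with their ARG1/ARG2 argument token (NA if absent)
verb_frames <- function(g, kind = "VERB") {
  ed <- g$edges[g$edges$pred_kind == kind, , drop = FALSE]
  if (nrow(ed) == 0)
    return(data.frame(predicate = integer(), voice = character(),
                      arg1 = integer(), arg2 = integer()))
  preds <- unique(ed$predicate)
  do.call(rbind, lapply(preds, function(p) {
    sub <- ed[ed$predicate == p, , drop = FALSE]
    a1 <- sub$arg[sub$role == "ARG1"]; a2 <- sub$arg[sub$role == "ARG2"]
    data.frame(predicate = p, voice = sub$voice[1],
               arg1 = if (length(a1)) a1[1] else NA_integer_,
               arg2 = if (length(a2)) a2[1] else NA_integer_)
  }))
}

## prepositional predicates as (predicate token, arg1 token, arg2 token)
prep_frames <- function(g) {
  ed <- g$edges[g$edges$pred_kind == "PREP", , drop = FALSE]
  if (nrow(ed) == 0)
    return(data.frame(predicate = integer(), arg1 = integer(),
                      arg2 = integer()))
  preds <- unique(ed$predicate)
  do.call(rbind, lapply(preds, function(p) {
    sub <- ed[ed$predicate == p, , drop = FALSE]
    data.frame(predicate = p, arg1 = sub$arg[sub$role == "ARG1"][1],
               arg2 = sub$arg[sub$role == "ARG2"][1])
  }))
}

tok_surface <- function(g, i) g$tokens$surface[i + 1L]
tok_lemma <- function(g, i) g$tokens$lemma[i + 1L]
tok_pos <- function(g, i) g$tokens$pos[i + 1L]

#' Match pattern 1: transitive verb, active voice
#'
#' `NP1 <- Verb -> NP2`: one pair per active verbal predicate whose ARG1 and
#' ARG2 heads each lie inside a base NP. The relation phrase is the verb
#' lemma.
#'
#' @param g A `parse_graph`.
#' @return A tibble of NP pairs (possibly empty) with columns `sentence_id`,
#'   `pattern_id`, NP ids/character spans/texts and `relation_phrase`.
#' @export
match_pattern_1 <- function(g) {
  vf <- verb_frames(g)
  rows <- list()
  for (i in seq_len(nrow(vf))) {
    f <- vf[i, ]
    if (f$voice != "ACTIVE" || is.na(f$arg1) || is.na(f$arg2)) next
    np1 <- np_row_of_token(g, f$arg1); np2 <- np_row_of_token(g, f$arg2)
    if (is.na(np1) || is.na(np2) || np1 == np2) next
    rows[[length(rows) + 1L]] <- pair_row(g, 1L, np1, np2,
                                          tok_lemma(g, f$predicate))
  }
  bind_pairs(rows)
}

#' Match pattern 2: transitive verb, passive voice
#'
#' `NP1 <- Verb -> by + NP2`: NP1 holds the surface subject (the deep ARG2),
#' NP2 the agent. The agent slot is filled either by a deep ARG1 edge on the
#' passive verb (phrase: lemma + " by") or, for agentless passives, by a
#' prepositional predicate attached to the verb (phrase: lemma + preposition),
#' which covers expressions like "measured in" and "increased following".
#'
#' @inheritParams match_pattern_1
#' @return A tibble of NP pairs.
#' @export
match_pattern_2 <- function(g) {
  vf <- verb_frames(g)
  pf <- prep_frames(g)
  rows <- list()
  for (i in seq_len(nrow(vf))) {
    f <- vf[i, ]
    if (f$voice != "PASSIVE" || is.na(f$arg2)) next
    np1 <- np_row_of_token(g, f$arg2)
    if (is.na(np1)) next
    if (!is.na(f$arg1)) {
      np2 <- np_row_of_token(g, f$arg1)
      if (!is.na(np2) && np2 != np1)
        rows[[length(rows) + 1L]] <- pair_row(g, 2L, np1, np2,
          paste(tok_lemma(g, f$predicate), "by"))
    } else {
      att <- pf[pf$arg1 == f$predicate, , drop = FALSE]
      for (j in seq_len(nrow(att))) {
        np2 <- np_row_of_token(g, att$arg2[j])
        if (is.na(np2) || np2 == np1) next
        rows[[length(rows) + 1L]] <- pair_row(g, 2L, np1, np2,
          paste(tok_lemma(g, f$predicate), tok_surface(g, att$predicate[j])))
      }
    }
  }
  bind_pairs(rows)
}

#' Match pattern 3: transitive verb with a modified object NP
#'
#' `NP1 <- Verb -> NP' <- Prep -> NP2`: light-verb and support-verb
#' constructions such as "play a role in" or "have an effect on". The object
#' NP' is intermediate only; the emitted pair is (NP1, NP2) and the relation
#' phrase is verb lemma + NP' head + preposition.
#'
#' @inheritParams match_pattern_1
#' @return A tibble of NP pairs.
#' @export
match_pattern_3 <- function(g) {
  vf <- verb_frames(g)
  pf <- prep_frames(g)
  np <- g$nps
  rows <- list()
  for (i in seq_len(nrow(vf))) {
    f <- vf[i, ]
    if (f$voice != "ACTIVE" || is.na(f$arg1) || is.na(f$arg2)) next
    np1 <- np_row_of_token(g, f$arg1)
    npi <- np_row_of_token(g, f$arg2)     # NP'
    if (is.na(np1) || is.na(npi) || np1 == npi) next
    for (j in seq_len(nrow(pf))) {
      a1 <- pf$arg1[j]
      if (a1 < np$token_start[npi] || a1 >= np$token_end[npi]) next
      np2 <- np_row_of_token(g, pf$arg2[j])
      if (is.na(np2) || np2 == npi || np2 == np1) next
      phrase <- paste(tok_lemma(g, f$predicate),
                      tok_surface(g, np$head[npi]),
                      tok_surface(g, pf$predicate[j]))
      rows[[length(rows) + 1L]] <- pair_row(g, 3L, np1, np2, phrase)
    }
  }
  bind_pairs(rows)
}

#' Match pattern 4: linking verb with adjectival complement
#'
#' `NP1 <- Link.Verb -> ADJ <- Prep -> NP2`: e.g. "EPO receptor be present in
#' epithelial cells". The complement must be adjectival; nominal complements
#' do not match. The relation phrase is linking-verb lemma + adjective +
#' preposition.
#'
#' @inheritParams match_pattern_1
#' @return A tibble of NP pairs.
#' @export
match_pattern_4 <- function(g) {
  vf <- verb_frames(g, kind = "LINKING_VERB")
  pf <- prep_frames(g)
  rows <- list()
  for (i in seq_len(nrow(vf))) {
    f <- vf[i, ]
    if (is.na(f$arg1) || is.na(f$arg2)) next
    if (tok_pos(g, f$arg2) != "ADJ") next
    np1 <- np_row_of_token(g, f$arg1)
    if (is.na(np1)) next
    att <- pf[pf$arg1 == f$arg2, , drop = FALSE]
    for (j in seq_len(nrow(att))) {
      np2 <- np_row_of_token(g, att$arg2[j])
      if (is.na(np2) || np2 == np1) next
      phrase <- paste(tok_lemma(g, f$predicate), tok_surface(g, f$arg2),
                      tok_surface(g, att$predicate[j]))
      rows[[length(rows) + 1L]] <- pair_row(g, 4L, np1, np2, phrase)
    }
  }
  bind_pairs(rows)
}

#' Match pattern 5: intransitive verb with prepositional phrase
#'
#' `NP1 <- Verb <- Prep -> NP2`: the verb has a subject but no direct object,
#' and a prepositional predicate modifies the verb. The relation phrase is
#' verb lemma + preposition. Transitive uses are handled by patterns 1/3;
#' passives by pattern 2.
#'
#' @inheritParams match_pattern_1
#' @return A tibble of NP pairs.
#' @export
match_pattern_5 <- function(g) {
  vf <- verb_frames(g)
  pf <- prep_frames(g)
  rows <- list()
  for (i in seq_len(nrow(vf))) {
    f <- vf[i, ]
    if (f$voice == "PASSIVE" || is.na(f$arg1) || !is.na(f$arg2)) next
    np1 <- np_row_of_token(g, f$arg1)
    if (is.na(np1)) next
    att <- pf[pf$arg1 == f$predicate, , drop = FALSE]
    for (j in seq_len(nrow(att))) {
      np2 <- np_row_of_token(g, att$arg2[j])
      if (is.na(np2) || np2 == np1) next
      phrase <- paste(tok_lemma(g, f$predicate),
                      tok_surface(g, att$predicate[j]))
      rows[[length(rows) + 1L]] <- pair_row(g, 5L, np1, np2, phrase)
    }
  }
  bind_pairs(rows)
}

#' Match pattern 6: bare preposition between noun phrases
#'
#' `NP1 <- Prep -> NP2`: captures localization and whole-part expressions
#' such as "vitronectin in the connective tissue". The preposition must
#' modify a noun inside a base NP; prepositions modifying verbs or adjectives
#' belong to patterns 5 and 4. The relation phrase is the preposition
#' surface.
#'
#' @inheritParams match_pattern_1
#' @return A tibble of NP pairs.
#' @export
match_pattern_6 <- function(g) {
  pf <- prep_frames(g)
  rows <- list()
  for (j in seq_len(nrow(pf))) {
    a1 <- pf$arg1[j]
    if (tok_pos(g, a1) != "NOUN") next
    np1 <- np_row_of_token(g, a1)
    np2 <- np_row_of_token(g, pf$arg2[j])
    if (is.na(np1) || is.na(np2) || np1 == np2) next
    rows[[length(rows) + 1L]] <- pair_row(g, 6L, np1, np2,
                                          tok_surface(g, pf$predicate[j]))
  }
  bind_pairs(rows)
}

#' Match all six patterns
#'
#' Union of patterns 1-6, deduplicated on (NP1, NP2, relation phrase) and
#' ordered by (pattern id, NP1 position, NP2 position). Overlapping patterns
#' all fire; no precedence is imposed.
#'
#' @inheritParams match_pattern_1
#' @return A tibble of NP pairs.
#' @export
match_all <- function(g) {
  out <- rbind(match_pattern_1(g), match_pattern_2(g), match_pattern_3(g),
               match_pattern_4(g), match_pattern_5(g), match_pattern_6(g))
  out <- out[order(out$pattern_id, out$np1_start, out$np2_start), ]
  key <- paste(out$np1_id, out$np2_id, out$relation_phrase, sep = "\r")
  out <- out[!duplicated(key), ]
  rownames(out) <- NULL
  tibble::as_tibble(out)
}

#' Match patterns over a list of parse graphs
#'
#' @param graphs A list of `parse_graph` objects.
#' @return A tibble of NP pairs across all sentences.
#' @export
match_corpus <- function(graphs) {
  tibble::as_tibble(do.call(rbind, c(list(empty_pairs()),
                                     lapply(graphs, match_all))))
}
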