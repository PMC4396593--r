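## CoNLL-U ingestion: a deterministic mapping from Universal Dependencies
## surface trees into the predicate-argument substrate. This replaces a deep
## parser only to the extent the six patterns need: verbal argument edges
## with voice, copular constructions, case-marked obliques/nominal modifiers
## as prepositional predicates, and maximal non-nested noun projections as
## base NPs.

UPOS_MAP <- c(NOUN = "NOUN", PROPN = "NOUN", PRON = "NOUN",
              VERB = "VERB", AUX = "VERB",
              ADJ = "ADJ", ADP = "PREP", NUM = "NUM")

## deprels that keep a dependent inside its head's base NP
NP_INTERNAL <- c("det", "amod", "compound", "nummod", "flat", "fixed")

DEFAULT_LINKING_VERBS <- c("be", "seem", "appear", "become", "remain")

split_conllu_sentences <- function(lines) {
  lines <- lines[!grepl("^#", lines)]
  groups <- list()
  cur <- character()
  for (ln in lines) {
    if (nzchar(trimws(ln))) cur <- c(cur, ln)
    else if (length(cur) > 0) { groups[[length(groups) + 1L]] <- cur; cur <- character() }
  }
  if (length(cur) > 0) groups[[length(groups) + 1L]] <- cur
  groups
}

parse_conllu_rows <- function(sent_lines) {
  fields <- strsplit(sent_lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) grepl("^[0-9]+$", f[[1]]), logical(1))
  fields <- fields[keep]
  if (length(fields) == 0) return(NULL)
  bad <- vapply(fields, length, integer(1)) < 8
  if (any(bad))
    stop("CoNLL-U record: missing UPOS/HEAD/DEPREL columns", call. = FALSE)
  data.frame(
    id = vapply(fields, function(f) as.integer(f[[1]]), integer(1)),
    form = vapply(fields, `[[`, character(1), 2),
    lemma = vapply(fields, `[[`, character(1), 3),
    upos = vapply(fields, `[[`, character(1), 4),
    head = vapply(fields, function(f) as.integer(f[[7]]), integer(1)),
    deprel = vapply(fields, `[[`, character(1), 8),
    misc = vapply(fields, function(f) if (length(f) >= 10) f[[10]] else "_",
                  character(1)),
    stringsAsFactors = FALSE)
}

#' Read a CoNLL-U file into parse graphs
#'
#' @param path Path to a CoNLL-U file (UPOS and DEPREL columns required).
#' @param sentence_ids Optional ids; defaults to `s1`, `s2`, ...
#' @param linking_verbs Lemmas treated as copular/linking verbs.
#' @return A list of `parse_graph` objects.
#' @export
read_conllu <- function(path, sentence_ids = NULL,
                        linking_verbs = DEFAULT_LINKING_VERBS) {
  groups <- split_conllu_sentences(readLines(path, warn = FALSE))
  if (is.null(sentence_ids)) sentence_ids <- paste0("s", seq_along(groups))
  Map(function(g, id) from_conllu(g, sentence_id = id,
                                  linking_verbs = linking_verbs),
      groups, sentence_ids)
}

#' Map one CoNLL-U sentence to a parse graph
#'
#' The mapping is deterministic:
#' * `nsubj`/`obj` dependents of a verb become ARG1/ARG2 edges (ACTIVE voice);
#' * `nsubj:pass` becomes the ARG2 (deep object) of a PASSIVE verb, and an
#'   `obl:agent` (or by-marked `obl`) becomes its deep ARG1;
#' * every case-marked `obl`/`nmod` yields a PREP predicate whose ARG1 is the
#'   modified head and ARG2 the oblique/nominal head;
#' * a copula over an adjectival predicate yields a LINKING_VERB predicate
#'   with the subject as ARG1 and the adjective as ARG2;
#' * maximal non-nested noun projections (a noun head plus its contiguous
#'   det/amod/compound/nummod/flat/fixed dependents) become base NP spans.
#'
#' @param x A character vector of CoNLL-U lines for one sentence.
#' @param sentence_id Sentence identifier.
#' @param linking_verbs Lemmas treated as copular/linking verbs.
#' @return A `parse_graph`.
#' @export
from_conllu <- function(x, sentence_id = "s1",
                        linking_verbs = DEFAULT_LINKING_VERBS) {
  rows <- parse_conllu_rows(x)
  if (is.null(rows))
    return(parse_graph(sentence_id, ""))
  if (any(rows$upos == "_" | !nzchar(rows$upos)))
    stop("CoNLL-U record: missing UPOS column", call. = FALSE)
  n <- nrow(rows)
  if (!identical(rows$id, seq_len(n)))
    stop("CoNLL-U record: token ids must be contiguous 1..n", call. = FALSE)

  no_space <- grepl("SpaceAfter=No", rows$misc, fixed = TRUE)
  starts <- integer(n); pos_cursor <- 0L
  text <- ""
  for (i in seq_len(n)) {
    starts[i] <- pos_cursor
    text <- paste0(text, rows$form[i])
    pos_cursor <- pos_cursor + nchar(rows$form[i])
    if (i < n && !no_space[i]) { text <- paste0(text, " "); pos_cursor <- pos_cursor + 1L }
  }
  pos <- unname(UPOS_MAP[rows$upos])
  pos[is.na(pos)] <- "OTHER"
  tokens <- data.frame(index = seq_len(n) - 1L, surface = rows$form,
                       lemma = rows$lemma, pos = pos, char_start = starts,
                       char_end = starts + nchar(rows$form),
                       stringsAsFactors = FALSE)

  ## 1-based CoNLL ids -> 0-based token indices
  tid <- function(i) i - 1L
  children <- function(h, rel = NULL) {
    sel <- rows$head == h
    if (!is.null(rel)) sel <- sel & rows$deprel %in% rel
    rows$id[sel]
  }
  base_rel <- sub(":.*$", "", rows$deprel)

  edges <- empty_edges()
  add_edge <- function(predicate, kind, role, arg, voice = "NA") {
    edges[nrow(edges) + 1L, ] <<- list(tid(predicate), kind, role, tid(arg), voice)
  }

  nounish <- rows$upos %in% c("NOUN", "PROPN", "PRON")
  is_verb <- rows$upos %in% c("VERB")

  has_by_case <- function(d)
    any(rows$lemma[rows$head == d & rows$deprel == "case"] == "by")

  for (v in rows$id[is_verb]) {
    subj <- children(v, "nsubj")
    pass_subj <- children(v, "nsubj:pass")
    obj <- children(v, "obj")
    obls <- rows$id[rows$head == v & base_rel == "obl"]
    agent <- obls[rows$deprel[obls] == "obl:agent" |
                    vapply(obls, has_by_case, logical(1))]
    passive <- length(pass_subj) > 0
    voice <- if (passive) "PASSIVE" else "ACTIVE"
    if (passive) {
      add_edge(v, "VERB", "ARG2", pass_subj[1], voice)
      if (length(agent) > 0) add_edge(v, "VERB", "ARG1", agent[1], voice)
    } else {
      if (length(subj) > 0) add_edge(v, "VERB", "ARG1", subj[1], voice)
      if (length(obj) > 0) add_edge(v, "VERB", "ARG2", obj[1], voice)
    }
  }

  ## copular constructions: cop child under a predicate head
  for (h in rows$id) {
    cops <- children(h, "cop")
    cops <- cops[rows$lemma[cops] %in% linking_verbs]
    if (length(cops) == 0) next
    subj <- children(h, "nsubj")
    if (length(subj) == 0) next
    if (rows$upos[h] == "ADJ") {
      add_edge(cops[1], "LINKING_VERB", "ARG1", subj[1])
      add_edge(cops[1], "LINKING_VERB", "ARG2", h)
    }
  }

  ## case-marked obliques and nominal modifiers -> PREP predicates
  for (d in rows$id) {
    if (!(base_rel[d] %in% c("obl", "nmod"))) next
    if (d %in% children(rows$head[d], "obl:agent")) next
    cases <- children(d, "case")
    cases <- cases[rows$upos[cases] == "ADP"]
    if (length(cases) == 0) next
    h <- rows$head[d]
    if (h == 0) next
    if (base_rel[d] == "obl" && rows$upos[h] == "VERB" &&
        any(rows$lemma[cases] == "by") && length(children(h, "nsubj:pass")) > 0)
      next  # consumed as the passive agent above
    add_edge(cases[1], "PREP", "ARG1", h)
    add_edge(cases[1], "PREP", "ARG2", d)
  }

  ## base NPs: noun heads not NP-internal to another noun
  head_is_noun <- rows$head >= 1 & nounish[pmax(rows$head, 1L)]
  np_head <- nounish & !(rows$deprel %in% NP_INTERNAL & head_is_noun)
  nps <- empty_nps()
  for (h in rows$id[np_head]) {
    members <- h
    repeat {
      more <- rows$id[rows$head %in% members & rows$deprel %in% NP_INTERNAL]
      more <- setdiff(more, members)
      if (length(more) == 0) break
      members <- c(members, more)
    }
    members <- sort(members)
    lo <- min(members); hi <- max(members)
    ## clip to the contiguous block around the head if interlopers intrude
    if (!all(lo:hi %in% members)) {
      blocks <- split(members, cumsum(c(1, diff(members) != 1)))
      members <- blocks[[which(vapply(blocks, function(b) h %in% b, logical(1)))]]
      lo <- min(members); hi <- max(members)
    }
    nps[nrow(nps) + 1L, ] <- list(paste0("np", nrow(nps) + 1L),
                                  tid(lo), tid(hi) + 1L, tid(h))
  }

  parse_graph(sentence_id, text, tokens = tokens, nps = nps, edges = edges)
}
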