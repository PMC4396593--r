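## Seeded synthetic-corpus generator. Every sentence instantiates exactly one
## pattern template with planted entities, so the gold NP pairs and gold
## relations are known by construction and the whole pipeline is testable
## without licensed resources. Surface text is template-filled
## pseudo-biomedical vocabulary: only the structure matters to the pipeline,
## so no attempt is made at fluency.

SYN_TYPE_POOL <- c("Amino Acid, Peptide or Protein", "Gene or Genome",
                   "Cell", "Disease or Syndrome", "Organic Chemical",
                   "Enzyme", "Hormone",
                   "Body Part, Organ, or Organ Component")

SYN_VERBS <- c("activate", "inhibit", "induce", "regulate", "modulate",
               "suppress")
SYN_PREPS <- c("in", "of", "with", "on", "at")
SYN_MODIFIERS <- c("beta", "gamma", "delta", "zeta")

#' Configuration for the synthetic-corpus generator
#'
#' @param n_sentences Number of sentences to generate.
#' @param pattern_mix Probability of each pattern 1-6 per sentence; must be
#'   non-negative and sum to 1.
#' @param entities_per_np Integer `c(min, max)`: entities planted per NP,
#'   sampled uniformly.
#' @param fraction_overfrequent Fraction of lexicon entries marked as highly
#'   frequent (removed by the frequency filter, hence excluded from gold).
#' @param fraction_type_pair_allowed Probability that an unordered semantic
#'   type pair is permitted by the generated network.
#' @param fraction_decoy Probability that an NP additionally carries an
#'   adjective decoy entity (in the lexicon, removed by the POS filter).
#' @param n_lexicon Number of noun concept entries in the generated lexicon.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `pasrel_gen_config`.
#' @export
gen_config <- function(n_sentences = 50, pattern_mix = rep(1 / 6, 6),
                       entities_per_np = c(1L, 3L),
                       fraction_overfrequent = 0.15,
                       fraction_type_pair_allowed = 0.5,
                       fraction_decoy = 0.1,
                       n_lexicon = 40, seed = 1L) {
  if (length(pattern_mix) != 6 || any(pattern_mix < 0))
    stop("pattern_mix must be six non-negative probabilities", call. = FALSE)
  if (sum(pattern_mix) == 0)
    stop("degenerate pattern_mix: all probabilities are zero", call. = FALSE)
  pattern_mix <- pattern_mix / sum(pattern_mix)
  structure(list(n_sentences = as.integer(n_sentences),
                 pattern_mix = pattern_mix,
                 entities_per_np = as.integer(entities_per_np),
                 fraction_overfrequent = fraction_overfrequent,
                 fraction_type_pair_allowed = fraction_type_pair_allowed,
                 fraction_decoy = fraction_decoy,
                 n_lexicon = as.integer(n_lexicon),
                 seed = as.integer(seed)),
            class = "pasrel_gen_config")
}

## sentence assembler: tokens as list of (surface, pos, lemma), NP specs as
## token ranges, edges as lists; returns parse_graph plus planted-entity
## char spans
assemble_sentence <- function(sid, toks, np_specs, edge_specs) {
  surface <- vapply(toks, `[[`, character(1), "surface")
  pos <- vapply(toks, `[[`, character(1), "pos")
  lemma <- vapply(toks, function(t) {
    if (is.null(t$lemma)) tolower(t$surface) else t$lemma
  }, character(1))
  tokens <- pas_tokens(surface, lemma = lemma, pos = pos)
  nps <- do.call(rbind, lapply(np_specs, function(s)
    pas_nps(s$id, s$start, s$end, s$head)))
  edges <- if (length(edge_specs) == 0) empty_edges() else
    do.call(rbind, lapply(edge_specs, function(e)
      pas_edges(e$predicate, e$kind, e$role, e$arg,
                if (is.null(e$voice)) "NA" else e$voice)))
  text <- paste(surface, collapse = " ")
  parse_graph(sid, text, tokens = tokens, nps = nps, edges = edges)
}

tok <- function(surface, pos = "NOUN", lemma = NULL)
  list(surface = surface, pos = pos, lemma = lemma)

#' Generate a synthetic corpus with known gold structure
#'
#' Produces parse graphs, a concept lexicon, a frequency table, a semantic
#' network, the gold NP pair per sentence, and the gold relation set. Gold
#' relations are exactly the candidate entity pairs that survive both noise
#' filters and whose semantic-type pair is permitted, computed from the
#' generator's own bookkeeping; running [extract_relations()] on the
#' generated inputs must reproduce them exactly.
#'
#' @param cfg A [gen_config()].
#' @return A list with elements `parses`, `lexicon`, `freq`, `semnet`,
#'   `gold_pairs`, `gold_relations`, `config`.
#' @export
generate_corpus <- function(cfg = gen_config()) {
  stopifnot(inherits(cfg, "pasrel_gen_config"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)

  ## --- lexicon: unique noun concepts, ~25% two-token surfaces, plus
  ##     adjective decoys that only the POS filter can remove
  n_lex <- cfg$n_lexicon
  base <- sprintf("ent%03da", seq_len(n_lex))
  two_tok <- stats::runif(n_lex) < 0.25
  surfaces <- ifelse(two_tok,
                     paste(sample(SYN_MODIFIERS, n_lex, replace = TRUE), base),
                     base)
  types1 <- sample(SYN_TYPE_POOL, n_lex, replace = TRUE)
  extra <- stats::runif(n_lex) < 0.2
  types2 <- sample(SYN_TYPE_POOL, n_lex, replace = TRUE)
  sem <- ifelse(extra & types2 != types1, paste(types1, types2, sep = "|"),
                types1)
  n_decoy <- 6L
  decoy_surfaces <- sprintf("reactivoid%02d", seq_len(n_decoy))
  lex <- lexicon(c(surfaces, decoy_surfaces),
                 sprintf("C%07d", seq_len(n_lex + n_decoy)),
                 c(sem, sample(SYN_TYPE_POOL, n_decoy, replace = TRUE)),
                 source = "SYN")
  lex$is_decoy <- c(rep(FALSE, n_lex), rep(TRUE, n_decoy))

  ## --- frequency table: over-frequent entries exceed the threshold
  threshold <- 100
  overfreq <- stats::runif(n_lex) < cfg$fraction_overfrequent
  counts <- sample(1:50, n_lex + n_decoy, replace = TRUE)
  counts[seq_len(n_lex)][overfreq] <- 500L
  freq <- frequency_table(lex$surface, counts, threshold = threshold)

  ## --- semantic network over unordered type pairs
  tp <- expand.grid(i = seq_along(SYN_TYPE_POOL), j = seq_along(SYN_TYPE_POOL))
  tp <- tp[tp$i <= tp$j, ]
  allowed <- stats::runif(nrow(tp)) < cfg$fraction_type_pair_allowed
  net <- semantic_network(SYN_TYPE_POOL[tp$i[allowed]],
                          SYN_TYPE_POOL[tp$j[allowed]])

  survives <- !overfreq  # noun entries kept by both filters
  type_sets <- strsplit(lex$semantic_types[seq_len(n_lex)], "|", fixed = TRUE)
  pair_ok <- function(a, b) semnet_allows(type_sets[[a]], type_sets[[b]], net)

  ## NP builder: returns tokens plus per-entity bookkeeping (token ranges)
  build_np <- function(entry_ids, with_det, decoy_id = NA_integer_) {
    toks <- list(); ents <- list()
    if (with_det) toks[[length(toks) + 1L]] <- tok("the", "OTHER")
    if (!is.na(decoy_id))
      toks[[length(toks) + 1L]] <- tok(decoy_surfaces[decoy_id], "ADJ")
    for (k in seq_along(entry_ids)) {
      if (k > 1) toks[[length(toks) + 1L]] <- tok("and", "OTHER")
      parts <- strsplit(lex$surface[entry_ids[k]], " ", fixed = TRUE)[[1]]
      start <- length(toks)
      for (p in parts) toks[[length(toks) + 1L]] <- tok(p, "NOUN")
      ents[[k]] <- list(entry = entry_ids[k], tok_start = start,
                        tok_end = length(toks))  # relative, 0-based half-open
    }
    list(toks = toks, ents = ents)
  }

  span_min <- cfg$entities_per_np[1]; span_max <- cfg$entities_per_np[2]
  pick_k <- function() if (span_min == span_max) span_min else
    sample(span_min:span_max, 1)
  parses <- vector("list", cfg$n_sentences)
  gp_rows <- list(); gr_rows <- list()

  for (s in seq_len(cfg$n_sentences)) {
    sid <- sprintf("syn%04d", s)
    pat <- sample(1:6, 1, prob = cfg$pattern_mix)
    k1 <- pick_k(); k2 <- pick_k()
    picks <- sample(seq_len(n_lex), k1 + k2)
    decoy1 <- if (stats::runif(1) < cfg$fraction_decoy)
      sample(n_decoy, 1) else NA_integer_
    np1 <- build_np(picks[seq_len(k1)], with_det = stats::runif(1) < 0.5,
                    decoy_id = decoy1)
    np2 <- build_np(picks[k1 + seq_len(k2)],
                    with_det = stats::runif(1) < 0.5)
    verb <- sample(SYN_VERBS, 1)
    prep <- sample(SYN_PREPS, 1)

    toks <- np1$toks
    np1_range <- c(0L, length(toks))            # 0-based half-open
    mid <- list(); edges <- list(); np_specs <- list()
    np_id1 <- "np1"; np_id2 <- "np2"
    h1 <- np1_range[2] - 1L                      # head = last token
    add_np <- function(id, start, end, head)
      np_specs[[length(np_specs) + 1L]] <<- list(id = id, start = start,
                                                 end = end, head = head)
    if (pat == 1) {
      mid <- list(tok(verb, "VERB"))
      phrase <- verb
    } else if (pat == 2) {
      mid <- list(tok(verb, "VERB"), tok("by", "PREP"))
      phrase <- paste(verb, "by")
    } else if (pat == 3) {
      mid <- list(tok(verb, "VERB"), tok("a", "OTHER"),
                  tok("effect", "NOUN"), tok(prep, "PREP"))
      phrase <- paste(verb, "effect", prep)
    } else if (pat == 4) {
      mid <- list(tok("be", "VERB", lemma = "be"), tok("present", "ADJ"),
                  tok(prep, "PREP"))
      phrase <- paste("be present", prep)
    } else if (pat == 5) {
      mid <- list(tok(verb, "VERB"), tok(prep, "PREP"))
      phrase <- paste(verb, prep)
    } else {
      mid <- list(tok(prep, "PREP"))
      phrase <- prep
    }
    n1 <- length(toks); nm <- length(mid)
    toks <- c(toks, mid, np2$toks)
    np2_start <- n1 + nm
    np2_end <- length(toks)
    h2 <- np2_end - 1L
    add_np(np_id1, 0L, n1, h1)
    add_np(np_id2, np2_start, np2_end, h2)

    v_tok <- n1                                  # first mid token
    if (pat == 1) {
      edges <- list(list(predicate = v_tok, kind = "VERB", role = "ARG1",
                         arg = h1, voice = "ACTIVE"),
                    list(predicate = v_tok, kind = "VERB", role = "ARG2",
                         arg = h2, voice = "ACTIVE"))
    } else if (pat == 2) {
      edges <- list(list(predicate = v_tok, kind = "VERB", role = "ARG2",
                         arg = h1, voice = "PASSIVE"),
                    list(predicate = v_tok, kind = "VERB", role = "ARG1",
                         arg = h2, voice = "PASSIVE"))
    } else if (pat == 3) {
      eff <- n1 + 2L; prep_tok <- n1 + 3L
      add_np("npi", n1 + 1L, n1 + 3L, eff)
      edges <- list(list(predicate = v_tok, kind = "VERB", role = "ARG1",
                         arg = h1, voice = "ACTIVE"),
                    list(predicate = v_tok, kind = "VERB", role = "ARG2",
                         arg = eff, voice = "ACTIVE"),
                    list(predicate = prep_tok, kind = "PREP", role = "ARG1",
                         arg = eff),
                    list(predicate = prep_tok, kind = "PREP", role = "ARG2",
                         arg = h2))
    } else if (pat == 4) {
      adj <- n1 + 1L; prep_tok <- n1 + 2L
      edges <- list(list(predicate = v_tok, kind = "LINKING_VERB",
                         role = "ARG1", arg = h1),
                    list(predicate = v_tok, kind = "LINKING_VERB",
                         role = "ARG2", arg = adj),
                    list(predicate = prep_tok, kind = "PREP", role = "ARG1",
                         arg = adj),
                    list(predicate = prep_tok, kind = "PREP", role = "ARG2",
                         arg = h2))
    } else if (pat == 5) {
      prep_tok <- n1 + 1L
      edges <- list(list(predicate = v_tok, kind = "VERB", role = "ARG1",
                         arg = h1, voice = "ACTIVE"),
                    list(predicate = prep_tok, kind = "PREP", role = "ARG1",
                         arg = v_tok),
                    list(predicate = prep_tok, kind = "PREP", role = "ARG2",
                         arg = h2))
    } else {
      prep_tok <- n1
      edges <- list(list(predicate = prep_tok, kind = "PREP", role = "ARG1",
                         arg = h1),
                    list(predicate = prep_tok, kind = "PREP", role = "ARG2",
                         arg = h2))
    }
    g <- assemble_sentence(sid, toks, np_specs, edges)
    parses[[s]] <- g

    tk <- g$tokens
    span_of <- function(ent, offset) {
      ts <- ent$tok_start + offset; te <- ent$tok_end + offset
      c(tk$char_start[ts + 1L], tk$char_end[te])
    }
    sp1 <- np_char_span(g, g$nps[g$nps$id == np_id1, ])
    sp2 <- np_char_span(g, g$nps[g$nps$id == np_id2, ])
    gp_rows[[length(gp_rows) + 1L]] <- data.frame(
      sentence_id = sid, pattern_id = pat,
      np1_start = unname(sp1[["start"]]), np1_end = unname(sp1[["end"]]),
      np2_start = unname(sp2[["start"]]), np2_end = unname(sp2[["end"]]),
      relation_phrase = phrase, stringsAsFactors = FALSE)

    for (e1 in np1$ents) {
      if (!survives[e1$entry]) next
      for (e2 in np2$ents) {
        if (!survives[e2$entry]) next
        if (!pair_ok(e1$entry, e2$entry)) next
        s1 <- span_of(e1, 0L); s2 <- span_of(e2, np2_start)
        gr_rows[[length(gr_rows) + 1L]] <- data.frame(
          sentence_id = sid, pattern_ids = as.character(pat),
          relation_phrase = phrase,
          e1_surface = lex$surface[e1$entry],
          e1_concept_id = lex$concept_id[e1$entry],
          e1_types = lex$semantic_types[e1$entry],
          e1_start = s1[1], e1_end = s1[2],
          e2_surface = lex$surface[e2$entry],
          e2_concept_id = lex$concept_id[e2$entry],
          e2_types = lex$semantic_types[e2$entry],
          e2_start = s2[1], e2_end = s2[2], stringsAsFactors = FALSE)
      }
    }
  }

  gold_pairs <- tibble::as_tibble(do.call(rbind, gp_rows))
  gold_relations <- if (length(gr_rows) == 0)
    tibble::as_tibble(empty_relations())
  else tibble::as_tibble(do.call(rbind, gr_rows))
  list(parses = parses, lexicon = lex, freq = freq, semnet = net,
       gold_pairs = gold_pairs, gold_relations = gold_relations, config = cfg)
}

#' Write a synthetic corpus to a directory
#'
#' Emits the same plain-text formats the extraction and evaluation readers
#' consume: `parses.jsonl`, `lexicon.tsv`, `freq.tsv`, `semnet.tsv`,
#' `gold_pairs.tsv`, `gold_relations.tsv`. Identical seeds produce
#' byte-identical files.
#'
#' @param corpus Output of [generate_corpus()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_parse_file(corpus$parses, file.path(dir, "parses.jsonl"))
  tsv <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(corpus$lexicon[c("surface", "concept_id", "semantic_types", "source")],
      "lexicon.tsv")
  freq_df <- data.frame(surface = corpus$freq$norm, count = corpus$freq$count)
  tsv(freq_df, "freq.tsv")
  tsv(as.data.frame(corpus$semnet), "semnet.tsv")
  tsv(as.data.frame(corpus$gold_pairs), "gold_pairs.tsv")
  tsv(as.data.frame(corpus$gold_relations), "gold_relations.tsv")
  invisible(dir)
}
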