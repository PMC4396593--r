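# Shared helpers: a seeded random parse-graph generator and brute-force
# oracle enumerators for the six patterns. The oracles enumerate every
# structural template exhaustively with naive nested loops, independently of
# the matcher implementation; matcher output is compared against them as
# canonical key sets.

random_graph <- function(seed, max_tokens = 15) {
  set.seed(seed)
  n <- sample(3:max_tokens, 1)
  pos <- sample(c("NOUN", "VERB", "ADJ", "PREP", "OTHER"), n, replace = TRUE,
                prob = c(0.45, 0.2, 0.1, 0.15, 0.1))
  tokens <- pas_tokens(sprintf("w%02d", seq_len(n)), pos = pos)

  # random disjoint NP spans
  nps <- empty_nps_df()
  taken <- rep(FALSE, n)
  for (k in seq_len(sample(0:4, 1))) {
    len <- sample(1:3, 1)
    start <- sample(seq_len(n), 1) - 1L
    end <- min(start + len, n)
    if (end <= start || any(taken[(start + 1):end])) next
    taken[(start + 1):end] <- TRUE
    head <- if (end - start == 1) start else sample(start:(end - 1), 1)
    nps <- rbind(nps, data.frame(id = paste0("np", nrow(nps) + 1),
                                 token_start = start, token_end = end,
                                 head = head, stringsAsFactors = FALSE))
  }

  edges <- list()
  for (t in which(pos == "VERB")) {
    if (stats::runif(1) > 0.8) next
    kind <- sample(c("VERB", "LINKING_VERB"), 1, prob = c(0.8, 0.2))
    voice <- if (kind == "VERB") sample(c("ACTIVE", "PASSIVE"), 1) else "NA"
    if (stats::runif(1) < 0.85)
      edges[[length(edges) + 1]] <- pas_edges(t - 1L, kind, "ARG1",
                                              sample(seq_len(n), 1) - 1L,
                                              voice)
    if (stats::runif(1) < 0.85)
      edges[[length(edges) + 1]] <- pas_edges(t - 1L, kind, "ARG2",
                                              sample(seq_len(n), 1) - 1L,
                                              voice)
  }
  for (t in which(pos == "PREP")) {
    if (stats::runif(1) > 0.85) next
    edges[[length(edges) + 1]] <- pas_edges(c(t - 1L, t - 1L), "PREP",
                                            c("ARG1", "ARG2"),
                                            sample(seq_len(n), 2,
                                                   replace = TRUE) - 1L)
  }
  edges <- if (length(edges) == 0) NULL else do.call(rbind, edges)
  g <- parse_graph(paste0("rg", seed), paste(tokens$surface, collapse = " "),
                   tokens = tokens, nps = nps,
                   edges = if (is.null(edges)) empty_edges_df() else edges)
  g
}

empty_nps_df <- function() {
  data.frame(id = character(), token_start = integer(),
             token_end = integer(), head = integer(), stringsAsFactors = FALSE)
}

empty_edges_df <- function() {
  data.frame(predicate = integer(), pred_kind = character(),
             role = character(), arg = integer(), voice = character(),
             stringsAsFactors = FALSE)
}

# ---- oracle plumbing -------------------------------------------------------

np_containing <- function(g, tok) {
  np <- g$nps
  for (i in seq_len(nrow(np)))
    if (np$token_start[i] <= tok && tok < np$token_end[i]) return(i)
  NA_integer_
}

lemma_of <- function(g, i) g$tokens$lemma[i + 1]
surface_of <- function(g, i) g$tokens$surface[i + 1]
pos_of <- function(g, i) g$tokens$pos[i + 1]

pair_key <- function(np1_id, np2_id, phrase) paste(np1_id, np2_id, phrase,
                                                   sep = "|")

matcher_keys <- function(pairs) {
  sort(unique(pair_key(pairs$np1_id, pairs$np2_id, pairs$relation_phrase)))
}

edge_rows <- function(g, kind) g$edges[g$edges$pred_kind == kind, ,
                                       drop = FALSE]

arg_of <- function(ed, p, role) {
  hit <- ed$arg[ed$predicate == p & ed$role == role]
  if (length(hit)) hit[1] else NA_integer_
}

# ---- per-pattern oracles ---------------------------------------------------

oracle_p1 <- function(g) {
  ed <- edge_rows(g, "VERB")
  out <- character()
  for (p in unique(ed$predicate)) {
    if (!any(ed$predicate == p & ed$voice == "ACTIVE")) next
    a1 <- arg_of(ed, p, "ARG1"); a2 <- arg_of(ed, p, "ARG2")
    if (is.na(a1) || is.na(a2)) next
    n1 <- np_containing(g, a1); n2 <- np_containing(g, a2)
    if (is.na(n1) || is.na(n2) || n1 == n2) next
    out <- c(out, pair_key(g$nps$id[n1], g$nps$id[n2], lemma_of(g, p)))
  }
  sort(unique(out))
}

oracle_p2 <- function(g) {
  ed <- edge_rows(g, "VERB")
  pe <- edge_rows(g, "PREP")
  out <- character()
  for (p in unique(ed$predicate)) {
    if (!any(ed$predicate == p & ed$voice == "PASSIVE")) next
    a2 <- arg_of(ed, p, "ARG2")
    if (is.na(a2)) next
    n1 <- np_containing(g, a2)
    if (is.na(n1)) next
    a1 <- arg_of(ed, p, "ARG1")
    if (!is.na(a1)) {
      n2 <- np_containing(g, a1)
      if (!is.na(n2) && n2 != n1)
        out <- c(out, pair_key(g$nps$id[n1], g$nps$id[n2],
                               paste(lemma_of(g, p), "by")))
    } else {
      for (q in unique(pe$predicate)) {
        if (!identical(arg_of(pe, q, "ARG1"), p)) next
        n2 <- np_containing(g, arg_of(pe, q, "ARG2"))
        if (is.na(n2) || n2 == n1) next
        out <- c(out, pair_key(g$nps$id[n1], g$nps$id[n2],
                               paste(lemma_of(g, p), surface_of(g, q))))
      }
    }
  }
  sort(unique(out))
}

oracle_p3 <- function(g) {
  ed <- edge_rows(g, "VERB")
  pe <- edge_rows(g, "PREP")
  np <- g$nps
  out <- character()
  for (p in unique(ed$predicate)) {
    if (!any(ed$predicate == p & ed$voice == "ACTIVE")) next
    a1 <- arg_of(ed, p, "ARG1"); a2 <- arg_of(ed, p, "ARG2")
    if (is.na(a1) || is.na(a2)) next
    n1 <- np_containing(g, a1); ni <- np_containing(g, a2)
    if (is.na(n1) || is.na(ni) || n1 == ni) next
    for (q in unique(pe$predicate)) {
      qa1 <- arg_of(pe, q, "ARG1")
      if (qa1 < np$token_start[ni] || qa1 >= np$token_end[ni]) next
      n2 <- np_containing(g, arg_of(pe, q, "ARG2"))
      if (is.na(n2) || n2 == ni || n2 == n1) next
      out <- c(out, pair_key(np$id[n1], np$id[n2],
                             paste(lemma_of(g, p),
                                   surface_of(g, np$head[ni]),
                                   surface_of(g, q))))
    }
  }
  sort(unique(out))
}

oracle_p4 <- function(g) {
  ed <- edge_rows(g, "LINKING_VERB")
  pe <- edge_rows(g, "PREP")
  out <- character()
  for (p in unique(ed$predicate)) {
    a1 <- arg_of(ed, p, "ARG1"); adj <- arg_of(ed, p, "ARG2")
    if (is.na(a1) || is.na(adj) || pos_of(g, adj) != "ADJ") next
    n1 <- np_containing(g, a1)
    if (is.na(n1)) next
    for (q in unique(pe$predicate)) {
      if (!identical(arg_of(pe, q, "ARG1"), adj)) next
      n2 <- np_containing(g, arg_of(pe, q, "ARG2"))
      if (is.na(n2) || n2 == n1) next
      out <- c(out, pair_key(g$nps$id[n1], g$nps$id[n2],
                             paste(lemma_of(g, p), surface_of(g, adj),
                                   surface_of(g, q))))
    }
  }
  sort(unique(out))
}

oracle_p5 <- function(g) {
  ed <- edge_rows(g, "VERB")
  pe <- edge_rows(g, "PREP")
  out <- character()
  for (p in unique(ed$predicate)) {
    if (any(ed$predicate == p & ed$voice == "PASSIVE")) next
    a1 <- arg_of(ed, p, "ARG1")
    if (is.na(a1) || !is.na(arg_of(ed, p, "ARG2"))) next
    n1 <- np_containing(g, a1)
    if (is.na(n1)) next
    for (q in unique(pe$predicate)) {
      if (!identical(arg_of(pe, q, "ARG1"), p)) next
      n2 <- np_containing(g, arg_of(pe, q, "ARG2"))
      if (is.na(n2) || n2 == n1) next
      out <- c(out, pair_key(g$nps$id[n1], g$nps$id[n2],
                             paste(lemma_of(g, p), surface_of(g, q))))
    }
  }
  sort(unique(out))
}

oracle_p6 <- function(g) {
  pe <- edge_rows(g, "PREP")
  out <- character()
  for (q in unique(pe$predicate)) {
    a1 <- arg_of(pe, q, "ARG1")
    if (pos_of(g, a1) != "NOUN") next
    n1 <- np_containing(g, a1)
    n2 <- np_containing(g, arg_of(pe, q, "ARG2"))
    if (is.na(n1) || is.na(n2) || n1 == n2) next
    out <- c(out, pair_key(g$nps$id[n1], g$nps$id[n2], surface_of(g, q)))
  }
  sort(unique(out))
}

pattern_oracles <- list(oracle_p1, oracle_p2, oracle_p3, oracle_p4,
                        oracle_p5, oracle_p6)
pattern_matchers <- list(match_pattern_1, match_pattern_2, match_pattern_3,
                         match_pattern_4, match_pattern_5, match_pattern_6)
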