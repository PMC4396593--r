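# CoNLL-U ingestion. Expected graphs are hand-built from the documented
# mapping rules and compared structurally.

cu <- function(...) paste(..., sep = "\t")

test_that("a case-marked nominal modifier becomes a prepositional predicate", {
  lines <- c(
    cu(1, "vitronectin", "vitronectin", "NOUN", "_", "_", 0, "root", "_", "_"),
    cu(2, "in", "in", "ADP", "_", "_", 5, "case", "_", "_"),
    cu(3, "the", "the", "DET", "_", "_", 5, "det", "_", "_"),
    cu(4, "connective", "connective", "ADJ", "_", "_", 5, "amod", "_", "_"),
    cu(5, "tissue", "tissue", "NOUN", "_", "_", 1, "nmod", "_", "_"))
  g <- from_conllu(lines, "vit")
  pe <- g$edges[g$edges$pred_kind == "PREP", ]
  expect_equal(nrow(pe), 2)
  expect_equal(unique(pe$predicate), 1L)  # 'in'
  expect_equal(pe$arg[pe$role == "ARG1"], 0L)  # vitronectin
  expect_equal(pe$arg[pe$role == "ARG2"], 4L)  # tissue
  # base NPs: [vitronectin], [the connective tissue]
  expect_equal(nrow(g$nps), 2)
  expect_equal(g$nps$token_start, c(0L, 2L))
  expect_equal(g$nps$token_end, c(1L, 5L))
  # and pattern 6 fires on the result
  pairs <- match_pattern_6(g)
  expect_equal(pairs$np1_text, "vitronectin")
  expect_equal(pairs$np2_text, "the connective tissue")
})

test_that("passive voice with a by-agent maps to deep argument roles", {
  lines <- c(
    cu(1, "Macrophages", "macrophage", "NOUN", "_", "_", 3, "nsubj:pass", "_", "_"),
    cu(2, "are", "be", "AUX", "_", "_", 3, "aux:pass", "_", "_"),
    cu(3, "activated", "activate", "VERB", "_", "_", 0, "root", "_", "_"),
    cu(4, "by", "by", "ADP", "_", "_", 5, "case", "_", "_"),
    cu(5, "LPS", "LPS", "PROPN", "_", "_", 3, "obl:agent", "_", "_"))
  g <- from_conllu(lines, "mac")
  ve <- g$edges[g$edges$pred_kind == "VERB", ]
  expect_equal(nrow(ve), 2)
  expect_true(all(ve$voice == "PASSIVE"))
  expect_equal(ve$arg[ve$role == "ARG1"], 4L)  # LPS, the deep subject
  expect_equal(ve$arg[ve$role == "ARG2"], 0L)  # macrophages, the deep object
  # the agent by-phrase is consumed; no PREP predicate remains
  expect_equal(sum(g$edges$pred_kind == "PREP"), 0)
  expect_equal(match_pattern_2(g)$relation_phrase, "activate by")
})

test_that("copular adjectives yield linking-verb predicates", {
  lines <- c(
    cu(1, "Receptors", "receptor", "NOUN", "_", "_", 3, "nsubj", "_", "_"),
    cu(2, "are", "be", "AUX", "_", "_", 3, "cop", "_", "_"),
    cu(3, "present", "present", "ADJ", "_", "_", 0, "root", "_", "_"),
    cu(4, "in", "in", "ADP", "_", "_", 5, "case", "_", "_"),
    cu(5, "cells", "cell", "NOUN", "_", "_", 3, "obl", "_", "_"))
  g <- from_conllu(lines, "cop")
  lv <- g$edges[g$edges$pred_kind == "LINKING_VERB", ]
  expect_equal(nrow(lv), 2)
  expect_equal(lv$predicate, c(1L, 1L))
  expect_equal(lv$arg[lv$role == "ARG2"], 2L)  # the adjective
  expect_equal(match_pattern_4(g)$relation_phrase, "be present in")
})

test_that("single-token and empty sentences produce edgeless graphs", {
  g <- from_conllu(cu(1, "Apoptosis", "apoptosis", "NOUN", "_", "_", 0,
                      "root", "_", "_"))
  expect_equal(nrow(g$edges), 0)
  expect_equal(nrow(g$nps), 1)
  expect_error(from_conllu(cu(1, "x", "x", "_", "_", "_", 0, "root", "_",
                              "_")),
               "UPOS")
})

test_that("randomized template sentences map to their hand-built graphs", {
  nouns <- c("kinase", "receptor", "cytokine", "ligand", "enzyme", "cell")
  verbs <- c("activates", "inhibits", "binds", "induces")
  set.seed(42)
  for (rep in 1:20) {
    n1 <- sample(nouns, 1); n2 <- sample(nouns[nouns != n1], 1)
    v <- sample(verbs, 1); vlem <- sub("s$", "", v)
    template <- sample(c("active", "intransitive"), 1)
    if (template == "active") {
      lines <- c(
        cu(1, n1, n1, "NOUN", "_", "_", 2, "nsubj", "_", "_"),
        cu(2, v, vlem, "VERB", "_", "_", 0, "root", "_", "_"),
        cu(3, n2, n2, "NOUN", "_", "_", 2, "obj", "_", "_"))
      expected <- parse_graph("tpl", paste(n1, v, n2),
        tokens = pas_tokens(c(n1, v, n2), lemma = c(n1, vlem, n2),
                            pos = c("NOUN", "VERB", "NOUN")),
        nps = pas_nps(c("np1", "np2"), c(0L, 2L), c(1L, 3L), c(0L, 2L)),
        edges = pas_edges(c(1L, 1L), "VERB", c("ARG1", "ARG2"), c(0L, 2L),
                          "ACTIVE"))
    } else {
      lines <- c(
        cu(1, n1, n1, "NOUN", "_", "_", 2, "nsubj", "_", "_"),
        cu(2, v, vlem, "VERB", "_", "_", 0, "root", "_", "_"),
        cu(3, "in", "in", "ADP", "_", "_", 4, "case", "_", "_"),
        cu(4, n2, n2, "NOUN", "_", "_", 2, "obl", "_", "_"))
      expected <- parse_graph("tpl", paste(n1, v, "in", n2),
        tokens = pas_tokens(c(n1, v, "in", n2),
                            lemma = c(n1, vlem, "in", n2),
                            pos = c("NOUN", "VERB", "PREP", "NOUN")),
        nps = pas_nps(c("np1", "np2"), c(0L, 3L), c(1L, 4L), c(0L, 3L)),
        edges = rbind(
          pas_edges(1L, "VERB", "ARG1", 0L, "ACTIVE"),
          pas_edges(c(2L, 2L), "PREP", c("ARG1", "ARG2"), c(1L, 3L))))
    }
    g <- from_conllu(lines, "tpl")
    expect_identical(g$text, expected$text)
    expect_equal(g$tokens, expected$tokens, ignore_attr = TRUE)
    expect_equal(g$nps[c("token_start", "token_end", "head")],
                 expected$nps[c("token_start", "token_end", "head")],
                 ignore_attr = TRUE)
    srt <- function(e) e[order(e$predicate, e$pred_kind, e$role), ]
    expect_equal(srt(g$edges), srt(expected$edges), ignore_attr = TRUE)
  }
})

test_that("ingested NP spans are never nested", {
  # exercised implicitly by parse_graph validation; spot-check a clause with
  # compounds and determiners
  lines <- c(
    cu(1, "The", "the", "DET", "_", "_", 4, "det", "_", "_"),
    cu(2, "tumor", "tumor", "NOUN", "_", "_", 4, "compound", "_", "_"),
    cu(3, "necrosis", "necrosis", "NOUN", "_", "_", 4, "compound", "_", "_"),
    cu(4, "factor", "factor", "NOUN", "_", "_", 0, "root", "_", "_"),
    cu(5, "level", "level", "NOUN", "_", "_", 4, "nmod", "_", "_"))
  g <- from_conllu(lines, "npx")
  np <- g$nps
  for (i in seq_len(nrow(np))) {
    strict <- np$token_start >= np$token_start[i] &
      np$token_end <= np$token_end[i] &
      !(np$token_start == np$token_start[i] & np$token_end == np$token_end[i])
    expect_false(any(strict))
  }
})
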