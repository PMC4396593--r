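test_that("precision/recall/F follow set arithmetic with 0 conventions", {
  expect_equal(unname(prf(c("a", "b"), c("a", "b"))), c(1, 1, 1))
  expect_equal(unname(prf(c("a", "b"), c("c", "d"))), c(0, 0, 0))
  expect_equal(unname(prf(character(), c("a"))), c(0, 0, 0))
  set.seed(3)
  for (rep in 1:20) {
    pred <- sample(letters, sample(0:15, 1))
    gold <- sample(letters, sample(1:15, 1))
    tp <- sum(pred %in% gold)
    got <- prf(pred, gold)
    expect_equal(unname(got["precision"]),
                 if (length(pred)) tp / length(pred) else 0)
    expect_equal(unname(got["recall"]), tp / length(gold))
    p <- got["precision"]; r <- got["recall"]
    expect_equal(unname(got["f1"]),
                 unname(if (p + r == 0) 0 else 2 * p * r / (p + r)))
  }
})

test_that("relative recall divides by the deduplicated pooled gold standard", {
  # a single system covers its own pool completely
  expect_equal(relative_recall(list(sys = c("x", "y")))$recall, 1)
  # disjoint true sets of sizes 3 and 7
  rr <- relative_recall(list(a = paste0("a", 1:3), b = paste0("b", 1:7)))
  expect_equal(rr$recall, c(0.3, 0.7))
  expect_equal(attr(rr, "pool_size"), 10)
  # identical true sets: everyone at 1.0
  same <- relative_recall(list(a = c("r1", "r2"), b = c("r1", "r2")))
  expect_equal(same$recall, c(1, 1))
  expect_error(relative_recall(list(a = character())), "empty")
})

test_that("pool size bounds hold on randomized system sets", {
  set.seed(21)
  for (rep in 1:30) {
    universe <- paste0("rel", 1:40)
    sets <- lapply(1:4, function(i) sample(universe, sample(1:25, 1)))
    names(sets) <- paste0("sys", 1:4)
    rr <- relative_recall(sets)
    r <- attr(rr, "pool_size")
    sizes <- vapply(sets, function(s) length(unique(s)), integer(1))
    expect_lte(r, sum(sizes))
    expect_gte(r, max(sizes))
    if (length(unique(lapply(sets, sort))) > 1 &&
        r > max(sizes)) expect_gt(r, max(sizes))
    expect_true(all(rr$recall > 0 & rr$recall <= 1))
    expect_equal(rr$recall, sizes / r, ignore_attr = TRUE)
  }
})

test_that("multi-coder kappa matches closed-form arithmetic on a worked example", {
  # 2 coders, 4 items: verdicts (T,T), (T,F), (F,F), (F,F)
  # per-item agreement: 1, 0, 1, 1 -> Po = 0.75
  # marginals: p(T) = 3/8, p(F) = 5/8 -> Pe = 9/64 + 25/64 = 0.53125
  # kappa = (0.75 - 0.53125) / (1 - 0.53125) = 0.4666667
  j <- data.frame(A = c(TRUE, TRUE, FALSE, FALSE),
                  B = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(as.numeric(multi_coder_kappa(j)), 0.4666667,
               tolerance = 1e-6)
})

test_that("kappa is 1 on unanimous mixed data and ~0 on independent verdicts", {
  j <- data.frame(A = rep(c(TRUE, FALSE), 5), B = rep(c(TRUE, FALSE), 5))
  k <- multi_coder_kappa(j)
  expect_equal(as.numeric(k), 1)
  expect_false(attr(k, "degenerate"))
  # all items in one category by all coders: degenerate chance term
  uni <- data.frame(A = rep(TRUE, 6), B = rep(TRUE, 6))
  ku <- multi_coder_kappa(uni)
  expect_equal(as.numeric(ku), 1)
  expect_true(attr(ku, "degenerate"))
  # independence: large-sample simulation oracle
  set.seed(99)
  big <- data.frame(A = sample(c(TRUE, FALSE), 10000, TRUE),
                    B = sample(c(TRUE, FALSE), 10000, TRUE),
                    C = sample(c(TRUE, FALSE), 10000, TRUE))
  expect_lt(abs(as.numeric(multi_coder_kappa(big))), 0.05)
  # invariance under category relabeling
  relab <- data.frame(A = ifelse(j$A, "yes", "no"),
                      B = ifelse(j$B, "yes", "no"))
  expect_equal(as.numeric(multi_coder_kappa(relab)),
               as.numeric(multi_coder_kappa(j)))
})

test_that("approximate randomization is smoothed, seeded and effect-monotone", {
  judged <- function(keys, strata, correct)
    data.frame(key = keys, stratum = strata, correct = correct)
  a <- judged(paste0("k", 1:20), rep(1:10, each = 2),
              rep(c(TRUE, FALSE), 10))
  # identical outputs: every shuffle ties the observed 0 difference
  expect_equal(as.numeric(approximate_randomization(a, a, 200, seed = 1)), 1)
  # fixed seed reproduces exactly
  b <- judged(paste0("m", 1:20), rep(1:10, each = 2),
              c(rep(TRUE, 15), rep(FALSE, 5)))
  p1 <- approximate_randomization(a, b, 300, seed = 42)
  p2 <- approximate_randomization(a, b, 300, seed = 42)
  expect_identical(as.numeric(p1), as.numeric(p2))
  expect_gt(as.numeric(p1), 0)
  expect_lte(as.numeric(p1), 1)
  expect_error(approximate_randomization(a, b, 0), "n_shuffles")
  # planted effect: monotone non-increasing p as the gap grows (stochastic)
  p_small <- as.numeric(approximate_randomization(
    a, judged(paste0("m", 1:20), rep(1:10, each = 2),
              c(rep(TRUE, 8), rep(FALSE, 12))), 300, seed = 7))
  p_large <- as.numeric(approximate_randomization(
    a, judged(paste0("m", 1:20), rep(1:10, each = 2), rep(FALSE, 20)),
    300, seed = 7))
  expect_lte(p_large, p_small)
})

test_that("pattern coverage counts gold relations inside matched NP pairs", {
  pairs <- tibble::tibble(
    sentence_id = paste0("s", 1:50), pattern_id = 1L,
    np1_id = "np1", np2_id = "np2",
    np1_start = 0L, np1_end = 10L, np1_text = "",
    np2_start = 20L, np2_end = 30L, np2_text = "",
    relation_phrase = "in")
  gold <- data.frame(sentence_id = paste0("s", 1:50),
                     e1_start = 0L, e1_end = 5L,
                     e2_start = c(rep(20L, 40), rep(40L, 10)),
                     e2_end = c(rep(25L, 40), rep(45L, 10)))
  cov <- pattern_coverage(gold, pairs)
  expect_equal(as.numeric(cov), 0.8)
  # orientation-insensitive: swapped entities still count
  gold_sw <- gold[1, ]
  gold_sw[c("e1_start", "e1_end", "e2_start", "e2_end")] <-
    c(20L, 25L, 0L, 5L)
  expect_equal(as.numeric(pattern_coverage(gold_sw, pairs)), 1)
  expect_error(pattern_coverage(gold[0, ], pairs), "empty")
})

test_that("a passive PPI sentence is covered by the passive-voice pattern", {
  # "Levels of IFN-gamma is slightly increased following IFN-alpha
  # treatment": the annotated PPI between IFN-gamma and IFN-alpha falls
  # inside the pattern-2 NP pair
  tk <- pas_tokens(c("Levels", "of", "IFN-gamma", "is", "slightly",
                     "increased", "following", "IFN-alpha", "treatment"),
                   lemma = c("level", "of", "ifn-gamma", "be", "slightly",
                             "increase", "following", "ifn-alpha",
                             "treatment"),
                   pos = c("NOUN", "PREP", "NOUN", "OTHER", "OTHER",
                           "VERB", "PREP", "NOUN", "NOUN"))
  g <- parse_graph("aimed", paste(tk$surface, collapse = " "), tk,
                   nps = pas_nps(c("np1", "np2"), c(0L, 7L), c(3L, 9L),
                                 c(0L, 8L)),
                   edges = rbind(
                     pas_edges(5L, "VERB", "ARG2", 0L, "PASSIVE"),
                     pas_edges(c(6L, 6L), "PREP", c("ARG1", "ARG2"),
                               c(5L, 8L))))
  pairs <- match_all(g)
  expect_true(2L %in% pairs$pattern_id)
  p2 <- pairs[pairs$pattern_id == 2L, ]
  expect_equal(p2$np1_text, "Levels of IFN-gamma")
  expect_equal(p2$np2_text, "IFN-alpha treatment")
  gamma <- g$tokens[g$tokens$surface == "IFN-gamma", ]
  alpha <- g$tokens[g$tokens$surface == "IFN-alpha", ]
  gold <- data.frame(sentence_id = "aimed",
                     e1_start = gamma$char_start, e1_end = gamma$char_end,
                     e2_start = alpha$char_start, e2_end = alpha$char_end)
  expect_equal(as.numeric(pattern_coverage(gold, pairs)), 1)
})

test_that("false-positive tallies split by error class and annotator", {
  judged <- data.frame(
    key = rep(paste0("r", 1:4), 2),
    annotator = rep(c("A", "B"), each = 4),
    verdict = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    error_class = c("NA", "C1_ENTITY", "C2_NOT_EXPLICIT", "BOTH",
                    "NA", "NA", "C1_ENTITY", "BOTH"))
  tal <- tally_false_positives(judged)
  expect_equal(tal$C1, c(1, 1))
  expect_equal(tal$C2, c(1, 0))
  expect_equal(tal$Both, c(1, 1))
  expect_equal(tal$Total, c(3, 2))
})
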