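## Evaluation statistics for open-domain relation extraction: span-based
## precision/recall/F, pooled relative recall (the pool is the deduplicated
## union of all systems' true relations), Fleiss-style multi-coder kappa on
## binary verdicts, a stratified approximate-randomization test on F-score
## differences, pattern-coverage estimation against gold annotations, and
## false-positive taxonomy bookkeeping.

#' Canonical span key for a relation
#'
#' @param relations A relation tibble with `sentence_id`, `e1_start`,
#'   `e1_end`, `e2_start`, `e2_end` (and `relation_phrase` when
#'   `with_phrase = TRUE`).
#' @param with_phrase Include the relation phrase in the key?
#' @return A character vector of keys, one per row.
#' @export
relation_key <- function(relations, with_phrase = FALSE) {
  if (nrow(relations) == 0) return(character())
  base <- paste(relations$sentence_id, relations$e1_start, relations$e1_end,
                relations$e2_start, relations$e2_end, sep = "\r")
  if (with_phrase) paste(base, relations$relation_phrase, sep = "\r") else base
}

#' Concept-level pooling key for cross-system comparison
#'
#' Relation identity used when pooling several systems' true relations:
#' the normalized unordered pair of concept ids plus the sentence id.
#'
#' @param relations A relation tibble with `sentence_id`, `e1_concept_id`,
#'   `e2_concept_id`.
#' @return A character vector of keys.
#' @export
pool_key <- function(relations) {
  if (nrow(relations) == 0) return(character())
  lo <- pmin(relations$e1_concept_id, relations$e2_concept_id)
  hi <- pmax(relations$e1_concept_id, relations$e2_concept_id)
  paste(relations$sentence_id, lo, hi, sep = "\r")
}

as_keys <- function(x) {
  if (is.character(x)) unique(x) else unique(relation_key(x))
}

#' Precision, recall and F-score over relation sets
#'
#' Standard set-based scores with span-equality matching. Empty denominators
#' follow the 0 convention (and F = 0 when P + R = 0).
#'
#' @param predicted,gold Relation tibbles or character key vectors
#'   (see [relation_key()]).
#' @return A named numeric vector `c(precision, recall, f1)`.
#' @export
prf <- function(predicted, gold) {
  p <- as_keys(predicted); g <- as_keys(gold)
  tp <- length(intersect(p, g))
  prec <- if (length(p) == 0) 0 else tp / length(p)
  rec <- if (length(g) == 0) 0 else tp / length(g)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(precision = prec, recall = rec, f1 = f1)
}

#' Relative recall against a pooled gold standard
#'
#' The pool is the deduplicated union of every system's true relations; each
#' system's relative recall is its true count divided by the pool size. When
#' the systems' true sets differ, the pool size `r` satisfies
#' `max_i |a_i| < r <= sum_i |a_i|`.
#'
#' @param true_sets A named list, one character key vector of true relations
#'   per system (deduplicated internally).
#' @return A tibble with columns `system`, `n_true`, `recall`, plus a
#'   `pool_size` attribute.
#' @export
relative_recall <- function(true_sets) {
  if (length(true_sets) == 0) stop("need at least one system", call. = FALSE)
  sets <- lapply(true_sets, unique)
  pool <- unique(unlist(sets, use.names = FALSE))
  r <- length(pool)
  if (r == 0)
    stop("relative recall undefined: pooled gold standard is empty",
         call. = FALSE)
  sizes <- unname(vapply(sets, length, integer(1)))
  out <- tibble::tibble(
    system = if (is.null(names(sets))) paste0("system", seq_along(sets))
             else names(sets),
    n_true = sizes,
    recall = sizes / r)
  attr(out, "pool_size") <- r
  out
}

#' Multi-coder kappa agreement on categorical verdicts
#'
#' Fleiss-style chance-corrected agreement for two or more coders rating the
#' same items: kappa = (Po - Pe) / (1 - Pe), where Po is the mean pairwise
#' agreement per item and Pe the chance agreement implied by the marginal
#' category proportions. Unanimous data over mixed categories give kappa = 1.
#' When every coder assigns every item to one single category the chance
#' term degenerates (Pe = 1); agreement is perfect, so 1 is returned with a
#' `degenerate` attribute set.
#'
#' @param judgments A matrix or data frame, items in rows and coders in
#'   columns; any atomic verdict coding (logical, character, factor).
#' @return Kappa as a numeric scalar; attribute `degenerate` flags the
#'   single-category case.
#' @export
multi_coder_kappa <- function(judgments) {
  m <- as.matrix(as.data.frame(judgments))
  if (ncol(m) < 2) stop("need at least two coders", call. = FALSE)
  if (nrow(m) < 1) stop("need at least one item", call. = FALSE)
  if (anyNA(m)) stop("every coder must judge every item", call. = FALSE)
  cats <- sort(unique(as.vector(m)))
  n <- ncol(m)   # coders per item
  counts <- t(apply(m, 1, function(row)
    vapply(cats, function(ct) sum(row == ct), numeric(1))))
  if (length(cats) == 1) counts <- matrix(n, nrow = nrow(m), ncol = 1)
  p_i <- (rowSums(counts^2) - n) / (n * (n - 1))
  p_obs <- mean(p_i)
  p_j <- colSums(counts) / (nrow(m) * n)
  p_exp <- sum(p_j^2)
  if (1 - p_exp < .Machine$double.eps^0.5) {
    out <- 1
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (p_obs - p_exp) / (1 - p_exp)
  attr(out, "degenerate") <- FALSE
  out
}

score_judged <- function(rows_a, rows_b) {
  f_of <- function(rows, r) {
    n <- nrow(rows)
    tp <- sum(rows$correct)
    prec <- if (n == 0) 0 else tp / n
    rec <- if (r == 0) 0 else length(unique(rows$key[rows$correct])) / r
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }
  pool <- unique(c(rows_a$key[rows_a$correct], rows_b$key[rows_b$correct]))
  r <- length(pool)
  abs(f_of(rows_a, r) - f_of(rows_b, r))
}

#' Approximate randomization test on two systems' F-scores
#'
#' Builds a null distribution for the absolute F-score difference by
#' repeatedly swapping the two systems' judged outputs wholesale within each
#' stratum (typically a sentence) with probability 1/2, and reports the
#' add-one-smoothed p-value
#' `p = (#\{shuffles with |dF| >= |dF_observed|\} + 1) / (n_shuffles + 1)`.
#' Recall inside each F-score uses the pooled union of both systems' true
#' relation keys, which is invariant under the swaps.
#'
#' @param out_a,out_b Judged outputs: data frames with columns `key`
#'   (relation identity), `stratum` (swap unit), `correct` (logical verdict).
#' @param n_shuffles Number of shuffles (the reference setting is 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return The p-value in (0, 1], with attribute `observed` holding |dF|.
#' @export
approximate_randomization <- function(out_a, out_b, n_shuffles = 1000,
                                      seed = NULL) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1", call. = FALSE)
  out_a <- as.data.frame(out_a); out_b <- as.data.frame(out_b)
  for (nm in c("key", "stratum", "correct")) {
    if (is.null(out_a[[nm]]) || is.null(out_b[[nm]]))
      stop("judged outputs need columns key, stratum, correct", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  observed <- score_judged(out_a, out_b)
  strata <- unique(c(out_a$stratum, out_b$stratum))
  a_by <- lapply(strata, function(s) out_a[out_a$stratum == s, , drop = FALSE])
  b_by <- lapply(strata, function(s) out_b[out_b$stratum == s, , drop = FALSE])
  hits <- 0L
  for (k in seq_len(n_shuffles)) {
    flip <- stats::runif(length(strata)) < 0.5
    new_a <- do.call(rbind, c(a_by[!flip], b_by[flip]))
    new_b <- do.call(rbind, c(b_by[!flip], a_by[flip]))
    if (is.null(new_a)) new_a <- out_a[0, ]
    if (is.null(new_b)) new_b <- out_b[0, ]
    if (score_judged(new_a, new_b) >= observed) hits <- hits + 1L
  }
  p <- (hits + 1) / (n_shuffles + 1)
  attr(p, "observed") <- observed
  p
}

#' Pattern coverage of gold relations
#'
#' Estimates how many annotated relations the patterns can in principle
#' reach: a gold relation is covered iff, for some NP pair of its sentence,
#' one entity span lies within NP1 and the other within NP2 (either
#' orientation).
#'
#' @param gold A data frame of gold relations with columns `sentence_id`,
#'   `e1_start`, `e1_end`, `e2_start`, `e2_end` (0-based half-open character
#'   spans).
#' @param pairs An NP-pair tibble from [match_all()]/[match_corpus()].
#' @return The covered fraction in `[0, 1]`, with attribute `covered`
#'   (logical vector per gold relation).
#' @export
pattern_coverage <- function(gold, pairs) {
  gold <- as.data.frame(gold)
  if (nrow(gold) == 0)
    stop("pattern coverage undefined: gold set is empty", call. = FALSE)
  inside <- function(s, e, lo, hi) s >= lo & e <= hi
  covered <- vapply(seq_len(nrow(gold)), function(i) {
    gr <- gold[i, ]
    pp <- pairs[pairs$sentence_id == gr$sentence_id, , drop = FALSE]
    if (nrow(pp) == 0) return(FALSE)
    fwd <- inside(gr$e1_start, gr$e1_end, pp$np1_start, pp$np1_end) &
      inside(gr$e2_start, gr$e2_end, pp$np2_start, pp$np2_end)
    rev <- inside(gr$e2_start, gr$e2_end, pp$np1_start, pp$np1_end) &
      inside(gr$e1_start, gr$e1_end, pp$np2_start, pp$np2_end)
    any(fwd | rev)
  }, logical(1))
  out <- mean(covered)
  attr(out, "covered") <- covered
  out
}

#' Tally false positives by error class
#'
#' Bookkeeping for the manual-evaluation taxonomy: per annotator, counts of
#' false positives caused by incorrect entity extraction (`C1_ENTITY`), by a
#' relation not expressed explicitly (`C2_NOT_EXPLICIT`), and by both.
#'
#' @param judged A data frame with columns `key`, `annotator`, `verdict`
#'   (logical or "TRUE"/"FALSE"), `error_class` (one of `C1_ENTITY`,
#'   `C2_NOT_EXPLICIT`, `BOTH`, `NA` for true relations).
#' @return A tibble with one row per annotator and columns `C1`, `C2`,
#'   `Both`, `Total`.
#' @export
tally_false_positives <- function(judged) {
  judged <- as.data.frame(judged)
  verdict <- if (is.logical(judged$verdict)) judged$verdict
             else judged$verdict %in% c("TRUE", "true", "T")
  fp <- judged[!verdict, , drop = FALSE]
  anns <- sort(unique(judged$annotator))
  rows <- lapply(anns, function(a) {
    sub <- fp[fp$annotator == a, , drop = FALSE]
    tibble::tibble(annotator = a,
                   C1 = sum(sub$error_class == "C1_ENTITY"),
                   C2 = sum(sub$error_class == "C2_NOT_EXPLICIT"),
                   Both = sum(sub$error_class == "BOTH"),
                   Total = nrow(sub))
  })
  do.call(rbind, rows)
}

#' Read gold relations from a standoff TSV
#'
#' Expected columns: `sentence_id`, `e1_start`, `e1_end`, `e2_start`,
#' `e2_end` and optionally `label`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A gold-relation tibble for [pattern_coverage()] / [prf()].
#' @export
read_gold_standoff <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  need <- c("sentence_id", "e1_start", "e1_end", "e2_start", "e2_end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("gold standoff file missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  tibble::as_tibble(df)
}
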