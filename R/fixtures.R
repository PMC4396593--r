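## Hand-encoded worked examples: the six pattern exemplar sentences plus the
## error-analysis sentences (BALF, Laminin, cocaine addicts, pollinosis,
## PDGF), with a small concept lexicon, frequency table and semantic network
## sized to reproduce the documented behaviour of each. The graphs encode
## the parses the extractor is described as receiving -- including the
## deliberately over-long Laminin NP2 produced by a parser error -- because
## they exercise the extractor's contract, not a parser. Concept ids are
## local stand-in identifiers, not Metathesaurus CUIs.

fixture_sentence <- function(sid, surface, pos, nps, edges,
                             lemma = tolower(surface)) {
  parse_graph(sid, paste(surface, collapse = " "),
              tokens = pas_tokens(surface, lemma = lemma, pos = pos),
              nps = nps, edges = edges)
}

#' Curated worked-example fixtures
#'
#' Returns hand-built parse graphs for eleven sentences: the six
#' pattern-exemplar sentences (`t1`..`t6`) and five error-analysis sentences
#' (`balf`, `laminin`, `cocaine`, `pollinosis`, `pdgf`), together with a
#' lexicon, frequency table and semantic network that reproduce the
#' documented extraction behaviour:
#' * `balf` yields 5 relations (five assay entities each related to
#'   "bronchoalveolar lavage fluid");
#' * `laminin` yields 3 relations from the over-long second NP;
#' * `cocaine` yields exactly ("alcoholism", "cocaine addicts") and
#'   ("drug abuse", "cocaine addicts") because "relatives" is over-frequent;
#' * `pollinosis` yields none ("patients" is over-frequent);
#' * `pdgf` yields none (NP1 "a novel factor" holds no entity).
#'
#' @return A list with `parses` (named list of `parse_graph`), `lexicon`,
#'   `freq`, `semnet`.
#' @examples
#' fx <- paper_fixtures()
#' nrow(extract_relations(fx$parses$balf, fx$lexicon, fx$freq, fx$semnet))
#' @export
paper_fixtures <- function() {
  parses <- list()

  parses$t1 <- fixture_sentence("t1",
    c("Protein", "RepA(cop)", "affects", "a", "single", "amino", "acid"),
    c("NOUN", "NOUN", "VERB", "OTHER", "ADJ", "NOUN", "NOUN"),
    lemma = c("protein", "repa(cop)", "affect", "a", "single", "amino",
              "acid"),
    nps = pas_nps(c("np1", "np2"), c(0L, 3L), c(2L, 7L), c(1L, 6L)),
    edges = pas_edges(c(2L, 2L), "VERB", c("ARG1", "ARG2"), c(1L, 6L),
                      "ACTIVE"))

  parses$t2 <- fixture_sentence("t2",
    c("Diabetes", "induced", "by", "streptozotocin", "injection"),
    c("NOUN", "VERB", "PREP", "NOUN", "NOUN"),
    lemma = c("diabetes", "induce", "by", "streptozotocin", "injection"),
    nps = pas_nps(c("np1", "np2"), c(0L, 3L), c(1L, 5L), c(0L, 4L)),
    edges = pas_edges(c(1L, 1L), "VERB", c("ARG2", "ARG1"), c(0L, 4L),
                      "PASSIVE"))

  parses$t3 <- fixture_sentence("t3",
    c("Endothelin-1", "(ET-1)", "had", "a", "strong", "effect", "in",
      "all", "trabeculae"),
    c("NOUN", "NOUN", "VERB", "OTHER", "ADJ", "NOUN", "PREP", "OTHER",
      "NOUN"),
    lemma = c("endothelin-1", "(et-1)", "have", "a", "strong", "effect",
              "in", "all", "trabeculae"),
    nps = pas_nps(c("np1", "npi", "np2"), c(0L, 3L, 7L), c(2L, 6L, 9L),
                  c(1L, 5L, 8L)),
    edges = rbind(
      pas_edges(c(2L, 2L), "VERB", c("ARG1", "ARG2"), c(1L, 5L), "ACTIVE"),
      pas_edges(c(6L, 6L), "PREP", c("ARG1", "ARG2"), c(5L, 8L))))

  parses$t4 <- fixture_sentence("t4",
    c("EPO", "receptor", "be", "present", "in", "epithelial", "cells"),
    c("NOUN", "NOUN", "VERB", "ADJ", "PREP", "ADJ", "NOUN"),
    lemma = c("epo", "receptor", "be", "present", "in", "epithelial",
              "cell"),
    nps = pas_nps(c("np1", "np2"), c(0L, 5L), c(2L, 7L), c(1L, 6L)),
    edges = rbind(
      pas_edges(c(2L, 2L), "LINKING_VERB", c("ARG1", "ARG2"), c(1L, 3L)),
      pas_edges(c(4L, 4L), "PREP", c("ARG1", "ARG2"), c(3L, 6L))))

  parses$t5 <- fixture_sentence("t5",
    c("Apoptosis", "involved", "in", "CD4", "T", "lymphocytes"),
    c("NOUN", "VERB", "PREP", "NOUN", "NOUN", "NOUN"),
    lemma = c("apoptosis", "involve", "in", "cd4", "t", "lymphocyte"),
    nps = pas_nps(c("np1", "np2"), c(0L, 3L), c(1L, 6L), c(0L, 5L)),
    edges = rbind(
      pas_edges(1L, "VERB", "ARG1", 0L, "ACTIVE"),
      pas_edges(c(2L, 2L), "PREP", c("ARG1", "ARG2"), c(1L, 5L))))

  parses$t6 <- fixture_sentence("t6",
    c("vitronectin", "in", "the", "connective", "tissue"),
    c("NOUN", "PREP", "OTHER", "ADJ", "NOUN"),
    nps = pas_nps(c("np1", "np2"), c(0L, 2L), c(1L, 5L), c(0L, 4L)),
    edges = pas_edges(c(1L, 1L), "PREP", c("ARG1", "ARG2"), c(0L, 4L)))

  ## passive "measured in": agentless passive whose agent slot is a
  ## verb-attached PP; "1" in "interleukin 1" is a name constituent and is
  ## tagged nominal
  balf_surface <- c("Total", "protein", ",", "lactate", "dehydrogenase",
                    "(", "LDH", ")", ",", "xanthine", "oxidase", "(", "XO",
                    ")", ",", "tumor", "necrosis", "factor", "(", "TNF",
                    ")", ",", "and", "interleukin", "1", "(", "IL-1", ")",
                    "were", "measured", "in", "bronchoalveolar", "lavage",
                    "fluid", "(", "BALF", ")", ".")
  balf_pos <- rep("OTHER", length(balf_surface))
  balf_pos[c(1, 2, 4, 5, 7, 10, 11, 13, 16, 17, 18, 20, 24, 25, 27, 32, 33,
             34, 36)] <- "NOUN"
  balf_pos[30] <- "VERB"; balf_pos[31] <- "PREP"
  balf_lemma <- tolower(balf_surface); balf_lemma[30] <- "measure"
  parses$balf <- fixture_sentence("balf", balf_surface, balf_pos,
    lemma = balf_lemma,
    nps = pas_nps(c("np1", "np2"), c(0L, 31L), c(28L, 37L), c(24L, 33L)),
    edges = rbind(
      pas_edges(29L, "VERB", "ARG2", 24L, "PASSIVE"),
      pas_edges(c(30L, 30L), "PREP", c("ARG1", "ARG2"), c(29L, 33L))))

  ## the parser error is encoded as described: NP2 spans the whereas-clause
  lam_surface <- c("Laminin", "was", "located", "in", "the", "zone", "of",
                   "the", "basal", "membrane", ",", "whereas", "tenascin",
                   "was", "mainly", "found", "in", "the", "mucosal",
                   "vessels", ".")
  lam_pos <- rep("OTHER", length(lam_surface))
  lam_pos[c(1, 6, 10, 13, 20)] <- "NOUN"
  lam_pos[c(9, 19)] <- "ADJ"
  lam_pos[3] <- "VERB"; lam_pos[c(4, 7, 17)] <- "PREP"; lam_pos[16] <- "VERB"
  lam_lemma <- tolower(lam_surface)
  lam_lemma[3] <- "locate"; lam_lemma[16] <- "find"
  parses$laminin <- fixture_sentence("laminin", lam_surface, lam_pos,
    lemma = lam_lemma,
    nps = pas_nps(c("np1", "np2"), c(0L, 4L), c(1L, 20L), c(0L, 5L)),
    edges = rbind(
      pas_edges(2L, "VERB", "ARG2", 0L, "PASSIVE"),
      pas_edges(c(3L, 3L), "PREP", c("ARG1", "ARG2"), c(2L, 5L))))

  parses$cocaine <- fixture_sentence("cocaine",
    c("Morbidity", "risk", "for", "alcoholism", "and", "drug", "abuse",
      "in", "relatives", "of", "cocaine", "addicts"),
    c("NOUN", "NOUN", "PREP", "NOUN", "OTHER", "NOUN", "NOUN", "PREP",
      "NOUN", "PREP", "NOUN", "NOUN"),
    nps = pas_nps(c("npa", "npb", "npc"), c(0L, 3L, 8L), c(2L, 7L, 12L),
                  c(1L, 6L, 8L)),
    edges = rbind(
      pas_edges(c(2L, 2L), "PREP", c("ARG1", "ARG2"), c(1L, 6L)),
      pas_edges(c(7L, 7L), "PREP", c("ARG1", "ARG2"), c(6L, 8L))))

  parses$pollinosis <- fixture_sentence("pollinosis",
    c("We", "monitored", "a", "group", "of", "patients", "with",
      "pollinosis", "sensitive", "to", "Olea"),
    c("NOUN", "VERB", "OTHER", "NOUN", "PREP", "NOUN", "PREP", "NOUN",
      "ADJ", "PREP", "NOUN"),
    lemma = c("we", "monitor", "a", "group", "of", "patient", "with",
              "pollinosis", "sensitive", "to", "olea"),
    nps = pas_nps(c("npw", "npg", "npp", "npo", "npl"),
                  c(0L, 2L, 5L, 7L, 10L), c(1L, 4L, 6L, 8L, 11L),
                  c(0L, 3L, 5L, 7L, 10L)),
    edges = rbind(
      pas_edges(c(1L, 1L), "VERB", c("ARG1", "ARG2"), c(0L, 3L), "ACTIVE"),
      pas_edges(c(4L, 4L), "PREP", c("ARG1", "ARG2"), c(3L, 5L)),
      pas_edges(c(6L, 6L), "PREP", c("ARG1", "ARG2"), c(5L, 7L)),
      pas_edges(c(9L, 9L), "PREP", c("ARG1", "ARG2"), c(8L, 10L))))

  parses$pdgf <- fixture_sentence("pdgf",
    c("A", "novel", "factor", "interacts", "with", "PGDF", "alpha"),
    c("OTHER", "ADJ", "NOUN", "VERB", "PREP", "NOUN", "NOUN"),
    lemma = c("a", "novel", "factor", "interact", "with", "pgdf", "alpha"),
    nps = pas_nps(c("np1", "np2"), c(0L, 5L), c(3L, 7L), c(2L, 6L)),
    edges = rbind(
      pas_edges(3L, "VERB", "ARG1", 2L, "ACTIVE"),
      pas_edges(c(4L, 4L), "PREP", c("ARG1", "ARG2"), c(3L, 6L))))

  aapp <- "Amino Acid, Peptide or Protein"
  bpoc <- "Body Part, Organ, or Organ Component"
  lex <- lexicon(
    surface = c("Total protein", "lactate dehydrogenase", "xanthine oxidase",
                "tumor necrosis factor", "interleukin 1",
                "bronchoalveolar lavage fluid",
                "Laminin", "membrane", "tenascin", "vessels",
                "alcoholism", "drug abuse", "relatives", "cocaine addicts",
                "patients", "pollinosis",
                "PGDF alpha", "vitronectin", "connective tissue"),
    concept_id = c("CFX0001", "CFX0002", "CFX0003", "CFX0004", "CFX0005",
                   "CFX0006", "CFX0007", "CFX0008", "CFX0009", "CFX0010",
                   "CFX0011", "CFX0012", "CFX0013", "CFX0014", "CFX0015",
                   "CFX0016", "CFX0017", "CFX0018", "CFX0019"),
    semantic_types = c(aapp, "Enzyme", "Enzyme", aapp, aapp,
                       "Body Substance",
                       aapp, bpoc, aapp, bpoc,
                       "Mental or Behavioral Dysfunction",
                       "Mental or Behavioral Dysfunction", "Family Group",
                       "Patient or Disabled Group",
                       "Patient or Disabled Group", "Disease or Syndrome",
                       aapp, aapp, "Tissue"),
    source = "FIXTURE")

  freq <- frequency_table(
    c("relatives", "patients", "alcoholism", "drug abuse", "cocaine addicts",
      "pollinosis", "Laminin", "membrane"),
    c(50000, 80000, 120, 80, 12, 60, 40, 900),
    threshold = 1000)

  semnet <- semantic_network(
    s1 = c(aapp, "Enzyme", aapp, aapp,
           "Mental or Behavioral Dysfunction", aapp),
    s2 = c("Body Substance", "Body Substance", bpoc, aapp,
           "Patient or Disabled Group", "Tissue"))

  list(parses = parses, lexicon = lex, freq = freq, semnet = semnet)
}
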