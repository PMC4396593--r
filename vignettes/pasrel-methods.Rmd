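---
title: "Wide-coverage relation extraction with predicate-argument patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wide-coverage relation extraction with predicate-argument patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pasrel)
```

## The extraction model

`pasrel` extracts open-domain binary relations from biomedical text as
(entity 1, relation phrase, entity 2) triples. Unlike type-specific relation
extractors (protein-protein interaction, drug-drug interaction, ...), it
imposes no inventory of relation types and no whitelist of trigger verbs:
any verbal or prepositional predicate that connects two noun phrases can
license a relation. The design is deliberately recall-first — the intended
use is wide-coverage harvesting over large literature collections, where a
downstream consumer (curation, semantic search, a typed classifier) can
afford to re-rank or filter, but cannot recover relations that were never
proposed.

The pipeline has four stages:

1. **Pattern matching.** Six predicate-argument patterns are matched
   against a deep-syntax parse of each sentence. Predicate-argument
   structures (PAS) normalize surface variation — passivization, relative
   clauses, control — into predicate-argument edges, so a small number of
   patterns covers many surface constructions. Each match yields a
   *relevant NP pair* (NP1, NP2) plus the relation phrase assembled from
   the licensing predicate tokens.
2. **Entity recognition.** A dictionary recognizer overlays concept
   mentions: greedy longest, case-insensitive match over token boundaries
   against a lexicon mapping surfaces to stable concept identifiers and
   semantic types. Two noise filters follow: entities whose head token is a
   verb, adjective, preposition or number are dropped, and entities whose
   corpus frequency exceeds a threshold (common nouns like "study",
   "result", "patients") are dropped.
3. **Candidate generation.** For each NP pair, every surviving entity
   `e_1i` in NP1 is coupled with every entity `e_2j` in NP2 (the full cross
   product). Entities inside a single NP never pair with each other.
4. **Semantic-type constraint.** A candidate becomes a relation iff the
   pair of semantic types `<s1, s2>` of its two entities is permitted by a
   semantic-type network. This is the only semantic filter; it is a
   type-level constraint, not a relation-type assignment — the system
   cannot name the relation it extracts.

## The six patterns

| # | Template | Example pair |
|---|----------|--------------|
| 1 | NP1 &larr; Verb &rarr; NP2 (active) | "Protein RepA(cop) *affects* a single amino acid" |
| 2 | NP1 &larr; Verb &rarr; by + NP2 (passive) | "Diabetes *induced by* streptozotocin injection" |
| 3 | NP1 &larr; Verb &rarr; NP&prime; &larr; Prep &rarr; NP2 | "Endothelin-1 *had a strong effect in* all trabeculae" |
| 4 | NP1 &larr; Link.Verb &rarr; ADJ &larr; Prep &rarr; NP2 | "EPO receptor *be present in* epithelial cells" |
| 5 | NP1 &larr; Verb &larr; Prep &rarr; NP2 (intransitive) | "Apoptosis *involved in* CD4 T lymphocytes" |
| 6 | NP1 &larr; Prep &rarr; NP2 | "vitronectin *in* the connective tissue" |

Patterns 1 and 2 cover transitive verbs in active and passive voice;
pattern 3 covers light-verb constructions ("play a role in", "have an
effect on"); pattern 4 linking verbs with adjectival complements; pattern 5
intransitive verbs detailed by a prepositional phrase; pattern 6 bare
prepositions, which capture localization and whole-part expressions.

Design choices that were genuinely open:

* **Passive agent slot.** Pattern 2's canonical form has a by-agent, which
  the ingester encodes as the deep ARG1 of a passive verb. Many passives in
  the literature are agentless but carry a verb-attached PP that plays the
  same role ("were *measured in* bronchoalveolar lavage fluid", "is
  *increased following* IFN-alpha treatment"). The matcher therefore fills
  the agent slot from either source: a deep ARG1 edge (phrase: lemma +
  "by") or, when no agent edge exists, a prepositional predicate modifying
  the verb (phrase: lemma + preposition). The two routes are mutually
  exclusive per verb.
* **Pattern overlap.** No precedence is imposed: a sentence with a
  transitive verb and an inner PP legitimately fires patterns 1, 3 and 6.
  `match_all()` emits the union and deduplicates on (NP1, NP2, relation
  phrase). Structural gates keep genuinely different readings apart: a
  preposition whose modified head is a verb belongs to pattern 5 (or the
  pattern-2 agent slot), an adjective to pattern 4, a noun to pattern 6.
* **Entities in the intermediate NP&prime;** of pattern 3 never join
  relations; only NP1 x NP2 candidates are generated. The intermediate
  phrase ("a strong effect") is typically a light noun that the relation
  phrase absorbs.
* **Relation phrases use predicate lemmas** plus literal preposition /
  adjective / intermediate-head surfaces ("induce by", "have effect in").
  Rendering is a display convention only; no downstream step depends on
  it.
* **Prepositions are unrestricted** — all prepositional predicates
  qualify, with no whitelist, matching the recall-first stance. The
  linking-verb inventory for CoNLL-U ingestion defaults to
  {be, seem, appear, become, remain} and is configurable.

## The parse substrate

Patterns match against a `parse_graph`: tokens (surface, lemma, coarse POS,
0-based half-open character offsets), base NP spans, and predicate-argument
edges. Coarse POS collapses any tagset to NOUN / VERB / ADJ / PREP / NUM /
OTHER — exactly the distinctions the entity POS filter needs. Voice is a
property of the ingested edges; pattern matching never re-inspects
morphology. Base NPs are unit noun phrases: spans may not nest or overlap,
which the readers enforce. Whether determiners are included in an NP span
is an ingester convention; entity matching is offset-based and insensitive
to it.

Parses arrive either in a versioned newline-delimited JSON interchange
format (`read_parse_file()` / `write_parse_file()`, round-trip stable) or
from CoNLL-U dependencies via a deterministic mapping (`from_conllu()`):
`nsubj`/`obj` become ARG1/ARG2 of active verbs, `nsubj:pass` plus an
agent-marked oblique become the deep ARG2/ARG1 of a passive verb,
case-marked obliques and nominal modifiers become prepositional predicates,
copulas over adjectives become linking-verb predicates, and maximal
non-nested noun projections become base NPs. The mapping makes no attempt
to reproduce any particular deep parser; it exists so that standard
dependency output can feed the pipeline.

## Entity layer choices

* **Longest match, greedy, left to right.** At each token position the
  longest matching lexicon surface wins and matching resumes after it, so
  detected spans never overlap. Normalization is lowercasing plus
  whitespace collapsing; nothing fancier (no stemming, no variant
  generation) — the dictionary is expected to carry synonym surfaces
  explicitly under a shared concept id.
* **Head of a multi-token entity = its last token**, the usual English NP
  headedness. The POS filter keys on the head token. Name-internal
  numerals ("interleukin 1") should be tagged nominal by the ingester,
  otherwise the numeral filter removes the entity.
* **Frequency threshold.** The common-noun filter removes entities whose
  corpus frequency exceeds a threshold, with unknown surfaces kept. The
  threshold is an explicit configuration value; when none is given,
  `frequency_table()` defaults to the 99.9th percentile of the supplied
  counts. It is a knob, not a claim about any particular corpus.
* **Multi-type entities keep all their types**, and the semantic-network
  check passes if ANY type combination is permitted. The network check is
  order-insensitive by default (accept if `<s1,s2>` or `<s2,s1>` is
  listed), with a strict directed mode available; both choices favour
  recall.

Both filters are idempotent and commute, so their order in the pipeline is
immaterial; the extractor applies POS first, frequency second.

## Evaluation toolkit

* `prf()`: span-equality precision / recall / F with 0 conventions for
  empty denominators.
* `relative_recall()`: recall against a pooled gold standard — the
  deduplicated union of all compared systems' true relations; with true
  sets `a_i` and pool size `r`, each recall is `|a_i| / r` and
  `max|a_i| < r <= sum|a_i|` whenever the sets differ. Pooling identity is
  the normalized unordered concept-id pair plus sentence id
  (`pool_key()`).
* `multi_coder_kappa()`: Fleiss-style chance-corrected agreement,
  `(Po - Pe) / (1 - Pe)`, with `Po` the mean pairwise per-item agreement
  and `Pe` from the marginal category proportions. When every coder puts
  every item in one category the chance term degenerates; agreement is
  perfect, so 1 is returned with a `degenerate` flag rather than 0/0.
* `approximate_randomization()`: permutation test for the F-score
  difference of two judged system outputs. Outputs are swapped wholesale
  per stratum (sentence) with probability 1/2; the p-value uses add-one
  smoothing, `p = (hits + 1) / (n + 1)`, so it lies in (0, 1] and is never
  exactly zero. The recall denominator inside each F is the pooled union
  of both systems' true keys, which is invariant under the swaps — this
  keeps the null distribution well-defined.
* `pattern_coverage()`: the fraction of gold relations whose two entity
  spans fall inside NP1 and NP2 of a single matched pair, in either
  orientation — an upper bound on what the patterns can reach before any
  entity or type filtering.
* `tally_false_positives()`: bookkeeping for the manual error taxonomy
  (entity errors, relations not explicitly expressed, both).

## The synthetic generator

`generate_corpus()` produces a corpus in which every quantity downstream of
the parser is known by construction: each sentence instantiates exactly one
pattern template with planted entities; the lexicon, frequency table and
semantic network are generated alongside; and the gold relations are
computed from the generator's own bookkeeping (which entities survive the
filters, which type pairs are permitted) — independently of the extraction
code. The central property is *closure*: `extract_relations()` on the
generated inputs must reproduce the gold set exactly.

Defaults: 50 sentences per corpus, uniform pattern mix, 1-3 entities per
NP, a 40-concept lexicon (about a quarter with two-token surfaces, a fifth
with two semantic types), 15% of lexicon entries over-frequent, half of
the unordered type pairs permitted, and a 10% chance per sentence of an
adjective decoy entity that only the POS filter can remove. These sizes
give every filter and every pattern regular work in a corpus small enough
to run hundreds of times in a test suite; the test suite exercises 100
seeded corpora of 50 sentences, 100 random graphs of up to 15 tokens per
pattern matcher against brute-force enumerators, 10,000 simulated verdicts
for the kappa null, and 1000-shuffle randomization runs.

What the generator deliberately does **not** emulate: fluent text (surface
strings are template-filled pseudo-vocabulary; only structure matters to
the pipeline), parser noise (templates are clean; the curated fixtures
carry the documented parser-error cases instead), dictionary-matching
ambiguity (planted surfaces are unique by construction), and realistic
type or frequency distributions. Passing the closure suite therefore shows
that the pipeline implements its contract exactly — not that it is robust
to the messiness of real parses and real dictionaries, which is what the
curated worked examples and, ultimately, real corpora are for.

## Curated worked examples

`paper_fixtures()` hand-encodes eleven sentences — the six pattern
exemplars plus five extraction case studies — with a small lexicon,
frequency table and semantic network sized to reproduce each documented
behaviour: the coordinated-NP sentence yielding five relations against
"bronchoalveolar lavage fluid"; the over-long parser NP2 yielding three
relations from "Laminin" (two of them spurious — the fixture encodes the
parser error on purpose, because greedy extraction is retained verbatim and
no attempt is made to repair parser-derived spans); the frequency filter
removing "relatives" and "patients"; and an NP pair whose NP1 contains no
entity, yielding nothing. Concept identifiers in the fixtures are local
stand-ins, not Metathesaurus CUIs.

## Numerical and degenerate-input conventions

* All offsets 0-based half-open; a single convention end to end.
* Deduplication keys join fields with a carriage-return separator, which
  cannot occur in tokenized text.
* Output order is deterministic: pairs by (pattern id, NP1 position, NP2
  position); relations by (sentence, entity-1 span, entity-2 span,
  phrase). Equal seeds give byte-identical generated corpora.
* Empty inputs return empty typed tables; an empty pool for relative
  recall and an empty gold set for coverage are signalled as errors, not
  returned as NaN.
* A relation licensed by several patterns collapses to one record that
  keeps all pattern ids.

## Known limitations

Nominal relations ("CD30/CD30L interaction"), coreference-mediated
relations, n-ary relations, and negation/speculation handling are out of
scope. The extractor pairs entities greedily, so over-long NPs from parser
errors propagate into spurious relations by design. The dictionary
recognizer does no variant generation or abbreviation expansion; recall on
real text is bounded by lexicon coverage.
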