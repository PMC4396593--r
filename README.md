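# pasrel

Wide-coverage extraction of binary semantic relations from parsed
biomedical text, with the accompanying evaluation toolkit and a seeded
synthetic-corpus generator.

## The problem

Most biomedical relation extractors target one predefined relation type —
protein-protein interaction, drug-drug interaction, gene-disease — which
caps what they can ever return. `pasrel` takes the open-information-
extraction stance for the biomedical domain: harvest *every* binary
relation between recognized concepts as a triple
(entity 1, relation phrase, entity 2), recall-first, and let downstream
consumers (curation pipelines, semantic search, typed classifiers) filter.
It is aimed at text-mining practitioners who have parses and a concept
lexicon and want a deterministic, inspectable extraction pipeline rather
than a trained black box.

## The method

Six predicate-argument-structure (PAS) patterns over deep-syntax parses
propose *relevant NP pairs* ⟨NP₁, NP₂⟩:

| # | Pattern | Example |
|---|---------|---------|
| 1 | NP₁ ← **Verb** → NP₂ | Protein RepA(cop) ← affects → a single amino acid |
| 2 | NP₁ ← **Verb** → by + NP₂ | Diabetes ← induced → by streptozotocin injection |
| 3 | NP₁ ← **Verb** → NP′ ← Prep → NP₂ | Endothelin-1 ← had → a strong effect ← in → all trabeculae |
| 4 | NP₁ ← **Link. Verb** → ADJP ← Prep → NP₂ | EPO receptor ← be → present ← in → epithelial cells |
| 5 | NP₁ ← **Verb** ← Prep → NP₂ | Apoptosis ← involved ← in → CD4 T lymphocytes |
| 6 | NP₁ ← **Prep** → NP₂ | vitronectin ← in → the connective tissue |

A dictionary recognizer (greedy longest match against a surface → concept
lexicon) finds entities e₁ᵢ in NP₁ and e₂ⱼ in NP₂, after two noise
filters: entities headed by verbs/adjectives/prepositions/numbers are
dropped, and over-frequent common-noun entities ("study", "patients") are
dropped. Every ⟨e₁ᵢ, e₂ⱼ⟩ is a candidate; it becomes a relation iff the
pair of semantic types ⟨s₁, s₂⟩ exists in a semantic-type network. No verb
whitelist, no relation-type inventory.

The package also implements the matching evaluation statistics —
span-based P/R/F, pooled *relative recall* (recallᵢ = |aᵢ| / r with r the
deduplicated union of all systems' true relations), Fleiss-style
multi-coder κ, a stratified approximate-randomization test on F-score
differences, and pattern-coverage estimation — plus a seeded generator
that builds corpora whose gold relations are known by construction.

## Worked example

A sentence with a coordinated subject NP, parsed and hand-encoded in the
bundled fixtures:

> "Total protein, lactate dehydrogenase (LDH), xanthine oxidase (XO),
> tumor necrosis factor (TNF), and interleukin 1 (IL-1) were measured in
> bronchoalveolar lavage fluid (BALF)."

```r
library(pasrel)
fx <- paper_fixtures()
extract_relations(fx$parses$balf, fx$lexicon, fx$freq, fx$semnet)[,
  c("sentence_id", "pattern_ids", "e1_surface", "relation_phrase", "e2_surface")]
#> # A tibble: 5 × 5
#>   sentence_id pattern_ids e1_surface            relation_phrase e2_surface      
#>   <chr>       <chr>       <chr>                 <chr>           <chr>           
#> 1 balf        2           Total protein         measure in      bronchoalveolar…
#> 2 balf        2           lactate dehydrogenase measure in      bronchoalveolar…
#> 3 balf        2           xanthine oxidase      measure in      bronchoalveolar…
#> 4 balf        2           tumor necrosis factor measure in      bronchoalveolar…
#> 5 balf        2           interleukin 1         measure in      bronchoalveolar…
```

The passive pattern (2) pairs the coordinated NP₁ with the
location PP; each of the five NP₁ entities is coupled with the single NP₂
entity, and all five type pairs are permitted by the network, so five
triples come out. Filtering in action, on a phrase where "relatives" is an
over-frequent entity:

```r
extract_relations(fx$parses$cocaine, fx$lexicon, fx$freq, fx$semnet)[,
  c("e1_surface", "relation_phrase", "e2_surface")]
#> # A tibble: 2 × 3
#>   e1_surface relation_phrase e2_surface     
#>   <chr>      <chr>           <chr>          
#> 1 alcoholism in              cocaine addicts
#> 2 drug abuse in              cocaine addicts
```

"relatives" is removed by the frequency filter, so no relation contains
it; the two relations that survive link the disorders to "cocaine
addicts". Scoring a prediction set against gold keys:

```r
prf(c("r1", "r2", "r3"), c("r1", "r2", "r4"))
#> precision    recall        f1
#> 0.6666667 0.6666667 0.6666667
```

## Package layout

- `R/pas-core.R` — parse-graph types, validation, interchange format
- `R/conllu.R` — CoNLL-U → parse-graph mapping
- `R/patterns.R` — the six pattern matchers
- `R/entities.R` — lexicon, dictionary NER, POS and frequency filters
- `R/extract.R` — candidate generation, semantic network, end-to-end pipeline
- `R/evaluation.R` — P/R/F, relative recall, κ, randomization, coverage
- `R/synthetic.R`, `R/fixtures.R` — corpus generator and curated fixtures
- `vignettes/pasrel-methods.Rmd` — the methods notes: model, parameters,
  design decisions, limitations
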