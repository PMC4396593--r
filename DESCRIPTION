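Package: pasrel
Title: Wide-Coverage Biomedical Relation Extraction with Predicate-Argument Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts open-domain binary relations from parsed biomedical text.
    Six predicate-argument-structure patterns over deep-syntax parses propose
    relevant noun-phrase pairs; a dictionary-based entity recognizer with
    part-of-speech and corpus-frequency noise filters overlays concept mentions;
    a semantic-type network constrains candidate entity pairs; the surviving
    candidates are emitted as (entity, relation phrase, entity) triples.
    Includes the accompanying evaluation toolkit (precision/recall/F, pooled
    relative recall, multi-coder kappa agreement, approximate randomization
    testing, pattern-coverage estimation) and a seeded synthetic-corpus
    generator with known gold structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
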