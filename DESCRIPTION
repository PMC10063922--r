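Package: cllsls
Title: CLL Stereotype-Like Sequence Assignment in Normal B-Cell Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies B-cell receptor heavy-chain rearrangements that resemble
    chronic lymphocytic leukemia (CLL) stereotyped subsets ("CLL stereotype-like
    sequences", CLL-SLS) in annotated AIRR-format repertoires. Implements the
    standard clustering criteria (shared IGHV phylogenetic clan, >= 50% VH CDR3
    amino-acid identity and >= 70% similarity, equal CDR3 length, identical motif
    offset) and the relaxed satellite criteria (associated clan, CDR3 length
    difference up to 2 amino acids, motif offset within +/- 2), quantifies
    CLL-SLS frequencies across B-cell subpopulations, IGHV mutation-status
    concordance with the subsets' canonical classes, and heavy/light-chain
    pairing restriction, and ships a seeded synthetic repertoire generator with
    planted stereotype and satellite sequences for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
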