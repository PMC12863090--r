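Package: degsig
Title: Degradation-Signal Analysis of Canonical and Noncanonical Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-sequence scoring of protein degradation determinants:
    C-terminal tail hydrophobicity (Kyte-Doolittle), anchored N-end and
    C-end degron motifs filtered by differential protein stability index,
    terminal intrinsically disordered regions called from per-residue
    disorder scores, KFERQ-like chaperone-mediated-autophagy motifs of
    three classes, tail-anchored protein architecture from residue-level
    topology, and aggregation fractions from per-residue pairing energies.
    Includes composition-preserving within-sequence shuffle nulls, the
    group-comparison statistics used in degradation-determinant studies
    (rank tests with rank-biserial effect sizes, exact 2x2 tests with odds
    ratios, McNemar paired tests, Benjamini-Hochberg adjustment, proportion
    confidence intervals), and a synthetic-data generator that plants
    determinants at controlled prevalences and effect sizes so the whole
    pipeline is testable without external predictors or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
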