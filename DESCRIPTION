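Package: darkspace
Title: Residue-Level Accounting of Protein Sequence Dark Matter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses the outputs of standard protein domain and region
    predictors (hmmscan domtblout tables for Pfam, RPS-BLAST tabular hits
    for CDD, TMHMM2, SEG, Phobius, PairCoil2) into a unified tidy
    annotation model, resolves overlapping domain hits by a longest-domain
    greedy rule, partitions low-complexity, transmembrane, coiled-coil and
    signal-peptide residues into within- and outside-domain fractions,
    extracts uncovered segments and classifies them as subtractable short
    linkers or dark matter at a configurable 50-aa cutoff, and aggregates
    per-protein accounting into database-scale coverage tables,
    dark-matter summaries and release-over-release comparisons. Includes
    a seedable synthetic proteome generator that plants known domain
    architectures and regions and emits them in every supported input
    dialect with ground truth, so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
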