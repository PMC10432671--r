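Package: neovax
Title: Neoantigen Identification and Validation for Tumor Vaccine Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing tumor neoantigens from somatic missense
    variant tables through to vaccine peptide design. Implements post-call
    somatic variant filtering (coverage, tumor/normal variant allele
    fraction, strand support, population allele frequency), enumeration of
    mutant 8-11-mer MHC class I epitope candidates paired with their
    wild-type counterparts, allele-specific anchor-position-aware selection
    rules on predicted binding affinities and percentile ranks, EC50/IC50
    quantification of cell-based MHC stabilization and competition binding
    assays, IFN-gamma T-cell responder calling, 31-mer long-peptide vaccine
    design, immunopeptidome matching, and candidate funnel summary tables.
    A synthetic-data module generates every input with known ground truth
    so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
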