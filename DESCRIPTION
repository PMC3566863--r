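Package: turnscout
Title: Conformational Reverse-Turn Analysis for Peptidomimetic Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to decide whether a small-molecule scaffold mimics a
    peptide reverse turn. Generates conformer ensembles by Monte-Carlo
    multiple-minimum search over a pluggable molecular-mechanics backend,
    detects intramolecular hydrogen bonds and classifies them by
    pseudo-cycle ring size (C7 gamma-turn vs C13 alpha-turn), measures the
    Calpha(1)-Calpha(5) turn-probe distance, computes Boltzmann ensemble
    statistics and circular torsion averages, assigns phi/psi conformational
    regions and composed turn designations, and quantifies amide NH
    hydrogen-bond evidence from NMR temperature coefficients and DMSO
    titrations. Includes a synthetic-data module that builds ideal peptide
    backbones from internal coordinates for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: python (>= 3.8) with rdkit, for the MMFF94
    conformer backend (the analytic torsion backend has no such
    requirement)
Config/testthat/edition: 3
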