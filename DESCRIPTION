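Package: dpdaqsar
Title: Chemometrics of Diarylpentadienamide TRPV1 Antagonists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reusable chemometrics pipeline for studying why
    5,5-diarylpentadienamides (DPDAs) antagonize the TRPV1 ion channel:
    2D autocorrelation molecular descriptors (Broto-Moreau, Moran, Geary)
    on hydrogen-suppressed molecular graphs, genetic-algorithm variable
    selection with multiple linear regression and leave-one-out
    cross-validation, maximum-common-substructure docking-pose RMSD
    comparison, geometric protein-ligand interaction fingerprints, and the
    vanilloid-pocket distance compatibility rule.  Ships the 64-compound
    DPDA activity table as a typed fixture together with synthetic-data
    generators so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
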