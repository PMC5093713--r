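Package: glycoPSC
Title: Multiplexed Label-Free N-Glycoproteomics of Pluripotent Stem Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative N-glycoproteomics analysis pipeline for comparing
    human induced pluripotent stem cells (hiPSCs), embryonic stem cells
    (hESCs) and parental somatic cells. Implements identification filtering
    of search-engine glycosite tables (decoy/contaminant removal, site
    localization gates, N-X!=P-[S/T/C] sequon validation), multiplexed
    label-free quantitation with mean normalization, coefficient-of-variation
    gating, fold-change calls and cross-comparison voting, calibration of
    glycopeptide fold changes by parent-protein abundance, candidate-PluriNet
    subnetwork significance via degree-preserving network randomization and
    Fisher's exact test, hypergeometric gene-set enrichment, and
    classification of imperfect-reprogramming expression states. Includes a
    synthetic-data generator that plants known truths in every input so the
    full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    fgsea,
    igraph,
    stats,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
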