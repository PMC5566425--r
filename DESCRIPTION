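Package: ereseq
Title: Estrogen Response Element Motif Annotation and Two-Phase
    Association Analysis for Targeted Resequencing Studies
Version: 0.1.0
Authors@R: person("Mayo", "Analyst", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for linking deep-resequencing variants to estrogen
    response element (ERE) motifs in targeted genomic regions:
    position-weight-matrix motif scanning with exact score p-values,
    SNP-to-motif distance annotation with allele-aware motif effect
    classification (create/disrupt/change), a dual-caller variant QC
    cascade with site-frequency-spectrum summaries, case-control
    association under an outcome-dependent two-phase stratified sampling
    design with inverse-probability weighting, and a truth-tagged
    synthetic cohort generator so the whole pipeline is testable without
    access to subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    VariantAnnotation,
    SummarizedExperiment,
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
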