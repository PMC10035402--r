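Package: gastroITH
Title: Multiregional Intratumoral Heterogeneity Analysis for Gastric Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multiregion tumor sequencing of gastric
    cancers. Merges per-biopsy somatic variant calls into per-patient records,
    rescues low-allele-fraction calls censored by the upstream caller,
    classifies each mutation as clonal, subclonal or private across spatially
    separated biopsies, assigns TCGA gastric molecular subtypes (EBV, MSI,
    CIN, GS) from viral read fractions, microsatellite instability scores and
    copy-number-altered genome fractions, builds per-patient clonal
    phylogenies from biopsy presence patterns, refits single-base-substitution
    mutational signatures stratified by clonality, applies rule-based
    pathogenicity and druggability annotation, and computes cohort-level
    statistics. Includes a synthetic-cohort generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
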