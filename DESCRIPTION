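Package: affpanel
Title: Rare-Variant and Copy-Number Interpretation for Atypical Femur
    Fracture Cohorts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects underlying monogenic bone disorders in cohorts of
    atypical femur fracture (AFF) patients. Implements inheritance-aware
    rare-variant filtering over a curated 37-gene panel (quality-by-depth,
    consequence and allele-frequency funnel with dominant/recessive
    cutoffs and compound-heterozygote flagging), an ACMG/AMP
    evidence-combination engine alongside a filter-based proxy classifier
    for large control sets, carrier-prevalence estimation with exact
    binomial enrichment testing against a background population rate, and
    SNP-array CNV filtering with ClinGen copy-number-loss rubric scoring.
    Ships a synthetic-cohort generator and a fully worked 60-patient
    example cohort so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    optparse,
    knitr,
    rmarkdown
biocViews: VariantAnnotation, GeneticVariability, CopyNumberVariation,
    Classification, Genetics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
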