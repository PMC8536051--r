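Package: vdfreq
Title: Population Allele-Frequency Enrichment and Genetic Risk Scores for
    Vitamin D-Associated SNPs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for comparing effect-allele frequencies of
    vitamin D concentration-associated SNPs across ancestry groups. Curates
    GWAS-catalog association exports into a harmonized SNP panel, derives
    per-population effect-allele frequencies from VCF genotype panels and
    published frequency tables, computes signed log10 Fisher exact enrichment
    statistics in log space (finite far below double-precision underflow),
    builds the SNP-by-population enrichment matrix and clusters populations,
    computes unweighted composite genetic risk scores with a two-phase
    frequency-concordance filter, and relates population mean scores to serum
    25-hydroxy-vitamin-D concentration and latitude by ordinary least squares.
    Includes a Balding-Nichols multi-population simulator so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: SNP, GenomeWideAssociation, Genetics, StatisticalMethod
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'methods.R'
    'association.R'
    'enrichment.R'
    'frequency-panel.R'
    'grs.R'
    'pipeline.R'
    'simulate.R'
    'snp-catalog.R'
    'table1.R'
    'vdfreq-package.R'
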