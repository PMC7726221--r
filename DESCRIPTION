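Package: hapblup
Title: Haplotype-Block Genomic Prediction with Multi-Allelic GBLUP/GREML
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genomic prediction and variance-component estimation using
    multi-allelic haplotype models. Haplotype blocks are constructed from
    structural rules (fixed chromosome distance, fixed SNP count) or
    functional annotation intervals (gene boundaries, ChIP-seq sites); each
    block is treated as a multi-allelic locus whose distinct phased allele
    strings are the alleles. The package builds SNP additive, SNP dominance
    and haplotype additive model matrices and their trace-normalized genomic
    relationship matrices, fits mixed models by restricted maximum
    likelihood (GREML) with average-information acceleration, computes GBLUP
    genetic values and per-locus heritability profiles, runs ten-fold
    cross-validation of six prediction model variants, and estimates
    within-block epistasis heritability by differencing haplotype-model and
    SNP-model total heritabilities. A synthetic-data module generates phased
    multi-chromosome SNP panels with tunable allele-frequency spectrum and
    local linkage disequilibrium, annotation intervals, and phenotypes with
    a known additive/dominance/epistasis variance architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
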