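Package: qtldissect
Title: Dissecting Closely Linked QTL by Iterative Conditional GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Mixed-model genome-wide association with iterative conditioning
    on lead SNPs to separate closely linked quantitative trait loci (QTL) on
    a chromosome. Provides genotype-dosage input/output with minor allele
    frequency and Hardy-Weinberg filtering, genomic relationship matrices and
    two-component REML variance partitioning, per-round QTL peak boundary
    definition, linkage-disequilibrium (r^2) regions around lead SNPs,
    closest-gene and phenotype-term candidate-gene prioritization with
    Fisher's exact enrichment, screening of variant-consequence annotation
    tables, and a haplotype-mosaic genotype simulator implementing a QTN
    spike-in type-I-error experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    optparse
Config/testthat/edition: 3
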