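Package: selarch
Title: Mapping the Architecture of Selection from Temporally Stratified Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the selection architecture of managed
    populations with temporally stratified genotype data. Implements
    Generation Proxy Selection Mapping (GPSM): a genome-wide linear mixed
    model that regresses SNP genotype on a continuous generation proxy
    (decimal years before a reference date) with a genomic relationship
    matrix controlling for drift and shared ancestry, with REML variance
    components, BLUP diagnostics, Box-Cox proxy transformation, a ladder
    of significance thresholds, and conditional-and-joint (COJO) locus
    refinement from summary statistics plus an LD reference. Complements
    the mixed-model scan with selective-sweep statistics: nSL haplotype
    homozygosity with 100-bin frequency standardization and spline-defined
    variable-width windows, a composite sweep statistic (mu) in 50-SNP
    sliding windows, and Tajima's D in fixed bins. A forward-in-time
    simulator of overlapping-generation diploid populations under
    truncation selection on a polygenic trait, hard sweeps, balancing
    selection, and drift generates phased genotypes, left-skewed birth-date
    metadata, and a truth table for power and calibration studies. Cross-
    method synthesis includes LD profiles around lead loci, locus-set
    overlap, gene/QTL proximity classification, and QTL-class enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml,
    rtracklayer
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
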