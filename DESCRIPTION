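Package: lohkit
Title: Loss-of-Heterozygosity Mapping, Tetrad Phasing, and Fluctuation
    Analysis for Heterozygous Diploid Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for characterizing loss-of-heterozygosity
    (LOH) in heterozygous diploid yeast genomes. Builds phased
    heterozygous-SNP marker maps from four-spore tetrad genotypes, infers
    recessive-allele carriers from all-pairs cross phenotype matrices and
    scans phased maps for strict co-segregation with a trait, estimates
    LOH rates from fluctuation assays by the Lea-Coulson method of the
    median with confidence intervals and per-kilobase normalization,
    resolves per-marker clone genotypes into directional LOH tracts with
    midpoint endpoints and interval-size chi-square tests, calls locus
    copy number from droplet digital PCR counts with a two-reference
    normalizer, and generates synthetic data sets (phased genomes,
    tetrads, Luria-Delbruck cultures, Poisson droplets) with the
    statistical structure these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
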