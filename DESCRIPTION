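Package: popgenscan
Title: Genomic Diversity, Runs of Homozygosity, Population Structure and
    Haplotype-Based Selection Scans for SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream population-genomic analysis of diploid SNP genotypes:
    variant and sample quality control, per-population diversity indices
    (observed and expected heterozygosity, minor allele frequency),
    PLINK-style sliding-window detection of runs of homozygosity with
    class-wise summaries, genomic inbreeding coefficients (F_ROH and F_HOM),
    principal component analysis with Patterson scaling, a maximum-likelihood
    admixture model fitted by EM with cross-validation over the number of
    ancestral populations, and an iHS (integrated haplotype score) selection
    scan built on extended haplotype homozygosity with frequency-bin
    standardization, overlapping-window outlier detection and candidate-gene
    annotation against an Ensembl GTF. Includes a seeded generator of phased
    multi-population genotype data with planted structure, autozygosity and
    hard sweeps, and a resumable pipeline orchestrating the full analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    vcfR,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
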