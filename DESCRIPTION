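Package: lethalscan
Title: Depletion-of-Homozygotes Screening for Recessive Lethal Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens phased genotype panels from large livestock populations
    for candidate recessive lethal haplotypes by comparing the observed
    (zero) count of haplotype homozygotes against expectations under random
    mating and under the realized carrier-sire by carrier-maternal-grandsire
    mating pattern. Includes a gene-drop simulator that plants a lethal
    haplotype in a pedigreed population, pedigree algebra (inbreeding,
    sparse inverse numerator relationship matrix), a single-trait liability
    threshold animal model fitted by Gibbs sampling, deregression of
    breeding values, single-SNP and haplotype association on deregressed
    breeding values, and gene-window annotation of significant markers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
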