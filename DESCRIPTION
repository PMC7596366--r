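Package: mixploid
Title: Ploidy Inference, Clone Detection and Demographic Model Comparison
    for Clonally Propagated Crops Genotyped by Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for mixed-ploidy, clonally propagated crop
    collections genotyped by reduced-representation sequencing (GBS).
    Infers per-accession ploidy (2x/3x/4x) from the distribution of
    alternate-allele read fractions at heterozygous sites, detects clonal
    lineages from identity-by-descent sharing and Manhattan kinship,
    computes windowed diversity statistics (nucleotide diversity, Tajima's
    D, Weir-Cockerham Fst), and compares split-and-migration demographic
    scenarios on joint site-frequency spectra by composite likelihood and
    AIC.  A synthetic GBS generator with known truth (ploidy, clone
    membership, population history) drives every stage so the pipeline is
    testable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    igraph,
    fitdistrplus,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
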