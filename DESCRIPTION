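Package: recombscape
Title: Meiotic Recombination Mapping and QTL Discovery in Half-Sib Livestock Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects meiotic crossovers from SNP genotypes within half-sib
    families, estimates window recombination rates along the genome, labels
    recombination hotspots and coldspots, and summarises per-parent genome-wide
    recombination number (GRN) and hotspot usage (GHU). Window-level genomic
    covariates (GC content, CpG island density, common haplotype alleles) and
    genomic inbreeding coefficients support feature association analyses.
    Heritability and repeatability of recombination propensity are estimated
    with a pedigree repeatability animal model, and QTL for recombination rate
    are mapped with weighted BayesB/BayesC whole-genome regression including
    1-Mb window variance partitioning (GV%, WPPA, SPPI). A gamete simulator
    with hotspot-structured crossover intensity and heritable per-parent
    recombination propensity provides fully specified synthetic data sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    Biostrings,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
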