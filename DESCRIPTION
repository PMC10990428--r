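Package: apescapes
Title: Correlated Genomic Landscapes of Diversity and Divergence Across a
    Phylogeny
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how landscapes of nucleotide diversity (pi)
    and absolute divergence (dXY), computed in non-overlapping genomic
    windows, covary across a clade of closely related species. Provides a
    dated species-tree container with per-branch effective population sizes,
    windowed diversity and divergence statistics from variant calls with
    callable-site masks, weak/strong site partitioning for GC-biased gene
    conversion analyses, a rescaled forward Wright-Fisher simulator with
    exon-restricted selected mutations drawn from gamma and exponential
    distributions of fitness effects, a fast neutral multispecies-coalescent
    mode with mutation-rate-map overlays, Spearman correlation and
    covariance-decomposition analyses of landscape pairs against
    phylogenetic distance, PCA embedding of simulations against data, a
    diffusion-approximation oracle for substitution rates by mutation class,
    and a seeded synthetic-dataset generator emulating a ten-population
    great-apes panel.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    S4Vectors,
    IRanges,
    GenomicRanges,
    data.table,
    jsonlite,
    yaml,
    vcfR,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: PopulationGenetics, Coverage, Genetics, Software
RoxygenNote: 7.3.3
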