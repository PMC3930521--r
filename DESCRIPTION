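Package: geelbek
Title: Phylogeography and Population Differentiation Across an Oceanographic
    Barrier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidy pipeline for two-marker population genetics of coastal
    fishes sampled across an oceanographic dispersal barrier, built around the
    geelbek (Atractoscion aequidens) study system of the Benguela Current.
    Reads mitochondrial control-region alignments (FASTA) and diploid
    microsatellite genotype tables (GenePop or TSV); computes haplotype and
    nucleotide diversity, Kimura two-parameter distances, hierarchical
    distance-based AMOVA with Phi-statistics and permutation tests,
    Weir-Cockerham F-statistics, Jost's D, Hardy-Weinberg and linkage
    permutation tests, null-allele EM estimation, allelic richness by
    rarefaction, and drift-based power simulation; fits the sudden-expansion
    mismatch model with parametric-bootstrap goodness of fit and converts
    tau to calendar time; builds median-joining haplotype networks; and
    includes a two-deme coalescent simulator so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
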