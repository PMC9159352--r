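Package: gradsweep
Title: Phenotype-Gradient Selective-Sweep Scans for a Short-Gestation-Length Trait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects trait-specific selective sweeps by contrasting nested,
    phenotype-defined focal groups against a fixed reference population.
    Implements windowed nucleotide diversity (pi) ratios, the Weir-Cockerham
    fixation index (FST) as a windowed ratio-of-sums estimator, and
    unstandardized cross-population extended haplotype homozygosity (XP-EHH)
    from phased haplotypes, together with top-tail selection and a
    gradient-increase filter across the nested population pairs. Also provides
    variant quality control (minor allele frequency, call rate, exact
    Hardy-Weinberg test), linkage-disequilibrium decay and pruning, principal
    component analysis and neighbour-joining trees for population structure,
    gene-interval annotation of candidate windows and SNPs, the
    stage-exclusion set logic that separates breed-specific from
    gestational-stage differential expression, known-gene overlap
    summaries, and a forward Wright-Fisher simulator that plants a
    trait-linked sweep for end-to-end recovery experiments.
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
    GenomicRanges,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
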