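Package: episcore
Title: Histone-Mark Peak Annotation, Super-Enhancer Calling, and
    Epigenetic Survival Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the computational core of
    ChIP-seq based epigenetic profiling of tumour cell panels: BED peak
    input and genomic-interval arithmetic, peak-to-feature annotation and
    TSS-anchored signal profiles, ROSE-style super-enhancer identification
    (stitching, rank-curve inflection cutoff, proximity gene assignment),
    discovery of promoters co-marked by H3K9me3 and H3K27me3, maximally
    selected rank statistics for survival cutpoints, Cox-beta weighted
    prognostic risk scores with cross-cohort transfer, differential
    binding between phenotype groups, and seeded synthetic-data
    generators with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
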