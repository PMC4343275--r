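Package: ploidyseq
Title: Mutational Chronology and Clonal Lineage from Flow-Sorted Tumor
    Subpopulation Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the mutational chronology and clonal lineage of a
    polyploid tumor from sequencing of flow-sorted ploidy subpopulations
    (Ploidy-Seq). Provides a clonal-evolution simulator with known ground
    truth (clone trees with whole-genome-doubling events, binomial read-count
    noise), presence/absence genotyping with early/intermediate/late
    chronology classification, read-depth copy-number profiling with
    Kolmogorov-Smirnov segmentation, sliding-window loss-of-heterozygosity
    detection, split-read structural-variant breakpoint clustering and
    filtering, neighbor-joining lineage trees, competing genome-doubling
    models (dual endoreduplication versus cell fusion) scored against
    observed allele frequencies, and in-silico bulk mixing with
    detection-efficiency estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
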