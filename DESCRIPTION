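Package: bsrmap
Title: Bulked-Segregant RNA-Seq Scanning and Fine Mapping of a Dominant Locus
Version: 0.1.0
Authors@R:
    person("bsrmap", "maintainers", email = "bsrmap@example.org", role = c("aut", "cre"))
Description: Tools for localizing a single dominant nuclear locus in an F2
    population from bulked-segregant RNA-seq (BSR-seq) data and marker
    genotypes: per-SNV Euclidean-distance (ED^k) scoring of the two bulks'
    allele frequencies with top-percentile candidate-region calling,
    recombinant-gamete counting in the homozygous-recessive class with
    Kosambi map distances and flanking-marker interval selection,
    chi-square tests of Mendelian segregation ratios, coding-consequence
    annotation of candidate-gene alleles (missense, frameshift, premature
    stop), and the spectrophotometric chlorophyll/carotenoid and 2^-ddCt
    relative-expression calculators used alongside such mapping studies.
    Includes a seeded F2 meiosis simulator that generates every pipeline
    input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
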