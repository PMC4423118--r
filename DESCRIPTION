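Package: ndrscope
Title: Promoter Chromatin Architecture Profiling Around Transcription Start Sites
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: TSS-anchored occupancy profiling of nucleosomes and chromatin
    remodelers in compact genomes. Reads standard genomic annotations and
    signal tracks, converts paired-end mono-nucleosome fragments into
    smoothed dyad-density tracks, scores occupancy in fixed windows around
    transcription start sites with neighbor-overlap masking, clusters
    promoters by their mutant/wild-type response profiles with a
    masked-distance k-means, quantifies nucleosome-depleted-region (NDR)
    geometry, NDR fill-in, +1-nucleosome shifts and double-mutant
    suppression, calls remodeler-enriched promoters at a target false
    discovery rate, tests promoter sequence-element enrichment by random
    permutation, and summarizes tiled-microarray (HybMap-style) expression
    ratios scaled to non-hybridizing control probes. Ships a fully
    specified synthetic chromatin cohort generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    Biostrings,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
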