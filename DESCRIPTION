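Package: dhmrscan
Title: Differential Histone Modification Region Calling from ChIP-Seq Coverage Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds deduplicated, read-extended, depth-normalized per-base ChIP-seq
    signal tracks and calls differential histone modification regions (DHMRs)
    between two conditions with a three-criterion procedure: a seed-and-extend
    sliding-window paired t-test scan over 100-bp bins, a fold-change filter with
    gap merging, and a Poisson enrichment test of 100-bp windows against a 10-kb
    local background. Called regions are mapped to gene promoters to obtain
    differential histone modification genes (DHMGs), and changes induced by a
    treatment are classified as reversed or retained under a second (drug)
    condition across a three-sample design. A seeded synthetic ChIP-seq read
    generator with spiked ground-truth regions supports end-to-end validation,
    including recall/precision scoring and metagene profile summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    jsonlite
Config/testthat/edition: 3
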