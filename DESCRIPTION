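Package: kernbreak
Title: Kernel-Based Breakpoint Detection in Copy-Number Variable Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects copy-number-variable regions (CNVRs) from multi-sample
    short-read alignments and localizes per-group breakpoints to near
    base-pair resolution. Windowed read depth is corrected for GC and
    mappability bias, standardized to a diploid-zero scale, and segmented
    per sample; samples are clustered into copy-number genotype groups with
    a spherical Gaussian mixture model, group breakpoints are estimated
    from segmentation boundaries with a Gaussian-kernel score and bootstrap
    resampling, and then refined to base resolution from soft-clip
    (split-read) evidence in CIGAR strings. Includes a CNV read simulator
    that emits pre-aligned SAM records with junction soft-clips, and an
    evaluation harness computing true-positive and false-discovery rates
    under a +/-10 bp matching radius.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    jsonlite,
    mclust,
    stats,
    tools,
    utils
Suggests:
    GenomicAlignments,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
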