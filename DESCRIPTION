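Package: riboterm
Title: Detection of Riboswitch-Mediated Transcription Termination from
    Paired-End RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers which riboswitch loci regulate gene expression by
    conditional transcription termination, using paired-end RNA-seq
    alignments. Builds signed fragment-termini pileups over oriented
    riboswitch neighborhoods, applies Gaussian-kernel edge detection to
    separate genuine transcript 3' ends from the paired termini created
    by internal fragmentation, scores candidate termination peaks
    against a per-locus bivariate-normal noise model, and tests peak
    clusters across experimental conditions for coverage-drop mean and
    variance shifts. Includes a ground-truthed paired-end read
    simulator so every pipeline stage can be exercised without external
    aligners or databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings,
    GenomicRanges,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
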