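Package: readbait
Title: Salvaging Unmapped RNA-Seq Reads and Estimating Full-Length Transcript Spans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for recycling the unmapped fraction of RNA-seq experiments.
    Implements a screening cascade that filters unmapped reads down to
    gap-bearing candidate reads (alignment gaps longer than 20 bp), a
    power-law model of transcript length fitted by binned log-log regression,
    a co-membership probability that scores mapped fragments near a model
    read by their center-to-center distance, and an estimator of the
    full-length genomic span of a low-coverage novel transcript. Includes a
    synthetic-data generator that emits genomes, annotations, alignments and
    screening truth tables for end-to-end testing without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
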