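Package: tnt1fst
Title: Tnt1 Flanking-Sequence-Tag Processing and Insertion-Landscape Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signature-based quality control of Tnt1 flanking sequence tags
    (FSTs), insertion-site mapping against a reference genome with a
    self-contained seed-and-extend local aligner and Karlin-Altschul
    E-values, per-gene/per-chromosome/per-bin insertion statistics,
    synteny-block tallies, and assembly partition statistics (N50,
    contig/scaffold counts). Includes a synthetic TAIL-PCR FST read
    generator with ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    rtracklayer,
    stats,
    utils
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
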