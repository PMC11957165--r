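Package: spliceworks
Title: Dilated Residual Convolutional Splice-Site Prediction Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for splice-site modelling from genomic
    sequence. Converts genome FASTA and GFF3/GTF annotation into one-hot
    encoded, segmented training tensors with donor/acceptor labels; defines
    and trains a dilated residual convolutional scorer that maps sequence to
    per-base probabilities over {none, acceptor, donor}; supports transfer
    learning, class-wise temperature-scaling calibration with reliability
    diagnostics, memory-bounded genome-wide prediction to BED, VCF variant
    annotation with splice gain/loss delta scores, and in-silico mutagenesis
    analyses. Ships a deterministic synthetic-genome fixture generator and a
    consensus-motif mock scorer so the whole pipeline is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ggplot2,
    jsonlite,
    tibble,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
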