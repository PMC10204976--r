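Package: utail
Title: Detection and Classification of mRNA 3' Uridylation from RNA-seq
    Soft-Clipped Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects non-templated 3' mRNA extensions (poly(A), poly(AU),
    oligo(U) and mixed A/U tails) in standard ligation-based RNA-seq data by
    extracting soft-clipped read ends from SAM/BAM alignments, classifying
    the clipped sequence by an A/U tail grammar, assigning tails to the
    closest annotated feature with a signed distance to its transcription
    end site (TES), and summarising per-sample tail category fractions,
    uridylation frequencies, between-strain uridylation losses, TES-distance
    distributions, uridine-run histograms and per-gene tail count tables.
    Includes a deterministic simulator that generates a synthetic genome,
    annotation and tailed-read SAM alignments with per-read ground truth so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
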