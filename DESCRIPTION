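Package: rtmark
Title: Read-Through Marking Analysis for iCLIP Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies iCLIP sequencing reads into read-through and remaining
    (presumed truncated) cDNAs by a 5'-marker prefix, extracts barcodes and
    unique molecular identifiers (UMIs), trims 3' adapters, assigns strand-aware
    cDNA start sites from alignments, collapses PCR duplicates by UMI and start
    position, and quantifies the genomic nucleotide composition around cDNA
    starts per group as count, frequency and information-content matrices. A
    generative simulator of the read-through-marking library (uridine-biased UV
    crosslinking, adenosine-biased RNase I cleavage, lossy 5'-marker ligation,
    reverse-transcription truncation, PCR duplication) makes every stage
    testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringi,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
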