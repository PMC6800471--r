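Package: tailtrace
Title: Poly(A) Tail Length Estimation from Raw Nanopore Signal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates poly(A) and poly(T) tail lengths of individual reads
    directly from base-called Oxford Nanopore FAST5 files, without read
    alignment. The raw current signal is z-normalized, the tail segment is
    located by smoothing and thresholding (native RNA) or by primer-anchored
    search with spike tolerance (DNA/cDNA), and its length in raw samples is
    converted to nucleotides using the read-specific nucleotide translocation
    rate derived from the events or move table. Supports standard and
    flip-flop basecaller output, Smith-Waterman based read-type classification
    and barcode demultiplexing, batch processing to CSV, per-read diagnostic
    plots, and a squiggle simulator that produces FAST5 fixtures with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rhdf5,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    parallel
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
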