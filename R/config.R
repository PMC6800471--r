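#' Configuration for the RNA tail estimator
#'
#' Tuning parameters of the native-RNA poly(A) search. Defaults correspond to
#' R9.4-era native RNA sequencing (roughly 70 nt/s translocation at ~3 kHz
#' sampling, i.e. some tens of raw samples per nucleotide).
#'
#' @param znorm_clip Absolute z-score at which the normalized signal is
#'   truncated. Default 3.
#' @param smooth_window Moving-average window (raw samples) of the
#'   bidirectional smoother used for coarse segmentation. Default 400.
#' @param smooth_stride Stride of that smoother. Default 1.
#' @param segment_threshold Threshold (in z units) separating high segments
#'   (adapter plateau, poly(A)) from low segments. Default 0.3: the expected
#'   normalized level of homopolymer A signal is about 0.89, and even signal
#'   two standard deviations below it stays above 0.3.
#' @param refine_window Window (samples) of the non-overlapping mean filter
#'   used for boundary refinement. Default 25.
#' @param refine_stride Stride of the refinement filter; equal to
#'   `refine_window` so windows do not overlap. Default 25.
#' @param slope_bound Bound on the absolute difference between consecutive
#'   window means inside the tail. Default 0.3.
#' @param adapter_order Expected coarse-segment pattern preceding the tail:
#'   `"above_below"` (one above-threshold segment, then one below, then the
#'   tail) is the standard adapter geometry; an optional leading
#'   below-threshold segment at the very read start is always skipped.
#' @param allow_flipflop Permit RNA reads carrying a flip-flop move table.
#'   Off by default: flip-flop basecalling of native RNA is not an expected
#'   input, and such reads are reported as failures unless this is set.
#'
#' @return An object of class `rna_config` (a named list).
#' @seealso [estimate_rna_tail()], [dna_config()]
#' @export
rna_config <- function(znorm_clip = 3,
                       smooth_window = 400L,
                       smooth_stride = 1L,
                       segment_threshold = 0.3,
                       refine_window = 25L,
                       refine_stride = 25L,
                       slope_bound = 0.3,
                       adapter_order = c("above_below", "below_above"),
                       allow_flipflop = FALSE) {
  adapter_order <- match.arg(adapter_order)
  stopifnot(znorm_clip > 0, smooth_window >= 1, smooth_stride >= 1,
            segment_threshold > 0, segment_threshold < 1,
            refine_window >= 1, refine_stride >= 1, slope_bound > 0)
  structure(list(znorm_clip = znorm_clip,
                 smooth_window = as.integer(smooth_window),
                 smooth_stride = as.integer(smooth_stride),
                 segment_threshold = segment_threshold,
                 refine_window = as.integer(refine_window),
                 refine_stride = as.integer(refine_stride),
                 slope_bound = slope_bound,
                 adapter_order = adapter_order,
                 allow_flipflop = isTRUE(allow_flipflop)),
            class = "rna_config")
}

#' Configuration for the DNA tail estimator
#'
#' Tuning parameters of the primer-anchored DNA poly(A)/poly(T) search.
#'
#' @param search_window Raw samples searched downstream of the rough tail
#'   start. Default 3000, wide enough for tails of ~350 nt at typical DNA
#'   translocation rates.
#' @param mean_window,mean_stride Window/stride (samples) of the
#'   non-overlapping mean filter on the absolute normalized signal.
#'   Default 10/10.
#' @param slope_bound Bound on the absolute difference of consecutive window
#'   means inside the tail. Default 0.2.
#' @param polyT_mean_bounds,polyA_mean_bounds Admissible window-mean range of
#'   the absolute normalized signal for poly(T) and poly(A) tails. Defaults
#'   (0, 0.3) and (0, 0.6): these bands contain homopolymer T / A signal to
#'   within two standard deviations of its expected level.
#' @param min_tail_run Minimum length (samples) of a downstream tail-like
#'   stretch that justifies bridging across a non-tail spike. Default 60.
#' @param max_gap_nt Maximum bridged spike length, expressed in nucleotides
#'   and converted per read via the translocation rate. Default 120.
#' @param primer_prefix Number of leading bases used for read-type
#'   classification. Default 100.
#' @param end_check_suffix Number of trailing bases checked for the
#'   reverse-complement end primer on poly(A) candidates. Default 50.
#' @param bridge_iterative Bridge multiple successive spikes (each gap
#'   individually limited by `max_gap_nt`). If `FALSE`, at most one bridging
#'   step is applied. Default `TRUE`.
#' @param anchor_tolerance Maximum tolerated disagreement (samples) between
#'   the primer-alignment anchor and the move-table coordinate before the
#'   read is flagged. Default 50.
#'
#' @return An object of class `dna_config` (a named list).
#' @seealso [estimate_dna_tail()], [rna_config()]
#' @export
dna_config <- function(search_window = 3000L,
                       mean_window = 10L,
                       mean_stride = 10L,
                       slope_bound = 0.2,
                       polyT_mean_bounds = c(0, 0.3),
                       polyA_mean_bounds = c(0, 0.6),
                       min_tail_run = 60L,
                       max_gap_nt = 120,
                       primer_prefix = 100L,
                       end_check_suffix = 50L,
                       bridge_iterative = TRUE,
                       anchor_tolerance = 50L) {
  stopifnot(search_window >= 1, mean_window >= 1, mean_stride >= 1,
            slope_bound > 0, length(polyT_mean_bounds) == 2,
            length(polyA_mean_bounds) == 2,
            polyT_mean_bounds[1] < polyT_mean_bounds[2],
            polyA_mean_bounds[1] < polyA_mean_bounds[2],
            min_tail_run >= 1, max_gap_nt > 0)
  structure(list(search_window = as.integer(search_window),
                 mean_window = as.integer(mean_window),
                 mean_stride = as.integer(mean_stride),
                 slope_bound = slope_bound,
                 polyT_mean_bounds = polyT_mean_bounds,
                 polyA_mean_bounds = polyA_mean_bounds,
                 min_tail_run = as.integer(min_tail_run),
                 max_gap_nt = max_gap_nt,
                 primer_prefix = as.integer(primer_prefix),
                 end_check_suffix = as.integer(end_check_suffix),
                 bridge_iterative = isTRUE(bridge_iterative),
                 anchor_tolerance = as.integer(anchor_tolerance)),
            class = "dna_config")
}

# Shipped default sequence set used by the simulator and as a demux example.
# Synthetic sequences (not from any sequencing kit): six 16-mers with pairwise
# Hamming distance >= 9, a 29-base probe marking the 5' start of the carrier
# reference, and 24-base front/end primers.
.default_barcodes <- c(
  bc01 = "GCTACATGACTGCGCA",
  bc02 = "TTGTACCCTGTGTGCT",
  bc03 = "AGCACTCAACCTTCCG",
  bc04 = "CTTTCTGTGAGACGAC",
  bc05 = "AAGAAGCTAACAGACA",
  bc06 = "TTTGTAGGCGTTGAGG")

.default_front_primer <- "AGTTGGTCAAGTAGCGAAATTGAG"
.default_end_primer   <- "AACTGAACTTGGGAATACTGTCTC"
.default_probe        <- "TGATGCAGGAAACCCAGCGAGCTATTGAA"

#' Primer, probe and barcode configuration for classification and demultiplexing
#'
#' Holds the experiment-specific sequences used by [classify_dna_read()],
#' [demux_barcode_rna()] and [demux_barcode_dna()], together with the
#' normalized-alignment-score thresholds. All alignment scores are normalized
#' by query length, so thresholds live in (0, 1].
#'
#' @param front_primer,end_primer Library front/end primer sequences (the end
#'   primer carries the oligo-dT anchor, so it flanks the tail).
#' @param probe Sequence marking the 5' start of the reference insert (e.g.
#'   the first 29 bases of a known carrier sequence); used to locate the
#'   barcode region and, for DNA, the read orientation.
#' @param barcodes Named character vector of barcode sequences.
#' @param score_threshold Minimum normalized alignment score for primer,
#'   probe and barcode hits. Default 0.6.
#' @param orientation_threshold Minimum normalized score for the DNA
#'   orientation test (probe vs its reverse complement). Default 0.5.
#'
#' @return An object of class `primer_config`.
#' @export
primer_config <- function(front_primer = .default_front_primer,
                          end_primer = .default_end_primer,
                          probe = .default_probe,
                          barcodes = .default_barcodes,
                          score_threshold = 0.6,
                          orientation_threshold = 0.5) {
  seqs <- c(front_primer, end_primer, probe, barcodes)
  stopifnot(length(front_primer) == 1, length(end_primer) == 1,
            length(probe) == 1, length(barcodes) >= 1,
            all(nchar(seqs) > 0),
            all(grepl("^[ACGT]+$", seqs)),
            score_threshold > 0, score_threshold <= 1,
            orientation_threshold > 0, orientation_threshold <= 1)
  if (is.null(names(barcodes)) || any(names(barcodes) == ""))
    names(barcodes) <- paste0("bc", sprintf("%02d", seq_along(barcodes)))
  structure(list(front_primer = front_primer,
                 end_primer = end_primer,
                 probe = probe,
                 barcodes = barcodes,
                 score_threshold = score_threshold,
                 orientation_threshold = orientation_threshold),
            class = "primer_config")
}

#' Read a primer configuration from plain-text files
#'
#' Loads sequences from a FASTA file and (optionally) thresholds from a
#' `key = value` text file. FASTA records named `front_primer`, `end_primer`
#' and `probe` fill those slots; every other record is treated as a barcode
#' named by its FASTA header.
#'
#' @param fasta Path to the FASTA file with primer/probe/barcode sequences.
#' @param thresholds Optional path to a key/value file with
#'   `score_threshold` and/or `orientation_threshold` entries.
#' @return A [primer_config()] object.
#' @export
read_primer_config <- function(fasta, thresholds = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  nm <- names(seqs)
  chr <- as.character(seqs)
  names(chr) <- nm
  opts <- list(score_threshold = 0.6, orientation_threshold = 0.5)
  if (!is.null(thresholds)) {
    lines <- readLines(thresholds, warn = FALSE)
    lines <- lines[grepl("=", lines, fixed = TRUE)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      if (key %in% names(opts)) opts[[key]] <- as.numeric(trimws(kv[2]))
    }
  }
  special <- c("front_primer", "end_primer", "probe")
  missing <- setdiff(special, nm)
  if (length(missing))
    stop("primer FASTA lacks required records: ", paste(missing, collapse = ", "))
  primer_config(front_primer = unname(chr[["front_primer"]]),
                end_primer = unname(chr[["end_primer"]]),
                probe = unname(chr[["probe"]]),
                barcodes = chr[setdiff(nm, special)],
                score_threshold = opts$score_threshold,
                orientation_threshold = opts$orientation_threshold)
}

#' @export
print.primer_config <- function(x, ...) {
  cat("Primer configuration\n")
  cat("  front primer:", x$front_primer, "\n")
  cat("  end primer:  ", x$end_primer, "\n")
  cat("  probe:       ", x$probe, "\n")
  cat("  barcodes:    ", length(x$barcodes), "(",
      paste(names(x$barcodes), collapse = ", "), ")\n")
  cat("  thresholds:   score", x$score_threshold,
      "/ orientation", x$orientation_threshold, "\n")
  invisible(x)
}
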