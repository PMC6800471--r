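# Smith-Waterman alignment utilities, read-type classification and barcode
# demultiplexing. All alignments use local (Smith-Waterman) mode with
# match +1, mismatch -1, gap opening 0 and gap extension 1 (i.e. a gap of
# length k costs k), and scores are normalized by query length.

# 5x5 substitution matrix: +1 on the ACGT diagonal, -1 everywhere else.
# Characters outside ACGT are mapped to N beforehand and N mismatches
# everything, including itself.
.sw_submat <- local({
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(b, b))
  diag(m)[1:4] <- 1
  m
})

.sanitize_seq <- function(x) {
  x <- toupper(x)
  gsub("[^ACGT]", "N", x)
}

#' Smith-Waterman local alignment with normalized score
#'
#' Local alignment of `query` against `subject` under the scoring scheme
#' match +1, mismatch -1, gap opening 0, gap extension 1 (a gap of length k
#' costs k). The normalized score is the alignment score divided by the
#' query length, so a perfect full-length query hit scores 1. Characters
#' outside `ACGT` are treated as a universal mismatch.
#'
#' @param query,subject Nucleotide strings (nonempty).
#' @return A list of class `alignment_result` with elements `score`
#'   (integer, >= 0), `normalized_score`, `query_span` and `subject_span`
#'   (both 0-based half-open `c(start, end)` intervals).
#' @examples
#' local_align("ACGT", "ACGT")$normalized_score  # 1
#' @export
local_align <- function(query, subject) {
  if (length(query) != 1 || length(subject) != 1 ||
      is.na(query) || is.na(subject) || nchar(query) == 0 || nchar(subject) == 0)
    stop("empty_sequence")
  al <- Biostrings::pairwiseAlignment(
    pattern = .sanitize_seq(query), subject = .sanitize_seq(subject),
    type = "local", substitutionMatrix = .sw_submat,
    gapOpening = 0, gapExtension = 1)
  sc <- max(0, Biostrings::score(al))
  structure(list(
    score = sc,
    normalized_score = sc / nchar(query),
    query_span = c(Biostrings::start(Biostrings::pattern(al)) - 1L,
                   Biostrings::end(Biostrings::pattern(al))),
    subject_span = c(Biostrings::start(Biostrings::subject(al)) - 1L,
                     Biostrings::end(Biostrings::subject(al)))),
    class = "alignment_result")
}

#' Reverse complement of a nucleotide string
#'
#' @param seq A string over `ACGTN` (lower case accepted).
#' @return The reversed, complemented string.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

# normalized score of query against a (possibly empty) subject region
.nscore <- function(query, subject) {
  if (is.na(subject) || nchar(subject) == 0) return(0)
  local_align(query, subject)$normalized_score
}

#' Classify a DNA read as poly(A)-, poly(T)-containing, truncated or unclassified
#'
#' Both strands of a double-stranded cDNA molecule are sequenced, so a read
#' may carry the tail as poly(A) (template strand, tail at the 3' end) or as
#' poly(T) (complement strand, tail near the 5' end). The front and end
#' primers are aligned against the first `primer_prefix` bases of the called
#' sequence; whichever scores higher, provided it exceeds the score
#' threshold, decides the type (front primer wins: poly(A); end primer wins:
#' poly(T)). For poly(A) candidates the reverse complement of the end primer
#' must additionally be found in the last `end_check_suffix` bases -
#' otherwise the molecule ended before the tail was reached and the read is
#' reported as `truncated`.
#'
#' @param record A `read_record` (or any list with a `sequence` string and
#'   `experiment_type = "dna"`).
#' @param primers A [primer_config()].
#' @param config A [dna_config()] (supplies `primer_prefix` and
#'   `end_check_suffix`).
#' @return A list of class `dna_read_class` with elements `read_type`
#'   (`"polyA"`, `"polyT"`, `"truncated"` or `"unclassified"`), the primer
#'   alignment scores/spans used, and a `short_read` flag for sequences
#'   shorter than `primer_prefix`.
#' @export
classify_dna_read <- function(record, primers = primer_config(),
                              config = dna_config()) {
  seq <- record$sequence
  n <- nchar(seq)
  short_read <- n < config$primer_prefix
  head_seq <- substr(seq, 1, min(n, config$primer_prefix))
  fp <- local_align(primers$front_primer, head_seq)
  ep <- local_align(primers$end_primer, head_seq)
  thr <- primers$score_threshold
  out <- list(read_type = "unclassified",
              front_score = fp$normalized_score,
              end_score = ep$normalized_score,
              end_span = ep$subject_span,
              rc_end_score = NA_real_,
              rc_end_span = NULL,
              short_read = short_read)
  if (ep$normalized_score > fp$normalized_score && ep$normalized_score > thr) {
    out$read_type <- "polyT"
  } else if (fp$normalized_score > ep$normalized_score &&
             fp$normalized_score > thr) {
    # poly(A) candidate: require the reverse-complement end primer near the
    # 3' end, else the tail was not captured
    tail_start <- max(1L, n - config$end_check_suffix + 1L)
    tail_seq <- substr(seq, tail_start, n)
    rc_ep <- local_align(reverse_complement(primers$end_primer), tail_seq)
    out$rc_end_score <- rc_ep$normalized_score
    out$rc_end_span <- rc_ep$subject_span + (tail_start - 1L)  # absolute, 0-based
    out$read_type <- if (rc_ep$normalized_score < thr) "truncated" else "polyA"
  }
  class(out) <- "dna_read_class"
  out
}

# Locate the probe within the first `window` bases of seq.
# Returns list(score, span) with span 0-based half-open on seq, or NULL.
.find_probe <- function(seq, probe, window = 250L, threshold = 0.6) {
  head_seq <- substr(seq, 1, min(nchar(seq), window))
  hit <- local_align(probe, head_seq)
  if (hit$normalized_score <= threshold) return(NULL)
  list(score = hit$normalized_score, span = hit$subject_span)
}

# Score all barcodes against a region; returns the winning name or NA with a
# reason ("no_barcode" if nothing passes the threshold, "ambiguous" on a tie).
.assign_barcode <- function(region, barcodes, threshold) {
  scores <- vapply(barcodes, .nscore, numeric(1), subject = region)
  best <- max(scores)
  if (best <= threshold)
    return(structure(NA_character_, reason = "no_barcode", scores = scores))
  winners <- names(scores)[scores == best]
  if (length(winners) > 1)
    return(structure(NA_character_, reason = "ambiguous", scores = scores))
  structure(winners, scores = scores)
}

#' Demultiplex an RNA read by its 5' barcode
#'
#' The probe (the first bases of the known carrier/reference sequence) is
#' located within the first 250 bases of the called sequence; every
#' configured barcode is then aligned against the subsequence preceding the
#' probe hit and the highest-scoring barcode above the score threshold is
#' assigned. Exact score ties are reported as unassigned (`"ambiguous"`).
#'
#' @inheritParams classify_dna_read
#' @param search_window Bases from the read start searched for the probe.
#' @return The barcode name, or `NA` with attribute `reason` (`"no_probe"`,
#'   `"no_barcode"` or `"ambiguous"`).
#' @export
demux_barcode_rna <- function(record, primers = primer_config(),
                              search_window = 250L) {
  seq <- record$sequence
  hit <- .find_probe(seq, primers$probe, search_window, primers$score_threshold)
  if (is.null(hit)) return(structure(NA_character_, reason = "no_probe"))
  if (hit$span[1] < 1) return(structure(NA_character_, reason = "no_barcode"))
  region <- substr(seq, 1, hit$span[1])  # bases before the probe hit
  .assign_barcode(region, primers$barcodes, primers$score_threshold)
}

# Forward-orientation DNA demux: front primer, then barcode, then probe.
.demux_dna_forward <- function(seq, primers, probe_span) {
  if (probe_span[1] < 1) return(structure(NA_character_, reason = "no_front_primer"))
  pre <- substr(seq, 1, probe_span[1])
  fp <- local_align(primers$front_primer, pre)
  if (fp$normalized_score <= primers$score_threshold)
    return(structure(NA_character_, reason = "no_front_primer"))
  bc_start <- fp$subject_span[2] + 1L  # 1-based position after the primer
  if (bc_start > nchar(pre)) return(structure(NA_character_, reason = "no_barcode"))
  region <- substr(pre, bc_start, nchar(pre))
  .assign_barcode(region, primers$barcodes, primers$score_threshold)
}

#' Demultiplex a DNA read by its barcode, on either strand
#'
#' Read orientation is decided by aligning the probe and its reverse
#' complement against the read ends (probe within the first 250 bases for
#' forward reads; its reverse complement within the last 250 bases for
#' reverse reads) at the orientation threshold. Forward reads are
#' demultiplexed by locating the front primer preceding the probe hit and
#' scoring the barcodes on the region between primer and probe; reverse
#' reads are reverse-complemented first and then processed identically, so
#' the assignment is strand-symmetric.
#'
#' @inheritParams demux_barcode_rna
#' @return The barcode name, or `NA` with attribute `reason`
#'   (`"no_orientation"`, `"no_front_primer"`, `"no_barcode"` or
#'   `"ambiguous"`).
#' @export
demux_barcode_dna <- function(record, primers = primer_config(),
                              search_window = 250L) {
  seq <- record$sequence
  n <- nchar(seq)
  thr <- primers$orientation_threshold
  head_seq <- substr(seq, 1, min(n, search_window))
  tail_seq <- substr(seq, max(1L, n - search_window + 1L), n)
  fwd <- local_align(primers$probe, head_seq)$normalized_score
  rev <- local_align(reverse_complement(primers$probe), tail_seq)$normalized_score
  if (fwd > rev && fwd > thr) {
    hit <- .find_probe(seq, primers$probe, search_window, primers$score_threshold)
    if (is.null(hit)) return(structure(NA_character_, reason = "no_orientation"))
    .demux_dna_forward(seq, primers, hit$span)
  } else if (rev > fwd && rev > thr) {
    rc <- reverse_complement(seq)
    hit <- .find_probe(rc, primers$probe, search_window, primers$score_threshold)
    if (is.null(hit)) return(structure(NA_character_, reason = "no_orientation"))
    .demux_dna_forward(rc, primers, hit$span)
  } else {
    structure(NA_character_, reason = "no_orientation")
  }
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("local alignment: score %g (normalized %.3f), query [%d,%d), subject [%d,%d)\n",
              x$score, x$normalized_score,
              x$query_span[1], x$query_span[2],
              x$subject_span[1], x$subject_span[2]))
  invisible(x)
}
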