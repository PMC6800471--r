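# DNA/cDNA poly(A)/poly(T) estimation: classify the read by its primers,
# anchor a rough tail start from the primer alignment via the move table,
# and find precise tail boundaries with spike tolerance inside a bounded
# search window on the absolute normalized signal.

#' Map a called-base index to its raw-sample coordinate
#'
#' Returns the 0-based raw-signal index at which the cumulative move count
#' of the translocation table first reaches `base_index + 1`, offset by the
#' table's `start_sample`. Bases called together in a multi-move block map
#' to that block's start.
#'
#' @param record A `read_record` (or anything with a `translocation` table).
#' @param base_index 0-based index into the called sequence.
#' @return 0-based raw-sample index.
#' @export
base_to_sample <- function(record, base_index) {
  tb <- record$translocation
  blocks <- tb$blocks
  cum_moves <- cumsum(blocks$move)
  if (base_index < 0 || base_index + 1 > cum_moves[length(cum_moves)])
    stop("base index beyond total moves")
  i <- which(cum_moves >= base_index + 1)[1]
  starts <- c(0, cumsum(blocks$n_samples))[i]
  as.numeric(tb$start_sample) + starts
}

#' Prepare the signal and rough tail start for a DNA read
#'
#' For poly(A) reads the raw signal is index-reversed before normalization
#' so that, as for poly(T) reads, the tail lies near the signal start. The
#' signal is then z-normalized and converted to absolute values. The rough
#' tail start is the sample coordinate of the tail-adjacent end of the end
#' primer alignment (the end primer flanks the tail), mapped through the
#' move table with [base_to_sample()] and mirrored for reversed signals.
#'
#' @param record A `read_record` with `experiment_type = "dna"`.
#' @param read_type `"polyA"` or `"polyT"` (from [classify_dna_read()]).
#' @param classification Optional `dna_read_class` with the primer spans;
#'   recomputed when missing.
#' @param primers,config See [classify_dna_read()].
#' @return A list with `signal` (|z| per sample, in processed orientation),
#'   `rough_start` (0-based sample), `reversed` (logical) and
#'   `anchor_flagged` (TRUE when primer alignment and move table disagree by
#'   more than `config$anchor_tolerance` samples about where called bases
#'   end), or a zero-length result with a `reason` attribute if the anchor
#'   is unmappable.
#' @export
prepare_dna_signal <- function(record, read_type, classification = NULL,
                               primers = primer_config(), config = dna_config()) {
  stopifnot(read_type %in% c("polyA", "polyT"))
  if (is.null(classification))
    classification <- classify_dna_read(record, primers, config)
  n_bases <- nchar(record$sequence)
  L <- length(record$raw_signal)
  total_moves <- sum(record$translocation$blocks$move)
  anchor_base <- if (read_type == "polyT") {
    # tail follows the end primer: first base after the alignment
    span <- classification$end_span
    if (is.null(span)) return(.not_found("no_tail_anchor"))
    span[2]
  } else {
    # tail precedes the reverse-complement end primer near the 3' end
    span <- classification$rc_end_span
    if (is.null(span)) return(.not_found("no_tail_anchor"))
    span[1]
  }
  if (is.na(anchor_base) || anchor_base < 0 || anchor_base >= total_moves)
    return(.not_found("no_tail_anchor"))
  anchor_sample <- tryCatch(base_to_sample(record, anchor_base),
                            error = function(e) NULL)
  if (is.null(anchor_sample)) return(.not_found("no_tail_anchor"))
  # consistency check: called bases should not extend past the raw signal
  covered <- record$translocation$start_sample +
    sum(record$translocation$blocks$n_samples)
  anchor_flagged <- covered - L > config$anchor_tolerance
  norm <- tryCatch(znormalize_clip(record$raw_signal),
                   error = function(e) conditionMessage(e))
  if (is.character(norm)) return(.not_found(norm))
  if (read_type == "polyA") {
    signal <- abs(rev(norm))  # reversal commutes with z-normalization
    rough_start <- L - anchor_sample
  } else {
    signal <- abs(norm)
    rough_start <- anchor_sample
  }
  rough_start <- max(0, min(rough_start, L - 1))
  list(signal = signal, rough_start = rough_start,
       reversed = read_type == "polyA", anchor_flagged = anchor_flagged)
}

#' Find precise DNA tail boundaries with spike tolerance
#'
#' Window means (window 10, stride 10) and consecutive-mean slopes are
#' computed on the absolute normalized signal within
#' `[rough_start, rough_start + search_window)`. The precise tail start is
#' the first window satisfying both the slope bound and the read-type mean
#' band; the tentative end is the first subsequent window violating either.
#' Because short non-tail spikes occur randomly, the scan continues
#' downstream: if another tail-like run of at least `min_tail_run` samples
#' begins within a gap of at most `max_gap_nt * rate` samples, the
#' tentative end is moved past the spike to that run's end (iteratively,
#' unless `bridge_iterative` is off). The first window's slope is taken as 0.
#'
#' @param signal Absolute normalized signal in processed orientation.
#' @param rough_start 0-based sample index of the rough tail start.
#' @param read_type `"polyA"` or `"polyT"` (selects the mean band).
#' @param rate Samples per nucleotide (converts `max_gap_nt` to samples).
#' @param config A [dna_config()].
#' @return `c(precise_start, precise_end)` 0-based half-open sample indices
#'   relative to the full `signal`, or a zero-length vector with attribute
#'   `reason = "no_tail_signal"`.
#' @export
find_precise_dna_tail <- function(signal, rough_start, read_type, rate,
                                  config = dna_config()) {
  stopifnot(read_type %in% c("polyA", "polyT"))
  w <- config$mean_window
  region_end <- min(length(signal), rough_start + config$search_window)
  span <- region_end - rough_start
  k <- span %/% w
  if (k < 1) return(.not_found("no_tail_signal"))
  seg <- signal[(rough_start + 1L):(rough_start + k * w)]
  means <- colMeans(matrix(seg, nrow = w))
  slopes <- c(0, diff(means))
  band <- if (read_type == "polyT") config$polyT_mean_bounds else config$polyA_mean_bounds
  tail_like <- abs(slopes) <= config$slope_bound &
    means >= band[1] & means <= band[2]
  first <- which(tail_like)[1]
  if (is.na(first)) return(.not_found("no_tail_signal"))
  # tentative end: last tail-like window of the run starting at `first`
  runs <- rle(tail_like)
  run_ends <- cumsum(runs$lengths)
  run_starts <- run_ends - runs$lengths + 1L
  ri <- which(run_starts <= first & run_ends >= first)
  end_win <- run_ends[ri]
  min_run_win <- ceiling(config$min_tail_run / w)
  max_gap <- config$max_gap_nt * rate
  repeat {
    ri_next <- ri + 2L  # next TRUE run (runs alternate TRUE/FALSE)
    if (ri_next > length(runs$lengths)) break
    gap_samples <- (run_starts[ri_next] - 1L - end_win) * w
    if (gap_samples > max_gap) break
    if (runs$lengths[ri_next] >= min_run_win) {
      end_win <- run_ends[ri_next]
      ri <- ri_next
      if (!config$bridge_iterative) break
    } else {
      ri <- ri_next  # spike too short to qualify as tail; keep scanning
    }
  }
  c(rough_start + (first - 1L) * w, rough_start + end_win * w)
}

#' Estimate the poly(A)/poly(T) tail length of a DNA read
#'
#' Full DNA pipeline: classify the read type via the library primers,
#' prepare the absolute normalized signal with a primer-anchored rough tail
#' start, find the precise boundaries with spike tolerance, and divide the
#' span by the read-specific translocation rate. Truncated and unclassified
#' reads produce `found = FALSE` rows with their reason. Reported
#' `tail_start`/`tail_end` are in forward raw-signal coordinates also for
#' poly(A) reads (whose signal is scanned in reverse).
#'
#' @param record A `read_record` with `experiment_type = "dna"`.
#' @param config A [dna_config()].
#' @param primers A [primer_config()].
#' @return A one-row `data.frame` of class `tail_estimate`.
#' @export
estimate_dna_tail <- function(record, config = dna_config(),
                              primers = primer_config()) {
  fail <- function(read_type, reason, ...)
    .tail_estimate(record, read_type = read_type, found = FALSE,
                   failure_reason = reason, ...)
  if (!identical(record$experiment_type, "dna"))
    return(fail("invalid", "not_dna"))
  cls <- classify_dna_read(record, primers, config)
  if (cls$read_type %in% c("truncated", "unclassified"))
    return(fail("invalid", cls$read_type))
  prep <- prepare_dna_signal(record, cls$read_type, cls, primers, config)
  if (length(prep) == 0) return(fail(cls$read_type, attr(prep, "reason")))
  rate <- tryCatch(select_rate(record), error = function(e) NULL)
  if (is.null(rate)) return(fail(cls$read_type, "no_moves"))
  precise <- find_precise_dna_tail(prep$signal, prep$rough_start,
                                   cls$read_type, rate$samples_per_nt, config)
  if (!.is_found(precise))
    return(fail(cls$read_type, attr(precise, "reason"),
                rough_start = prep$rough_start))
  L <- length(record$raw_signal)
  if (prep$reversed) {  # map back to forward coordinates
    bounds <- c(L - precise[2], L - precise[1])
  } else {
    bounds <- precise
  }
  .tail_estimate(record, read_type = cls$read_type, found = TRUE,
                 rough_start = if (prep$reversed) L - prep$rough_start else prep$rough_start,
                 tail_start = bounds[1], tail_end = bounds[2],
                 samples_per_nt = rate$samples_per_nt,
                 anchor_flagged = prep$anchor_flagged)
}
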