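# Native RNA poly(A) estimation: z-normalize and clip the raw signal, smooth
# it bidirectionally, locate the adapter-then-tail pattern by thresholding,
# refine the tail boundaries by the slope of windowed means, and convert the
# span to nucleotides with the read's translocation rate.

# zero-length sentinel carrying the reason a stage found nothing
.not_found <- function(reason) structure(numeric(0), reason = reason)
.is_found <- function(x) length(x) == 2L

#' Z-normalize a raw signal and truncate extreme values
#'
#' `(x - mean(x)) / sd(x)` per sample using the whole read's mean and
#' population standard deviation, followed by clipping to `[-clip, +clip]`.
#'
#' @param raw Numeric vector (length >= 2).
#' @param clip Truncation bound in z units (default 3).
#' @return Numeric vector of clipped z-scores.
#' @export
znormalize_clip <- function(raw, clip = 3) {
  n <- length(raw)
  if (n < 2) stop("read_too_short")
  m <- mean(raw)
  s <- sqrt(mean((raw - m)^2))  # population sd: deterministic convention
  if (s == 0) stop("flat_signal")
  pmin(pmax((raw - m) / s, -clip), clip)
}

# truncated trailing moving average: avg[i] = mean(x[max(1, i-w+1) .. i])
.trailing_mean <- function(x, w) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(0L, seq_len(n) - w)
  (cs[seq_len(n) + 1L] - cs[lo + 1L]) / (seq_len(n) - lo)
}

#' Bidirectional moving-average smoothing
#'
#' Two moving averages are computed - one running from the read start to the
#' end and one from the end to the start - and merged by point-by-point
#' maximum. The maximum merge keeps high-level segments (adapter plateau,
#' poly(A)) at full width instead of eroding their edges. Windows are
#' truncated at the signal edges (averaged over the available samples).
#'
#' @param signal Numeric vector, at least `window` samples long.
#' @param window Window size in samples (default 400).
#' @param stride Stride; only 1 is supported (every sample is smoothed).
#' @return Numeric vector of the same length as `signal`.
#' @export
bidirectional_smooth <- function(signal, window = 400L, stride = 1L) {
  if (stride != 1L) stop("only stride 1 is supported")
  if (length(signal) < window) stop("read_too_short")
  fwd <- .trailing_mean(signal, window)
  bwd <- rev(.trailing_mean(rev(signal), window))
  pmax(fwd, bwd)
}

#' Locate the rough poly(A) region by threshold segmentation
#'
#' The smoothed signal is segmented into runs above or below the threshold.
#' The sequencing-adapter signature is one above-threshold segment followed
#' by one below-threshold segment (an optional below-threshold segment at
#' the very read start is skipped); the next above-threshold segment is the
#' candidate poly(A) region and its bounds are returned.
#'
#' @param smoothed Output of [bidirectional_smooth()].
#' @param threshold Segmentation threshold in z units (default 0.3).
#' @param adapter_order `"above_below"` (default) or `"below_above"` for
#'   chemistries whose adapter presents the segments in opposite order.
#' @return `c(rough_start, rough_end)` (0-based half-open sample indices),
#'   or a zero-length vector with attribute `reason = "no_adapter_pattern"`
#'   when the pattern is not found.
#' @export
find_rough_polya <- function(smoothed, threshold = 0.3,
                             adapter_order = "above_below") {
  if (length(smoothed) == 0) stop("empty signal")
  r <- rle(smoothed > threshold)
  above <- r$values
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])  # 0-based half-open
  i <- 1L
  if (length(above) >= 1 && !above[1L]) i <- 2L  # skip leading below-segment
  want <- if (identical(adapter_order, "below_above")) c(FALSE, TRUE) else c(TRUE, FALSE)
  # match the two adapter segments, then take the next above-threshold segment
  if (i + 2L > length(above) ||
      above[i] != want[1L] || above[i + 1L] != want[2L]) {
    return(.not_found("no_adapter_pattern"))
  }
  j <- i + 2L
  while (j <= length(above) && !above[j]) j <- j + 1L
  if (j > length(above))
    return(.not_found("no_adapter_pattern"))
  c(starts[j], ends[j])
}

#' Refine poly(A) boundaries by the slope of windowed means
#'
#' Within the rough bounds, non-overlapping window means of the clipped
#' normalized signal are computed (window 25, stride 25), the slope between
#' each two consecutive means is taken, and the longest continuous run of
#' low-slope values (|slope| <= `slope_bound`) marks the precise tail. Ties
#' between equal-length runs are broken toward the earlier run. Run bounds
#' are mapped back to sample coordinates; the end is inclusive of the final
#' window. Trailing samples that do not fill a complete window are ignored.
#'
#' @param normalized Clipped z-normalized signal (whole read).
#' @param rough `c(start, end)` rough bounds, 0-based half-open.
#' @param window,stride Mean-filter window and stride in samples (default
#'   25/25; only `stride == window` is supported).
#' @param slope_bound Bound on |difference of consecutive means| (default 0.3).
#' @return `c(precise_start, precise_end)` sample indices, or a zero-length
#'   vector with attribute `reason = "no_low_slope_run"`.
#' @export
refine_polya <- function(normalized, rough, window = 25L, stride = 25L,
                         slope_bound = 0.3) {
  if (stride != window) stop("only stride == window is supported")
  rs <- rough[1]; re <- rough[2]
  span <- re - rs
  if (span < 2L * window) return(.not_found("no_low_slope_run"))
  k <- span %/% window
  seg <- normalized[(rs + 1L):(rs + k * window)]
  means <- colMeans(matrix(seg, nrow = window))
  slopes <- diff(means)
  ok <- abs(slopes) <= slope_bound
  if (!any(ok)) return(.not_found("no_low_slope_run"))
  r <- rle(ok)
  run_ends <- cumsum(r$lengths)
  run_starts <- run_ends - r$lengths + 1L
  true_runs <- which(r$values)
  best <- true_runs[which.max(r$lengths[true_runs])]  # which.max: earliest tie
  i <- run_starts[best]  # slopes i..j -> means i..j+1
  j <- run_ends[best]
  c(rs + (i - 1L) * window, rs + (j + 1L) * window)
}

#' Estimate the poly(A) tail length of a native RNA read
#'
#' Full RNA pipeline: z-normalize and clip the raw signal, smooth it
#' bidirectionally, locate the adapter-then-tail pattern by thresholding,
#' refine the tail boundaries by slope, and divide the tail span by the
#' read-specific translocation rate. Any stage that fails produces a
#' `tail_estimate` row with `found = FALSE` and the failure reason.
#'
#' @param record A `read_record` with `experiment_type = "rna"`.
#' @param config An [rna_config()].
#' @return A one-row `data.frame` of class `tail_estimate` (see
#'   [find_tails()] for the column schema).
#' @export
estimate_rna_tail <- function(record, config = rna_config()) {
  fail <- function(reason, ...) {
    .tail_estimate(record, read_type = "rna", found = FALSE,
                   failure_reason = reason, ...)
  }
  if (!identical(record$experiment_type, "rna"))
    return(fail("not_rna"))
  if (identical(record$basecall_model, "flipflop") && !config$allow_flipflop)
    return(fail("flipflop_rna_unsupported"))
  norm <- tryCatch(znormalize_clip(record$raw_signal, config$znorm_clip),
                   error = function(e) conditionMessage(e))
  if (is.character(norm)) return(fail(norm))
  smoothed <- tryCatch(
    bidirectional_smooth(norm, config$smooth_window, config$smooth_stride),
    error = function(e) conditionMessage(e))
  if (is.character(smoothed)) return(fail(smoothed))
  rough <- find_rough_polya(smoothed, config$segment_threshold,
                            config$adapter_order)
  if (!.is_found(rough)) return(fail(attr(rough, "reason")))
  precise <- refine_polya(norm, rough, config$refine_window,
                          config$refine_stride, config$slope_bound)
  if (!.is_found(precise))
    return(fail(attr(precise, "reason"),
                rough_start = rough[1], rough_end = rough[2]))
  rate <- tryCatch(select_rate(record), error = function(e) NULL)
  if (is.null(rate))
    return(fail("no_moves", rough_start = rough[1], rough_end = rough[2]))
  .tail_estimate(record, read_type = "rna", found = TRUE,
                 rough_start = rough[1], rough_end = rough[2],
                 tail_start = precise[1], tail_end = precise[2],
                 samples_per_nt = rate$samples_per_nt)
}

# shared one-row result constructor; tail_length_nt is always derived from
# the boundaries and the rate so the tabulated invariant holds exactly
.tail_estimate <- function(record, read_type, found,
                           failure_reason = NA_character_,
                           rough_start = NA_real_, rough_end = NA_real_,
                           tail_start = NA_real_, tail_end = NA_real_,
                           samples_per_nt = NA_real_,
                           anchor_flagged = NA) {
  out <- data.frame(
    read_id = record$read_id,
    file_path = if (is.null(record$source_path)) NA_character_ else record$source_path,
    read_type = read_type,
    found = found,
    failure_reason = if (found) "" else failure_reason,
    rough_start = rough_start,
    rough_end = rough_end,
    tail_start = tail_start,
    tail_end = tail_end,
    samples_per_nt = samples_per_nt,
    tail_length_nt = if (found) (tail_end - tail_start) / samples_per_nt else NA_real_,
    basecall_model = record$basecall_model,
    anchor_flagged = anchor_flagged,
    stringsAsFactors = FALSE)
  class(out) <- c("tail_estimate", "data.frame")
  out
}
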