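# Read-specific nucleotide translocation rate (raw samples per nucleotide),
# the normalizer that converts a tail span in samples into nucleotides.

#' Expand a translocation table into samples-per-single-move entries
#'
#' Each block with move m > 0 emits m entries of `n_samples / m` samples
#' (a move of two corresponds to a nucleotide translocation the basecaller
#' did not resolve as its own event, so its samples are split evenly).
#' Blocks with move 0 describe the pore dwelling on the current nucleotide
#' and are merged into the preceding emitted entry; move-0 blocks before the
#' first move are attached to the first entry. Fractional sample counts are
#' kept as reals.
#'
#' @param table A translocation table (see [translocation_table()]).
#' @return Numeric vector of positive dwell times, one per single-nucleotide
#'   move; its length equals the total move count.
#' @examples
#' tb <- translocation_table(data.frame(n_samples = c(8, 20), move = c(1L, 2L)))
#' samples_per_single_move(tb)  # 8 10 10
#' @export
samples_per_single_move <- function(table) {
  blocks <- table$blocks
  if (is.null(blocks) || nrow(blocks) == 0 || sum(blocks$move) == 0)
    stop("no_moves")
  out <- numeric(sum(blocks$move))
  pos <- 0L
  pending <- 0  # samples seen before the first move
  for (i in seq_len(nrow(blocks))) {
    n <- blocks$n_samples[i]
    m <- blocks$move[i]
    if (m > 0) {
      out[pos + seq_len(m)] <- n / m
      pos <- pos + m
      if (pending > 0) {  # leading move-0 samples attach to the first entry
        out[1L] <- out[1L] + pending
        pending <- 0
      }
    } else if (pos > 0) {
      out[pos] <- out[pos] + n  # stall on the current nucleotide
    } else {
      pending <- pending + n
    }
  }
  out
}

.translocation_rate <- function(samples_per_nt, method, n_moves_used) {
  structure(list(samples_per_nt = samples_per_nt, method = method,
                 n_moves_used = as.integer(n_moves_used)),
            class = "translocation_rate")
}

#' Geometric-mean translocation rate
#'
#' `exp(mean(log(dwells)))` over the per-move dwell times. The geometric mean
#' damps the influence of the long stalls that occur stochastically during
#' sequencing without requiring an explicit outlier threshold, and is the
#' rate estimator used for standard-model basecalls.
#'
#' @param dwells Positive numeric vector of samples per single move.
#' @return A `translocation_rate` object.
#' @export
rate_geometric_mean <- function(dwells) {
  if (length(dwells) == 0 || any(!is.finite(dwells)) || any(dwells <= 0))
    stop("dwell times must be positive")
  .translocation_rate(exp(mean(log(dwells))), "geometric_mean", length(dwells))
}

#' Trimmed arithmetic-mean translocation rate
#'
#' Arithmetic mean of the per-move dwell times after discarding the
#' `ceiling(trim_fraction * n)` largest entries. Used for flip-flop
#' basecalls, where the signal tends to be over-segmented (too many moves)
#' and a tail of large dwell outliers remains.
#'
#' @param dwells Positive numeric vector of samples per single move.
#' @param trim_fraction Fraction of the largest entries to discard
#'   (default 0.05).
#' @return A `translocation_rate` object.
#' @export
rate_trimmed_mean <- function(dwells, trim_fraction = 0.05) {
  if (length(dwells) == 0 || any(!is.finite(dwells)) || any(dwells <= 0))
    stop("dwell times must be positive")
  stopifnot(trim_fraction >= 0, trim_fraction < 1)
  n <- length(dwells)
  k <- ceiling(trim_fraction * n)
  if (k >= n) stop("all entries trimmed")
  kept <- if (k > 0) sort(dwells)[seq_len(n - k)] else dwells
  .translocation_rate(mean(kept), "trimmed_arithmetic_mean", length(kept))
}

#' Select and compute the translocation rate for a read
#'
#' Standard-model basecalls (RNA and DNA) use the geometric mean; flip-flop
#' basecalls use the arithmetic mean after discarding the 5% largest dwell
#' outliers.
#'
#' @param record A `read_record`.
#' @param trim_fraction Trim fraction for the flip-flop path.
#' @return A `translocation_rate` object.
#' @export
select_rate <- function(record, trim_fraction = 0.05) {
  dwells <- samples_per_single_move(record$translocation)
  if (identical(record$basecall_model, "flipflop"))
    rate_trimmed_mean(dwells, trim_fraction)
  else
    rate_geometric_mean(dwells)
}

#' @export
print.translocation_rate <- function(x, ...) {
  cat(sprintf("translocation rate: %.3f samples/nt (%s, %d moves)\n",
              x$samples_per_nt, x$method, x$n_moves_used))
  invisible(x)
}
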