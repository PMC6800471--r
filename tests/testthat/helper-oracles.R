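# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately naive (quadratic DP, O(n*w) loops) and share no
# code with the package.

# Smith-Waterman DP with match +1, mismatch -1, and linear gaps costing 1
# per gapped position (gap opening 0, extension 1).
sw_oracle <- function(query, subject) {
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  n <- length(q); m <- length(s)
  H <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (q[i] %in% c("A", "C", "G", "T") && q[i] == s[j]) 1 else -1
      H[i + 1, j + 1] <- max(0,
                             H[i, j] + sub,
                             H[i, j + 1] - 1,
                             H[i + 1, j] - 1)
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# naive truncated trailing/leading moving averages merged by max
smooth_oracle <- function(x, w) {
  n <- length(x)
  fwd <- vapply(seq_len(n), function(i) mean(x[max(1, i - w + 1):i]), 0)
  bwd <- vapply(seq_len(n), function(i) mean(x[i:min(n, i + w - 1)]), 0)
  pmax(fwd, bwd)
}

# run-length scan oracle for flip-flop move unification
unify_oracle <- function(moves, stride) {
  idx <- which(moves == 1)
  out <- data.frame(n_samples = numeric(0), move = integer(0))
  for (k in seq_along(idx)) {
    from <- if (k == 1) 1 else idx[k]
    to <- if (k == length(idx)) length(moves) else idx[k + 1] - 1
    out <- rbind(out, data.frame(n_samples = (to - from + 1) * stride, move = 1L))
  }
  out
}

# per-entry expansion oracle for samples-per-single-move
expand_oracle <- function(blocks) {
  out <- numeric(0)
  pending <- 0
  for (i in seq_len(nrow(blocks))) {
    n <- blocks$n_samples[i]; m <- blocks$move[i]
    if (m > 0) {
      out <- c(out, rep(n / m, m))
      if (pending > 0) { out[1] <- out[1] + pending; pending <- 0 }
    } else if (length(out) > 0) {
      out[length(out)] <- out[length(out)] + n
    } else pending <- pending + n
  }
  out
}

# linear-scan oracle for base index -> sample coordinate
base_to_sample_oracle <- function(blocks, start_sample, base_index) {
  moves_seen <- 0
  pos <- start_sample
  for (i in seq_len(nrow(blocks))) {
    if (moves_seen + blocks$move[i] >= base_index + 1) return(pos)
    moves_seen <- moves_seen + blocks$move[i]
    pos <- pos + blocks$n_samples[i]
  }
  stop("index beyond moves")
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# quick simulated read with sensible test defaults
quick_sim <- function(tail = 60, type = "rna", strand = "polyA", seed = 1, ...) {
  simulate_read(sim_params(tail_length_nt = tail, experiment_type = type,
                           strand = strand, seed = seed, ...))
}
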