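# Synthetic squiggle generation with known ground truth. The simulator
# emulates the signal anatomy the estimators rely on: a two-level adapter
# block at the read start, a low-variance homopolymer tail block at its
# characteristic normalized level, a heterogeneous sequence body with
# per-base levels, per-nucleotide dwell times with stochastic stalling, and
# an events/move table consistent with the dwells.

# Fixed per-base signal levels (design z units; the per-read calibration in
# simulate_read() recenters and rescales them). Every level sits well
# outside the tail acceptance bands; G is placed high above the RNA
# homopolymer-A plateau (0.89) so that G-rich stretches keep the smoothed
# trace elevated. Single-base levels are a deliberate simplification of
# pore k-mer models.
.sim_base_levels <- c(A = 0.45, C = -1.05, G = 2.0, T = -0.75)

# Fixed 400 nt carrier reference (synthetic): no homopolymer runs of 4+.
# The 3' terminus is a single C behind a G-rich stretch: the C makes the
# signal step at the tail/body junction far larger than the refinement
# slope bound on every read type (so boundary decisions stay crisp after
# per-read level calibration), while the following Gs keep the smoothed
# trace of short RNA tails from dipping below the segmentation threshold
# mid-tail.
.sim_body_reference <- paste0(
  "AACATACAGACCCGGTAGTAATGTAGAAGTTTACGTACGTCCACGGCGATCTGATCTATC",
  "ACATGTGCTACCAGTTACCGAGTGATCAATCATATACCTTCTCCACTGTCTGTCCTCCGC",
  "CCGGACTGTAGTGTAGCTCTTTCGAGAGGCTAGCCCTCACGGTATCAACCATTACTGAGT",
  "CGGGCTACTGGGTATTGCCTGTTCGAGACGCTAGAGTTAGTGCAGAAGTAAAGACCTGAG",
  "CTACATTGCGTGGCTTTACTAGGTGTGAGTGCGGCCGAACCGTGAAACATACGCGCATCA",
  "CAGGTGCCAAGCCCTACTAGTGGGCTGCCAATACGACTTGCTCATCCTCTTTCCGAGTCA",
  "ATTGAATCCTGGCTTGGGCTTGCAGTTAAGGAGTGGAGGC")

#' The simulator's carrier reference sequence
#'
#' A fixed synthetic 400 nt sequence used as the default read body, playing
#' the role of the known carrier a spike-in experiment would use. Its first
#' 29 bases are not the default probe; the probe is a separate configured
#' sequence placed 5' of the body.
#' @return A character string.
#' @export
sim_body_reference <- function() .sim_body_reference

# run code under a private RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

#' Simulation parameters for one synthetic read
#'
#' Defaults describe the study conditions the package is validated under:
#' native RNA at 40 samples/nt (roughly 70 nt/s at ~3 kHz sampling) and DNA
#' at 8 samples/nt (roughly 450 nt/s at 4 kHz), log-normal per-base dwell
#' variability with CV 0.3, and per-sample Gaussian noise of 0.25 in
#' normalized units.
#'
#' @param tail_length_nt True tail length in nucleotides (>= 0).
#' @param experiment_type `"rna"` or `"dna"`.
#' @param strand For DNA, whether the read carries the tail as `"polyA"`
#'   (tail at the 3' end of the called sequence) or `"polyT"` (tail near the
#'   5' end). Ignored for RNA.
#' @param rate_mean Mean translocation rate in samples per nucleotide
#'   (default 40 for RNA, 8 for DNA).
#' @param dwell_cv Coefficient of variation of the log-normal per-base dwell
#'   distribution (default 0.3). The log-normal location is `log(rate_mean)`,
#'   so the geometric mean of the dwell times is `rate_mean`.
#' @param noise_sd Per-sample Gaussian noise, in normalized signal units
#'   (default 0.25).
#' @param tail_level_z Tail signal level in normalized units. Defaults:
#'   0.89 for RNA poly(A) (the expected normalized homopolymer-A level),
#'   +0.30 for DNA poly(A) and -0.15 for DNA poly(T) (simulator choices
#'   inside the detector's |z| acceptance bands of 0.6 and 0.3).
#' @param adapter_profile List with `levels` and `lengths` describing the
#'   read-start adapter blocks (normalized units / samples).
#' @param basecall_model `"standard"` (events table) or `"flipflop"` (move
#'   vector; DNA only in practice).
#' @param barcode Name of the barcode (from `primers$barcodes`) placed 5' of
#'   the probe.
#' @param body Body sequence (default [sim_body_reference()]).
#' @param primers A [primer_config()] supplying barcode, probe and primer
#'   sequences.
#' @param move2_prob Probability that a base is merged into its
#'   predecessor's event as a move of two (standard model; default 0.05).
#' @param move0_prob Probability that an event is split with a trailing
#'   move-0 stall event (standard model; default 0.05).
#' @param ff_split_prob Probability that a base's dwell is split by a
#'   spurious extra move (flip-flop over-segmentation; default 0.2).
#' @param ff_stride Flip-flop block stride in samples (default 2).
#' @param seed Integer seed; all randomness in [simulate_read()] derives
#'   from it.
#' @param index Read index used in the read id (default 1).
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(tail_length_nt = 100L,
                       experiment_type = c("rna", "dna"),
                       strand = c("polyA", "polyT"),
                       rate_mean = NULL,
                       dwell_cv = 0.3,
                       noise_sd = 0.25,
                       tail_level_z = NULL,
                       adapter_profile = NULL,
                       basecall_model = c("standard", "flipflop"),
                       barcode = "bc01",
                       body = sim_body_reference(),
                       primers = primer_config(),
                       move2_prob = 0.05,
                       move0_prob = 0.05,
                       ff_split_prob = 0.2,
                       ff_stride = 2L,
                       seed = 1L,
                       index = 1L) {
  experiment_type <- match.arg(experiment_type)
  strand <- match.arg(strand)
  basecall_model <- match.arg(basecall_model)
  if (is.null(rate_mean))
    rate_mean <- if (experiment_type == "rna") 40 else 8
  if (is.null(tail_level_z)) {
    tail_level_z <- if (experiment_type == "rna") 0.89
    else if (strand == "polyA") 0.30 else -0.15
  }
  if (is.null(adapter_profile)) {
    adapter_profile <- if (experiment_type == "rna")
      list(levels = c(1.15, -0.75), lengths = c(1200L, 1800L))
    else
      list(levels = c(0.9, -0.9), lengths = c(400L, 400L))
  }
  stopifnot(tail_length_nt >= 0, rate_mean > 0, dwell_cv >= 0, noise_sd >= 0,
            is.finite(tail_level_z), barcode %in% names(primers$barcodes),
            nchar(body) > 0, ff_stride >= 1)
  structure(list(tail_length_nt = as.integer(tail_length_nt),
                 experiment_type = experiment_type, strand = strand,
                 rate_mean = rate_mean, dwell_cv = dwell_cv,
                 noise_sd = noise_sd, tail_level_z = tail_level_z,
                 adapter_profile = adapter_profile,
                 basecall_model = basecall_model, barcode = barcode,
                 body = body, primers = primers,
                 move2_prob = move2_prob, move0_prob = move0_prob,
                 ff_split_prob = ff_split_prob, ff_stride = as.integer(ff_stride),
                 seed = as.integer(seed), index = as.integer(index)),
            class = "sim_params")
}

# integer dwells whose cumulative sum tracks the real-valued dwells
.integer_dwells <- function(d_real) {
  d <- diff(c(0, round(cumsum(d_real))))
  pmax(d, 1)
}

# standard-model events table from per-base dwells (signal order)
.standard_events <- function(dwells, move2_prob, move0_prob) {
  n <- length(dwells)
  lens <- numeric(0); moves <- integer(0)
  i <- 1L
  while (i <= n) {
    if (i < n && runif(1) < move2_prob) {  # unresolved translocation: move 2
      lens <- c(lens, dwells[i] + dwells[i + 1L]); moves <- c(moves, 2L)
      i <- i + 2L
    } else if (dwells[i] >= 4 && runif(1) < move0_prob) {  # stall split
      d1 <- ceiling(dwells[i] / 2)
      lens <- c(lens, d1, dwells[i] - d1); moves <- c(moves, 1L, 0L)
      i <- i + 1L
    } else {
      lens <- c(lens, dwells[i]); moves <- c(moves, 1L)
      i <- i + 1L
    }
  }
  data.frame(n_samples = lens, move = moves)
}

# flip-flop move vector from per-base dwells: a move flag on the
# fixed-stride grid at each base start, plus spurious extra moves inside
# long dwells (over-segmentation). Every flag corresponds to a called base,
# so `base_rep` reports how many called bases each true base yields
# (2 when split, 0 in the degenerate case that no grid slot was free).
.flipflop_moves <- function(dwells, stride, split_prob) {
  total <- sum(dwells)
  K <- total %/% stride
  if (K < 1) stop("read too short for flip-flop table")
  starts <- c(0, cumsum(dwells))[seq_along(dwells)]
  occupied <- logical(K)
  base_rep <- integer(length(dwells))
  place <- function(idx0) {  # first free grid slot at or after idx0 (0-based)
    i <- idx0 + 1L
    while (i <= K && occupied[i]) i <- i + 1L
    if (i > K) return(NA_integer_)
    occupied[i] <<- TRUE
    i
  }
  for (i in seq_along(dwells)) {
    slot <- place(floor(starts[i] / stride))
    base_rep[i] <- if (is.na(slot)) 0L else 1L
    if (base_rep[i] == 1L && dwells[i] >= 3 * stride && runif(1) < split_prob) {
      s2 <- place(floor((starts[i] + dwells[i] / 2) / stride))
      if (!is.na(s2)) base_rep[i] <- 2L
    }
  }
  list(moves = as.integer(occupied), base_rep = base_rep)
}

#' Simulate one nanopore read with ground truth
#'
#' Builds the called sequence (barcode + probe + body, with library primers
#' and tail placement appropriate to the experiment type and strand), draws
#' integer per-base dwell times from a log-normal with geometric mean
#' `rate_mean`, assembles the signal from the adapter blocks, the tail block
#' at `tail_level_z` and per-base body levels, adds Gaussian noise, and maps
#' to integer DAC counts. The body levels are affinely recalibrated per read
#' so the emitted trace has mean 0 and variance 1 in design units, keeping
#' the estimator's read-level z-normalization aligned with the design levels
#' (tail and adapter levels are never touched). A translocation table
#' matching the requested basecall model is generated from the same dwells,
#' so both table styles of the same seed describe the same signal.
#'
#' @param params A [sim_params()] object.
#' @return A list with `record` (a [read_record()]) and `truth` (a one-row
#'   `data.frame`: `read_id`, `true_tail_start`, `true_tail_end` (0-based
#'   half-open, forward signal coordinates), `true_tail_length_nt`,
#'   `true_rate` (realized geometric mean of the integer dwells), `barcode`,
#'   `read_type`, `short_tail_warn`).
#' @export
simulate_read <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  .with_seed(p$seed + 7919L * p$index, {
    bc_seq <- unname(p$primers$barcodes[[p$barcode]])
    tail_seq <- strrep(if (p$experiment_type == "dna" && p$strand == "polyT") "T" else "A",
                       p$tail_length_nt)
    if (p$experiment_type == "rna") {
      seq5to3 <- paste0(bc_seq, p$primers$probe, p$body, tail_seq)
      # RNA translocates 3' to 5': signal-order bases are the reversed sequence
      bases_signal <- rev(strsplit(seq5to3, "")[[1]])
      tail_idx <- seq_len(p$tail_length_nt)  # tail comes first after adapter
      read_type <- "rna"
    } else if (p$strand == "polyA") {
      seq5to3 <- paste0(p$primers$front_primer, bc_seq, p$primers$probe, p$body,
                        tail_seq, reverse_complement(p$primers$end_primer))
      bases_signal <- strsplit(seq5to3, "")[[1]]
      n_head <- nchar(p$primers$front_primer) + nchar(bc_seq) +
        nchar(p$primers$probe) + nchar(p$body)
      tail_idx <- n_head + seq_len(p$tail_length_nt)
      read_type <- "polyA"
    } else {
      fwd <- paste0(p$primers$front_primer, bc_seq, p$primers$probe, p$body,
                    strrep("A", p$tail_length_nt),
                    reverse_complement(p$primers$end_primer))
      seq5to3 <- reverse_complement(fwd)
      bases_signal <- strsplit(seq5to3, "")[[1]]
      n_ep <- nchar(p$primers$end_primer)
      tail_idx <- n_ep + seq_len(p$tail_length_nt)
      read_type <- "polyT"
    }
    n_bases <- length(bases_signal)
    sigma <- sqrt(log(1 + p$dwell_cv^2))
    d_real <- p$rate_mean * exp(rnorm(n_bases, 0, sigma))
    dwells <- .integer_dwells(d_real)
    levels <- unname(.sim_base_levels[bases_signal])
    levels[tail_idx] <- p$tail_level_z
    adapter <- rep(p$adapter_profile$levels, p$adapter_profile$lengths)
    adapter_len <- length(adapter)
    v <- c(adapter, rep(levels, dwells))
    N <- length(v)
    # per-read calibration: shift/scale the non-tail base levels so the whole
    # trace is standardized in design units (see the methods vignette)
    template <- rep(c(rep(FALSE, length(p$adapter_profile$levels)),
                      !seq_len(n_bases) %in% tail_idx),
                    c(p$adapter_profile$lengths, dwells))
    target_var <- max(0.05, 1 - p$noise_sd^2)
    nB <- sum(template)
    if (nB > 1) {
      S1 <- sum(v[!template]); S2 <- sum(v[!template]^2)
      dB <- v[template]
      mB <- mean(dB); vB <- mean((dB - mB)^2)
      b <- -S1 / nB
      a2 <- (N * target_var - S2 - nB * b^2) / (nB * vB)
      if (is.finite(a2) && a2 > 0) v[template] <- sqrt(a2) * (dB - mB) + b
    }
    if (p$noise_sd > 0) v <- v + rnorm(N, 0, p$noise_sd)
    raw <- as.integer(round(v * 30 + 500))
    if (p$basecall_model == "standard") {
      blocks <- .standard_events(dwells, p$move2_prob, p$move0_prob)
      table <- translocation_table(blocks, start_sample = adapter_len)
      moves_vec <- NULL
    } else {
      ff <- .flipflop_moves(dwells, p$ff_stride, p$ff_split_prob)
      moves_vec <- ff$moves
      table <- unify_flipflop_moves(moves_vec, p$ff_stride,
                                    start_sample = adapter_len)
      # over-segmentation emits extra (duplicate) called bases; dropped
      # bases (no free grid slot) disappear from the call
      called <- rep(bases_signal, ff$base_rep)
      seq5to3 <- if (p$experiment_type == "rna")
        paste(rev(called), collapse = "") else paste(called, collapse = "")
    }
    table$move_vector <- moves_vec  # kept so FAST5 writing can round-trip
    read_id <- sprintf("sim-%d-%s-%s-%04d", p$seed,
                       p$experiment_type,
                       if (p$experiment_type == "dna") p$strand else "t",
                       p$index)
    record <- read_record(
      read_id = read_id, raw_signal = raw, sequence = seq5to3,
      translocation = table, basecall_model = p$basecall_model,
      experiment_type = p$experiment_type, source_path = NA_character_,
      sampling_rate = if (p$experiment_type == "rna") 3012 else 4000)
    before_tail <- if (length(tail_idx))
      sum(dwells[seq_len(min(tail_idx) - 1L)]) else sum(dwells)
    tail_samples <- if (length(tail_idx)) sum(dwells[tail_idx]) else 0
    truth <- data.frame(
      read_id = read_id,
      true_tail_start = adapter_len + before_tail,
      true_tail_end = adapter_len + before_tail + tail_samples,
      true_tail_length_nt = p$tail_length_nt,
      true_rate = exp(mean(log(dwells))),
      barcode = p$barcode,
      read_type = read_type,
      short_tail_warn = p$tail_length_nt > 0 &&
        tail_samples < (if (p$experiment_type == "rna") 25 else 10),
      stringsAsFactors = FALSE)
    list(record = record, truth = truth)
  })
}

#' Simulate a cohort of reads across tail-length groups
#'
#' Deterministic generation of `n` reads per requested tail length, with
#' per-read seeds derived from the cohort seed. Optionally writes the reads
#' as multi-read FAST5 fixtures (one file per group) with a truth CSV and a
#' FASTA of the called sequences.
#'
#' @param tail_lengths Integer vector of true tail lengths (one group each).
#' @param n Reads per group.
#' @param seed Cohort seed.
#' @param dir Output directory for FAST5/truth/FASTA files, or `NULL` to
#'   keep the cohort in memory only.
#' @param barcode_by_group Assign barcode `i` of the primer set to group `i`
#'   (recycled), mirroring a barcoded spike-in design. Default `TRUE`.
#' @param ... Further arguments passed to [sim_params()] (e.g.
#'   `experiment_type`, `strand`, `dwell_cv`, `noise_sd`).
#' @return A list with `records` (list of [read_record()]), `truth`
#'   (`data.frame` with one row per read) and `files` (paths, when `dir` is
#'   given).
#' @export
simulate_cohort <- function(tail_lengths, n, seed = 1L, dir = NULL,
                            barcode_by_group = TRUE, ...) {
  dots <- list(...)
  primers <- if (!is.null(dots$primers)) dots$primers else primer_config()
  bc_names <- names(primers$barcodes)
  records <- list(); truths <- list(); files <- character(0)
  for (g in seq_along(tail_lengths)) {
    group_records <- vector("list", n)
    group_truths <- vector("list", n)
    for (r in seq_len(n)) {
      args <- dots
      args$tail_length_nt <- tail_lengths[g]
      args$seed <- (seed * 10007L + g * 997L) %% 2147483647L
      args$index <- r
      if (barcode_by_group && is.null(dots$barcode))
        args$barcode <- bc_names[(g - 1L) %% length(bc_names) + 1L]
      sim <- simulate_read(do.call(sim_params, args))
      group_records[[r]] <- sim$record
      group_truths[[r]] <- sim$truth
    }
    truth_g <- do.call(rbind, group_truths)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      f <- file.path(dir, sprintf("group%02d_%03dnt.fast5", g, tail_lengths[g]))
      write_fast5(group_records, f, truth = truth_g)
      files <- c(files, f)
    }
    records <- c(records, group_records)
    truths[[g]] <- truth_g
  }
  truth <- do.call(rbind, truths)
  if (!is.null(dir)) {
    fa <- file.path(dir, "simulated_reads.fasta")
    writeLines(unlist(lapply(records, function(r)
      c(paste0(">", r$read_id), r$sequence))), fa)
    files <- c(files, fa)
  }
  list(records = records, truth = truth, files = files)
}

#' Write read records as a minimal FAST5 fixture
#'
#' Writes a multi-read FAST5 layout (`/read_<id>/Raw/Signal` plus
#' `Analyses/Basecall_1D_000/BaseCalled_template` with a `Fastq` string and
#' either an `Events` table or a `Move` vector) readable by [read_fast5()],
#' or a single-read layout (`/Raw/Reads/Read_0/...`) for one record. This is
#' a minimal dialect: real chemistry metadata is not emulated. When `truth`
#' is supplied it is written to a `<path>.truth.csv` sidecar.
#'
#' @param records List of [read_record()] objects (or a single record).
#' @param path Output file path.
#' @param truth Optional truth `data.frame` (from [simulate_read()]).
#' @param layout `"multi"` (default) or `"single"` (first record only).
#' @return `path`, invisibly.
#' @export
write_fast5 <- function(records, path, truth = NULL,
                        layout = c("multi", "single")) {
  layout <- match.arg(layout)
  if (inherits(records, "read_record")) records <- list(records)
  stopifnot(length(records) >= 1)
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  write_one <- function(rec, raw_group, analyses_parent) {
    tmpl <- paste0(analyses_parent, "/Basecall_1D_000/BaseCalled_template")
    for (g in c(analyses_parent,
                paste0(analyses_parent, "/Basecall_1D_000"), tmpl)) {
      rhdf5::h5createGroup(path, g)
    }
    rhdf5::h5write(rec$raw_signal, path, paste0(raw_group, "/Signal"))
    fastq <- paste0("@", rec$read_id, "\n", rec$sequence, "\n+\n",
                    strrep("I", nchar(rec$sequence)))
    rhdf5::h5write(fastq, path, paste0(tmpl, "/Fastq"))
    tb <- rec$translocation
    if (identical(rec$basecall_model, "flipflop")) {
      mv <- tb$move_vector
      if (is.null(mv)) {  # reconstruct flags from the unified blocks
        stride <- tb$stride
        n_blocks <- as.integer(tb$blocks$n_samples / stride)
        mv <- integer(sum(n_blocks))
        mv[c(1L, head(cumsum(n_blocks), -1) + 1L)] <- 1L
      }
      rhdf5::h5write(as.integer(mv), path, paste0(tmpl, "/Move"))
    } else {
      rhdf5::h5write(data.frame(length = as.integer(round(tb$blocks$n_samples)),
                                move = as.integer(tb$blocks$move)),
                     path, paste0(tmpl, "/Events"))
    }
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, raw_group)
    rhdf5::h5writeAttribute(rec$read_id, gid, "read_id")
    rhdf5::h5writeAttribute(rec$experiment_type, gid, "experiment_type")
    if (is.finite(rec$sampling_rate))
      rhdf5::h5writeAttribute(rec$sampling_rate, gid, "sampling_rate")
    rhdf5::H5Gclose(gid)
    tid <- rhdf5::H5Gopen(fid, tmpl)
    rhdf5::h5writeAttribute(as.integer(tb$start_sample), tid, "start_sample")
    if (identical(rec$basecall_model, "flipflop"))
      rhdf5::h5writeAttribute(as.integer(tb$stride), tid, "block_stride")
    rhdf5::H5Gclose(tid)
    rhdf5::H5Fclose(fid)
  }
  if (layout == "multi") {
    for (rec in records) {
      root <- paste0("/read_", rec$read_id)
      rhdf5::h5createGroup(path, root)
      rhdf5::h5createGroup(path, paste0(root, "/Raw"))
      write_one(rec, paste0(root, "/Raw"), paste0(root, "/Analyses"))
    }
  } else {
    rec <- records[[1]]
    rhdf5::h5createGroup(path, "/Raw")
    rhdf5::h5createGroup(path, "/Raw/Reads")
    rhdf5::h5createGroup(path, "/Raw/Reads/Read_0")
    write_one(rec, "/Raw/Reads/Read_0", "/Analyses")
  }
  if (!is.null(truth))
    utils::write.csv(truth, paste0(path, ".truth.csv"), row.names = FALSE)
  invisible(path)
}
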