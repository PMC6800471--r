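# FAST5 (HDF5) reading: raw signal, called sequence and a unified
# translocation table, for both single-read and multi-read layouts and for
# standard (events table) and flip-flop (move vector) basecaller output.

#' Construct a translocation table
#'
#' Ordered, contiguous blocks of raw signal, each annotated with the number
#' of single-nucleotide moves the basecaller detected in it. `start_sample`
#' is the 0-based raw-signal index of the first block; all sample
#' coordinates in the package are 0-based half-open.
#'
#' @param blocks `data.frame` with integer-ish columns `n_samples` (> 0) and
#'   `move` (>= 0).
#' @param start_sample 0-based index of the first block in the raw signal.
#' @param stride Block stride in samples for flip-flop tables (informational).
#' @return An object of class `translocation_table`.
#' @export
translocation_table <- function(blocks, start_sample = 0L, stride = NA_integer_) {
  stopifnot(is.data.frame(blocks), all(c("n_samples", "move") %in% names(blocks)),
            all(blocks$n_samples > 0), all(blocks$move >= 0), start_sample >= 0)
  structure(list(blocks = data.frame(n_samples = as.numeric(blocks$n_samples),
                                     move = as.integer(blocks$move)),
                 start_sample = as.integer(start_sample),
                 stride = as.integer(stride)),
            class = "translocation_table")
}

#' @export
print.translocation_table <- function(x, ...) {
  cat(sprintf("translocation table: %d blocks, %d moves, start sample %d\n",
              nrow(x$blocks), sum(x$blocks$move), x$start_sample))
  invisible(x)
}

#' Unify a flip-flop move vector into a translocation table
#'
#' Flip-flop basecallers emit a 0/1 move flag per fixed-stride signal block.
#' Consecutive blocks between move flags are merged so that each output
#' block holds all samples dwelt since the previous move (move = 1); blocks
#' before the first move are attached to the first output block.
#'
#' @param move_vector Integer vector of 0/1 flags, one per block.
#' @param block_stride Samples per block (>= 1).
#' @param start_sample 0-based raw-signal index of the first block.
#' @return A [translocation_table()] whose blocks all have move 1.
#' @examples
#' unify_flipflop_moves(c(1L, 0L, 0L, 1L, 0L), 2L)$blocks  # (6,1), (4,1)
#' @export
unify_flipflop_moves <- function(move_vector, block_stride, start_sample = 0L) {
  stopifnot(length(move_vector) >= 1, block_stride >= 1)
  move_vector <- as.integer(move_vector)
  if (!all(move_vector %in% c(0L, 1L)))
    stop("flip-flop move vector must be 0/1")
  if (sum(move_vector) == 0) stop("no_moves")
  idx <- which(move_vector == 1L)
  # samples per emitted block: from each move flag up to (excluding) the next;
  # leading blocks before the first flag are attached to the first block
  bounds <- c(1L, idx[-1L], length(move_vector) + 1L)
  n_blocks <- diff(bounds)
  translocation_table(
    data.frame(n_samples = n_blocks * as.numeric(block_stride),
               move = rep(1L, length(idx))),
    start_sample = start_sample, stride = block_stride)
}

#' Construct a read record
#'
#' The in-memory representation of one sequencing read: raw signal (DAC
#' counts), the called sequence (5' to 3'), the translocation table linking
#' signal blocks to called bases, and metadata.
#'
#' @param read_id Unique read identifier.
#' @param raw_signal Integer vector of DAC counts (length >= 1).
#' @param sequence Called nucleotide string (length >= 1).
#' @param translocation A [translocation_table()].
#' @param basecall_model `"standard"` or `"flipflop"`.
#' @param experiment_type `"rna"` or `"dna"`.
#' @param source_path Originating file (or `NA` for simulated reads).
#' @param sampling_rate Samples per second (informational).
#' @return An object of class `read_record`.
#' @export
read_record <- function(read_id, raw_signal, sequence, translocation,
                        basecall_model = c("standard", "flipflop"),
                        experiment_type = c("rna", "dna"),
                        source_path = NA_character_,
                        sampling_rate = NA_real_) {
  basecall_model <- match.arg(basecall_model)
  experiment_type <- match.arg(experiment_type)
  stopifnot(length(raw_signal) >= 1, nchar(sequence) >= 1,
            inherits(translocation, "translocation_table"))
  if (sum(translocation$blocks$move) != nchar(sequence))
    stop("translocation move count does not match sequence length")
  if (translocation$start_sample + sum(translocation$blocks$n_samples) >
      length(raw_signal))
    stop("translocation table exceeds raw signal length")
  structure(list(read_id = read_id,
                 raw_signal = as.integer(raw_signal),
                 sequence = sequence,
                 translocation = translocation,
                 basecall_model = basecall_model,
                 experiment_type = experiment_type,
                 source_path = source_path,
                 sampling_rate = sampling_rate),
            class = "read_record")
}

#' @export
print.read_record <- function(x, ...) {
  cat(sprintf("read %s [%s, %s]: %d raw samples, %d called bases\n",
              x$read_id, x$experiment_type, x$basecall_model,
              length(x$raw_signal), nchar(x$sequence)))
  invisible(x)
}

.h5_exists <- function(fid, name) rhdf5::H5Lexists(fid, name)

.h5_attr <- function(path, obj, default = NULL) {
  at <- tryCatch(rhdf5::h5readAttributes(path, obj), error = function(e) list())
  function(name) {
    v <- at[[name]]
    if (is.null(v)) default else as.vector(v)[1]
  }
}

# highest-numbered basecall analysis group under <prefix>/Analyses
.pick_basecall_group <- function(ls_df, prefix) {
  analyses <- paste0(prefix, "/Analyses")
  groups <- ls_df$name[ls_df$group == analyses &
                         grepl("^Basecall_1D_\\d+$", ls_df$name)]
  if (length(groups) == 0) return(NULL)
  nums <- as.integer(sub("^Basecall_1D_", "", groups))
  paste0(analyses, "/", groups[which.max(nums)])
}

# parse one read rooted at `prefix` ("" for single-read layout after /Raw
# normalization); returns a read_record or a character failure reason
.read_one_fast5 <- function(path, ls_df, prefix, raw_path, raw_attr_obj,
                            default_experiment, default_model) {
  full_paths <- paste0(ifelse(ls_df$group == "/", "", ls_df$group), "/", ls_df$name)
  has <- function(p) p %in% full_paths
  if (!has(raw_path)) return("no_raw_signal")
  raw <- as.integer(rhdf5::h5read(path, raw_path))
  rattr <- .h5_attr(path, raw_attr_obj)
  read_id <- rattr("read_id")
  if (is.null(read_id)) read_id <- sub("^/?read_", "", prefix)
  bc <- .pick_basecall_group(ls_df, prefix)
  if (is.null(bc)) return("no_basecall")
  tmpl <- paste0(bc, "/BaseCalled_template")
  fq_path <- paste0(tmpl, "/Fastq")
  if (!has(fq_path)) return("no_basecall")
  fq <- rhdf5::h5read(path, fq_path)
  lines <- strsplit(as.character(fq)[1], "\n", fixed = TRUE)[[1]]
  sequence <- if (length(lines) >= 2) lines[2] else lines[1]
  if (is.na(sequence) || nchar(sequence) == 0) return("no_basecall")
  tattr <- .h5_attr(path, tmpl)
  start_sample <- tattr("start_sample")
  if (is.null(start_sample)) start_sample <- 0L
  ev_path <- paste0(tmpl, "/Events")
  mv_path <- paste0(tmpl, "/Move")
  if (has(mv_path)) {
    stride <- tattr("block_stride")
    if (is.null(stride)) stride <- 2L
    moves <- as.integer(rhdf5::h5read(path, mv_path))
    table <- unify_flipflop_moves(moves, as.integer(stride),
                                  as.integer(start_sample))
    model <- "flipflop"
  } else if (has(ev_path)) {
    ev <- rhdf5::h5read(path, ev_path)
    if (!all(c("length", "move") %in% names(ev))) return("no_translocation_table")
    table <- translocation_table(
      data.frame(n_samples = as.numeric(ev$length), move = as.integer(ev$move)),
      start_sample = as.integer(start_sample))
    model <- "standard"
  } else {
    return("no_translocation_table")
  }
  experiment <- rattr("experiment_type")
  if (is.null(experiment)) experiment <- default_experiment
  sampling <- rattr("sampling_rate")
  if (is.null(sampling)) sampling <- NA_real_
  tryCatch(
    read_record(read_id = as.character(read_id), raw_signal = raw,
                sequence = sequence, translocation = table,
                basecall_model = model, experiment_type = experiment,
                source_path = path, sampling_rate = as.numeric(sampling)),
    error = function(e) "inconsistent_translocation_table")
}

#' Read base-called reads from a FAST5 file
#'
#' Supports both the multi-read layout (top-level `read_<id>` groups) and
#' the single-read layout (`/Raw/Reads/Read_<n>`), detected from the HDF5
#' group structure. For each read the raw signal, the called sequence and
#' the translocation table are extracted; the basecall model is detected as
#' flip-flop when a fixed-stride `Move` vector is present and standard when
#' an `Events` table with `length` and `move` columns is present. When
#' several `Basecall_1D_*` analysis groups exist the highest-numbered one is
#' used. Reads that cannot be extracted are skipped with a warning; the
#' failure reasons are returned in the `"failures"` attribute so that batch
#' output can report them.
#'
#' @param path Path to a FAST5 (HDF5) file.
#' @param default_experiment Experiment type assumed when the file does not
#'   record one (`"rna"` or `"dna"`).
#' @return A list of [read_record()] objects with attribute `failures`, a
#'   `data.frame` of `read_id`/`reason` for skipped reads.
#' @export
read_fast5 <- function(path, default_experiment = c("rna", "dna")) {
  default_experiment <- match.arg(default_experiment)
  if (!file.exists(path)) stop("file not found: ", path)
  ls_df <- tryCatch(rhdf5::h5ls(path, recursive = TRUE),
                    error = function(e) stop("malformed HDF5 file: ", path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  records <- list()
  failures <- data.frame(read_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  top_reads <- ls_df$name[ls_df$group == "/" & grepl("^read_", ls_df$name)]
  if (length(top_reads) > 0) {
    for (g in top_reads) {
      prefix <- paste0("/", g)
      res <- .read_one_fast5(path, ls_df, prefix,
                             raw_path = paste0(prefix, "/Raw/Signal"),
                             raw_attr_obj = paste0(prefix, "/Raw"),
                             default_experiment, "standard")
      if (is.character(res)) {
        warning("skipping ", g, " in ", basename(path), ": ", res, call. = FALSE)
        failures <- rbind(failures,
                          data.frame(read_id = sub("^read_", "", g), reason = res))
      } else records[[length(records) + 1L]] <- res
    }
  } else if (any(ls_df$group == "/Raw/Reads")) {
    sub_reads <- ls_df$name[ls_df$group == "/Raw/Reads" & grepl("^Read_", ls_df$name)]
    for (g in sub_reads) {
      res <- .read_one_fast5(path, ls_df, "",
                             raw_path = paste0("/Raw/Reads/", g, "/Signal"),
                             raw_attr_obj = paste0("/Raw/Reads/", g),
                             default_experiment, "standard")
      if (is.character(res)) {
        warning("skipping ", g, " in ", basename(path), ": ", res, call. = FALSE)
        failures <- rbind(failures, data.frame(read_id = g, reason = res))
      } else records[[length(records) + 1L]] <- res
    }
  } else {
    stop("not a recognized FAST5 layout: ", path)
  }
  attr(records, "failures") <- failures
  records
}
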