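# Batch processing over FAST5 directories, per-group summaries and per-read
# diagnostic plots.

.estimate_record <- function(record, mode, rna_cfg, dna_cfg, primers) {
  if (mode == "rna") estimate_rna_tail(record, rna_cfg)
  else estimate_dna_tail(record, dna_cfg, primers)
}

.failure_row <- function(read_id, file_path, reason, mode) {
  out <- data.frame(read_id = read_id, file_path = file_path,
                    read_type = "invalid", found = FALSE,
                    failure_reason = reason,
                    rough_start = NA_real_, rough_end = NA_real_,
                    tail_start = NA_real_, tail_end = NA_real_,
                    samples_per_nt = NA_real_, tail_length_nt = NA_real_,
                    basecall_model = NA_character_, anchor_flagged = NA,
                    stringsAsFactors = FALSE)
  class(out) <- c("tail_estimate", "data.frame")
  out
}

#' Estimate tail lengths for every read in a FAST5 directory
#'
#' Processes all `.fast5` files under `input_dir` with the RNA or DNA
#' estimator and returns one row per read, including reads whose tail could
#' not be measured (`found = FALSE` with an explicit `failure_reason`), so
#' users can apply their own filtering. Row order is deterministic (sorted
#' by file, then read id) and independent of the worker count.
#'
#' Columns: `read_id`, `file_path`, `read_type` (`rna`/`polyA`/`polyT`/
#' `invalid`), `found`, `failure_reason`, `rough_start`, `rough_end`,
#' `tail_start`, `tail_end` (0-based half-open raw-sample indices, forward
#' orientation), `samples_per_nt`, `tail_length_nt`, `basecall_model`,
#' `anchor_flagged`. Failure reasons: `no_raw_signal`, `no_basecall`,
#' `no_translocation_table`, `inconsistent_translocation_table`,
#' `read_too_short`, `flat_signal`, `no_adapter_pattern`,
#' `no_low_slope_run`, `no_moves`, `flipflop_rna_unsupported`, `truncated`,
#' `unclassified`, `no_tail_anchor`, `no_tail_signal`, `not_rna`,
#' `not_dna`, `corrupt_file`.
#'
#' @param input_dir Directory containing at least one `.fast5` file.
#' @param mode `"rna"` or `"dna"`.
#' @param rna_cfg,dna_cfg,primers Configuration objects.
#' @param workers Number of parallel workers (files are processed in
#'   parallel via [parallel::mclapply()]; results are identical to a serial
#'   run).
#' @param output_csv Optional path; when given, the table is also written as
#'   CSV (comma-separated, UTF-8, header, `NA` for missing values).
#' @param plots_dir Optional directory for per-read diagnostic plots
#'   ([plot_read()]), one PNG per read.
#' @param cap Optional upper cap applied to a `tail_length_capped` column
#'   (for plotting conventions); estimates themselves are never truncated.
#' @return A `data.frame` (class `tail_estimate`) with one row per read.
#' @export
find_tails <- function(input_dir, mode = c("rna", "dna"),
                       rna_cfg = rna_config(), dna_cfg = dna_config(),
                       primers = primer_config(), workers = 1L,
                       output_csv = NULL, plots_dir = NULL, cap = NULL) {
  mode <- match.arg(mode)
  files <- sort(list.files(input_dir, pattern = "\\.fast5$", full.names = TRUE))
  if (length(files) == 0) stop("no FAST5 files in ", input_dir)
  process_file <- function(f) {
    reads <- tryCatch(
      suppressWarnings(read_fast5(f, default_experiment = mode)),
      error = function(e) e)
    if (inherits(reads, "error"))
      return(list(rows = .failure_row(NA_character_, f, "corrupt_file", mode),
                  records = list()))
    rows <- lapply(reads, .estimate_record, mode = mode, rna_cfg = rna_cfg,
                   dna_cfg = dna_cfg, primers = primers)
    fl <- attr(reads, "failures")
    if (!is.null(fl) && nrow(fl) > 0)
      rows <- c(rows, lapply(seq_len(nrow(fl)), function(i)
        .failure_row(fl$read_id[i], f, fl$reason[i], mode)))
    list(rows = do.call(rbind, rows), records = reads)
  }
  results <- if (workers > 1L)
    parallel::mclapply(files, process_file, mc.cores = workers)
  else lapply(files, process_file)
  tab <- do.call(rbind, lapply(results, `[[`, "rows"))
  tab <- tab[order(tab$file_path, tab$read_id), , drop = FALSE]
  rownames(tab) <- NULL
  n_found <- sum(tab$found)
  reasons <- table(tab$failure_reason[!tab$found])
  message(sprintf("processed %d reads in %d files: %d with tail, %d without%s",
                  nrow(tab), length(files), n_found, nrow(tab) - n_found,
                  if (length(reasons))
                    paste0(" (", paste(names(reasons), reasons, sep = ": ",
                                       collapse = ", "), ")")
                  else ""))
  if (!is.null(cap)) tab$tail_length_capped <- pmin(tab$tail_length_nt, cap)
  if (!is.null(plots_dir)) {
    if (!dir.exists(plots_dir)) dir.create(plots_dir, recursive = TRUE)
    for (res in results) {
      for (rec in res$records) {
        est <- tab[!is.na(tab$read_id) & tab$read_id == rec$read_id, , drop = FALSE]
        if (nrow(est) == 1)
          plot_read(rec, est, file.path(plots_dir, paste0(rec$read_id, ".png")),
                    rna_cfg = rna_cfg, dna_cfg = dna_cfg)
      }
    }
  }
  if (!is.null(output_csv))
    utils::write.csv(tab, output_csv, row.names = FALSE, na = "NA")
  tab
}

#' Summarize tail estimates per group
#'
#' Per-group count, mean, median, distribution mode, standard deviation and
#' coefficient of variation of the found tail estimates. The mode is the
#' argmax of a Gaussian kernel density with Silverman's rule-of-thumb
#' bandwidth (estimates are continuous); for degenerate groups with a single
#' distinct value the mode is that value.
#'
#' @param x A `tail_estimate` table (from [find_tails()]) or a CSV path.
#' @param group_by Optional column name to group by (e.g. a barcode column
#'   joined onto the table); when `NULL` all reads form one group.
#' @param bw Kernel bandwidth selector passed to [stats::density()]
#'   (default `"nrd0"`, Silverman's rule).
#' @return A `data.frame` with columns `group`, `n`, `mean`, `median`,
#'   `mode`, `sd`, `cv_pct` (sd/mean * 100). Empty groups are omitted with
#'   a warning.
#' @export
summarize_tails <- function(x, group_by = NULL, bw = "nrd0") {
  tab <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else x
  tab <- tab[tab$found & !is.na(tab$tail_length_nt), , drop = FALSE]
  groups <- if (is.null(group_by)) rep("all", nrow(tab)) else as.character(tab[[group_by]])
  keep <- !is.na(groups)
  tab <- tab[keep, , drop = FALSE]; groups <- groups[keep]
  out <- lapply(unique(groups), function(g) {
    v <- tab$tail_length_nt[groups == g]
    if (length(v) == 0) {
      warning("empty group omitted: ", g)
      return(NULL)
    }
    mode_v <- if (length(unique(v)) == 1) v[1] else {
      d <- stats::density(v, bw = bw)
      d$x[which.max(d$y)]
    }
    data.frame(group = g, n = length(v), mean = mean(v),
               median = stats::median(v), mode = mode_v,
               sd = if (length(v) > 1) stats::sd(v) else 0,
               cv_pct = if (mean(v) != 0 && length(v) > 1)
                 stats::sd(v) / mean(v) * 100 else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-read diagnostic plot
#'
#' Draws the normalized signal with its smoothed/windowed derivatives and
#' shades the rough (light) and precise (dark) tail regions, so boundary
#' decisions can be inspected read by read. For RNA reads the bidirectional
#' smoothing and the refinement slope track are shown; for DNA reads the
#' absolute normalized signal with its window means. Output style is fixed
#' (no timestamps), so repeated calls produce identical files.
#'
#' @param record A `read_record`.
#' @param estimate The matching one-row `tail_estimate`.
#' @param out_path Output PNG path, or `NULL` to draw on the current device.
#' @param rna_cfg,dna_cfg Configuration objects (for smoothing parameters).
#' @return `out_path` (or `NULL`), invisibly.
#' @export
plot_read <- function(record, estimate, out_path = NULL,
                      rna_cfg = rna_config(), dna_cfg = dna_config()) {
  if (!is.null(out_path)) {
    grDevices::png(out_path, width = 1200, height = 700)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  norm <- tryCatch(znormalize_clip(record$raw_signal), error = function(e) NULL)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE, after = FALSE)  # restore before dev.off
  if (is.null(norm)) {
    plot(record$raw_signal, type = "l", xlab = "sample", ylab = "DAC",
         main = paste0(record$read_id, " (not normalizable)"))
    return(invisible(out_path))
  }
  shade <- function(from, to, col) {
    if (!is.na(from) && !is.na(to))
      graphics::rect(from, par("usr")[3], to, par("usr")[4],
                     col = col, border = NA)
  }
  main <- sprintf("%s [%s]  %s", record$read_id, estimate$read_type,
                  if (isTRUE(estimate$found))
                    sprintf("tail %.1f nt (%.0f-%.0f @ %.2f samples/nt)",
                            estimate$tail_length_nt, estimate$tail_start,
                            estimate$tail_end, estimate$samples_per_nt)
                  else paste("no tail:", estimate$failure_reason))
  plot(norm, type = "l", col = "grey50", xlab = "sample",
       ylab = "normalized signal", main = main)
  shade(estimate$rough_start, estimate$rough_end, grDevices::adjustcolor("palegreen", 0.3))
  shade(estimate$tail_start, estimate$tail_end, grDevices::adjustcolor("gold", 0.4))
  if (identical(record$experiment_type, "rna") &&
      length(norm) >= rna_cfg$smooth_window) {
    lines(bidirectional_smooth(norm, rna_cfg$smooth_window), col = "black", lwd = 2)
    abline(h = rna_cfg$segment_threshold, lty = 2, col = "red")
  }
  lines(norm, col = NA)
  # lower panel: windowed means and their slope over the plotted region
  w <- if (identical(record$experiment_type, "rna")) rna_cfg$refine_window else dna_cfg$mean_window
  sig <- if (identical(record$experiment_type, "rna")) norm else abs(norm)
  k <- length(sig) %/% w
  means <- colMeans(matrix(sig[seq_len(k * w)], nrow = w))
  xs <- (seq_len(k) - 0.5) * w
  plot(xs, means, type = "s", col = "darkorange", xlab = "sample",
       ylab = "window mean / slope", main = "windowed mean (orange) and slope (red)")
  lines(xs[-1], diff(means), type = "h", col = "red")
  abline(h = 0, col = "grey70")
  shade(estimate$tail_start, estimate$tail_end, grDevices::adjustcolor("gold", 0.25))
  invisible(out_path)
}
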