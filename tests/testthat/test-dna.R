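test_that("base-to-sample mapping follows the cumulative move count", {
  rec <- list(translocation = translocation_table(
    data.frame(n_samples = c(10, 10), move = c(1L, 1L))))
  expect_equal(base_to_sample(rec, 0), 0)
  expect_equal(base_to_sample(rec, 1), 10)
  rec2 <- list(translocation = translocation_table(
    data.frame(n_samples = 20, move = 2L)))
  expect_equal(base_to_sample(rec2, 1), 0)  # both bases called in one block
  expect_error(base_to_sample(rec, 2), "beyond")
  # offset by start_sample
  rec3 <- list(translocation = translocation_table(
    data.frame(n_samples = c(5, 7), move = c(1L, 1L)), start_sample = 100))
  expect_equal(base_to_sample(rec3, 1), 105)
})

test_that("base-to-sample matches a linear-scan oracle on random tables", {
  set.seed(47)
  for (i in 1:30) {
    n <- sample(3:25, 1)
    blocks <- data.frame(n_samples = sample(2:30, n, replace = TRUE),
                         move = sample(0:2, n, replace = TRUE, prob = c(.2, .7, .1)))
    if (sum(blocks$move) == 0) blocks$move[1] <- 1L
    start <- sample(0:50, 1)
    rec <- list(translocation = translocation_table(blocks, start_sample = start))
    for (b in sample(0:(sum(blocks$move) - 1), min(5, sum(blocks$move)))) {
      expect_equal(base_to_sample(rec, b),
                   base_to_sample_oracle(blocks, start, b))
    }
  }
})

test_that("DNA signal preparation anchors the rough start at the true tail", {
  for (strand in c("polyT", "polyA")) {
    sim <- quick_sim(tail = 80, type = "dna", strand = strand, seed = 700,
                     dwell_cv = 0, noise_sd = 0, move2_prob = 0, move0_prob = 0)
    prep <- prepare_dna_signal(sim$record, strand)
    expect_false(is.null(prep))
    L <- length(sim$record$raw_signal)
    true_start <- if (strand == "polyA") L - sim$truth$true_tail_end
                  else sim$truth$true_tail_start
    # within one translocation block (8 samples at the simulated rate)
    expect_lte(abs(prep$rough_start - true_start), 8)
    expect_equal(prep$reversed, strand == "polyA")
    # |z| output
    expect_true(all(prep$signal >= 0))
  }
})

test_that("signal reversal is an involution", {
  sim <- quick_sim(tail = 40, type = "dna", strand = "polyA", seed = 701)
  x <- sim$record$raw_signal
  expect_identical(rev(rev(x)), x)
  # reversal commutes with z-normalization
  expect_equal(abs(rev(znormalize_clip(x))), abs(znormalize_clip(rev(x))))
})

test_that("precise DNA tail search honors slope and mean bounds with spike bridging", {
  rate <- 10
  cfg <- dna_config()
  # clean tail of 1000 samples at |z| ~ 0.2, then high-variance body
  set.seed(53)
  body <- abs(rep(rnorm(200, 0, 1.3), each = 5)) + 0.5
  sig <- c(rep(0.2, 1000), body)
  got <- find_precise_dna_tail(sig, 0, "polyT", rate, cfg)
  expect_equal(got[1], 0)
  expect_lte(abs(got[2] - 1000), cfg$mean_window)
  # tail split by an 80-sample spike into 400 + 500 sample runs: merged
  sig2 <- c(rep(0.2, 400), rep(2, 80), rep(0.2, 500), body)
  got2 <- find_precise_dna_tail(sig2, 0, "polyT", rate, cfg)
  expect_equal(got2[1], 0)
  expect_lte(abs(got2[2] - 980), cfg$mean_window)
  # a second low-variance run beyond max_gap_nt * rate is not bridged
  sig3 <- c(rep(0.2, 400), rep(2, 2000), rep(0.2, 500))
  got3 <- find_precise_dna_tail(sig3, 0, "polyT", rate, cfg)
  expect_equal(got3, c(0, 400))
  # no tail-like window at all
  res <- find_precise_dna_tail(rep(2, 500), 0, "polyT", rate, cfg)
  expect_length(res, 0)
  expect_equal(attr(res, "reason"), "no_tail_signal")
})

test_that("bridged gaps and search window bound the precise span", {
  rate <- 8.5
  cfg <- dna_config()
  # a 350 nt tail at the typical rate still fits the search window
  tail_len <- round(350 * rate)
  sig <- c(rep(0.2, tail_len), rep(2, 400))
  got <- find_precise_dna_tail(sig, 0, "polyT", rate, cfg)
  expect_lte(abs((got[2] - got[1]) - tail_len), cfg$mean_window)
  expect_lte(got[2] - got[1], cfg$search_window)
})

test_that("noise-free simulated DNA reads are measured at their true length", {
  for (strand in c("polyA", "polyT")) {
    for (tail in c(10, 60, 150)) {
      sim <- quick_sim(tail = tail, type = "dna", strand = strand,
                       seed = 800 + tail, dwell_cv = 0, noise_sd = 0,
                       move2_prob = 0, move0_prob = 0)
      est <- estimate_dna_tail(sim$record)
      expect_true(est$found, info = paste(strand, tail))
      expect_lt(abs(est$tail_length_nt - tail), 10 / 8)
      # reported boundaries are in forward coordinates
      expect_lte(abs(est$tail_start - sim$truth$true_tail_start), 10)
      expect_lte(abs(est$tail_end - sim$truth$true_tail_end), 10)
    }
  }
})

test_that("truncated and unclassified DNA reads yield found = FALSE rows", {
  sim <- quick_sim(tail = 60, type = "dna", strand = "polyA", seed = 900)
  rec <- sim$record
  # cut off the 3' end primer: truncated poly(A) read
  rec$sequence <- substr(rec$sequence, 1, nchar(rec$sequence) - 30)
  # keep the translocation table consistent with the shortened call
  tb <- rec$translocation$blocks
  drop <- 30
  keep <- rev(cumsum(rev(tb$move))) > drop
  rec$translocation$blocks <- tb[keep, , drop = FALSE]
  extra <- sum(rec$translocation$blocks$move) - (sum(tb$move) - drop)
  if (extra > 0) {
    n <- nrow(rec$translocation$blocks)
    rec$translocation$blocks$move[n] <- rec$translocation$blocks$move[n] - extra
  }
  est <- estimate_dna_tail(rec)
  expect_false(est$found)
  expect_equal(est$failure_reason, "truncated")
  # a sequence with no primers at all
  rec2 <- sim$record
  rec2$sequence <- paste(rep("ACGT", ceiling(nchar(rec2$sequence) / 4)),
                         collapse = "")
  rec2$sequence <- substr(rec2$sequence, 1, nchar(sim$record$sequence))
  est2 <- estimate_dna_tail(rec2)
  expect_false(est2$found)
  expect_equal(est2$failure_reason, "unclassified")
})

test_that("poly(A) and poly(T) renderings of the same molecule agree on average", {
  diffs <- vapply(1:15, function(i) {
    sa <- quick_sim(tail = 80, type = "dna", strand = "polyA", seed = 1000 + i)
    st <- quick_sim(tail = 80, type = "dna", strand = "polyT", seed = 1000 + i)
    ea <- estimate_dna_tail(sa$record)
    et <- estimate_dna_tail(st$record)
    if (isTRUE(ea$found) && isTRUE(et$found))
      (ea$tail_length_nt - et$tail_length_nt) / et$tail_length_nt
    else NA_real_
  }, 0)
  expect_gt(sum(!is.na(diffs)), 10)
  expect_lt(abs(mean(diffs, na.rm = TRUE)), 0.15)
})
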