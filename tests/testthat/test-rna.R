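test_that("z-normalization centers, scales and truncates", {
  z <- znormalize_clip(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(sqrt(mean(z^2)), 1)  # population sd convention
  expect_equal(z[2], 0)
  # a sample at z = 4.2 is truncated to the clip bound
  x <- c(rnorm(1000), 0)
  x[1001] <- mean(x[1:1000]) + 4.2 * sd(x[1:1000])
  expect_equal(max(znormalize_clip(x)), 3)
  expect_error(znormalize_clip(rep(5, 10)), "flat_signal")
})

test_that("bidirectional smoothing matches a naive oracle and preserves constants", {
  expect_equal(bidirectional_smooth(rep(2.5, 50), window = 10), rep(2.5, 50))
  set.seed(41)
  for (i in 1:10) {
    x <- rnorm(sample(60:200, 1))
    w <- sample(5:40, 1)
    expect_equal(bidirectional_smooth(x, w), smooth_oracle(x, w),
                 tolerance = 1e-9)
  }
  # merged maximum dominates each directional average on a step signal
  x <- c(rep(0, 100), rep(1, 100))
  sm <- bidirectional_smooth(x, 20)
  fwd <- vapply(seq_along(x), function(i) mean(x[max(1, i - 19):i]), 0)
  expect_true(all(sm >= fwd - 1e-12))
  expect_error(bidirectional_smooth(rnorm(10), 400), "read_too_short")
})

test_that("rough poly(A) segmentation finds the segment after the adapter pattern", {
  sm <- c(rep(1, 500), rep(0, 500), rep(0.8, 800), rep(0.1, 200))
  expect_equal(find_rough_polya(sm, 0.3), c(1000, 1800))
  # leading below-threshold segment at the read start is skipped
  sm2 <- c(rep(0.1, 100), sm)
  expect_equal(find_rough_polya(sm2, 0.3), c(1100, 1900))
  # entirely above threshold: no below segment, no pattern
  res <- find_rough_polya(rep(1, 1000), 0.3)
  expect_length(res, 0)
  expect_equal(attr(res, "reason"), "no_adapter_pattern")
  res2 <- find_rough_polya(c(rep(1, 500), rep(0, 500)), 0.3)
  expect_length(res2, 0)
})

test_that("boundary refinement selects the longest low-slope run, earliest on ties", {
  w <- 25
  # flat signal across the rough span: precise equals rough up to one window
  x <- rep(0.9, 1000)
  got <- refine_polya(x, c(0, 1000), window = w)
  expect_equal(got, c(0, 1000))
  # two flat runs (10 vs 25 windows) separated by a spike: longer run wins
  mk <- function(nwin, level) rep(level, nwin * w)
  x2 <- c(mk(10, 0.9), mk(1, 3), mk(25, 0.9), mk(4, 0))
  got2 <- refine_polya(x2, c(0, length(x2)), window = w)
  expect_equal(got2, c(11 * w, 36 * w))
  # equal-length runs: the earlier one is returned
  x3 <- c(mk(10, 0.9), mk(1, 3), mk(1, -3), mk(10, 0.9), mk(2, 3))
  got3 <- refine_polya(x3, c(0, length(x3)), window = w)
  expect_equal(got3, c(0, 10 * w))
  # no qualifying run
  x4 <- rep(c(0, 3), each = w, times = 10)
  res <- refine_polya(x4, c(0, length(x4)), window = w)
  expect_length(res, 0)
  expect_equal(attr(res, "reason"), "no_low_slope_run")
})

test_that("precise boundaries always lie within the rough boundaries", {
  set.seed(43)
  for (i in 1:20) {
    x <- rnorm(2000, 0, 0.4) + rep(runif(20, -1, 1), each = 100)
    rough <- sort(sample(0:2000, 2))
    if (diff(rough) < 50) next
    got <- refine_polya(x, rough)
    if (length(got) == 2) {
      expect_gte(got[1], rough[1])
      expect_lte(got[2], rough[2])
      expect_lt(got[1], got[2])
    }
  }
})

test_that("noise-free simulated RNA reads are measured at their true length", {
  for (tail in c(10, 40, 100)) {
    sim <- quick_sim(tail = tail, type = "rna", seed = 500 + tail,
                     dwell_cv = 0, noise_sd = 0, move2_prob = 0, move0_prob = 0)
    est <- estimate_rna_tail(sim$record)
    expect_true(est$found)
    expect_lte(abs(est$tail_length_nt - tail), 25 / 40)
    # rough bounds cover the true tail block
    expect_lte(est$rough_start, sim$truth$true_tail_start)
    expect_gte(est$rough_end, sim$truth$true_tail_end)
  }
})

test_that("RNA estimates do not depend on sequence added after the tail", {
  base_body <- sim_body_reference()
  long_body <- paste0(rand_seq(300), base_body)  # extra 5' sequence: after the
  # tail in signal order, since RNA translocates 3' to 5'
  s1 <- quick_sim(tail = 80, type = "rna", seed = 600, body = base_body,
                  dwell_cv = 0, noise_sd = 0, move2_prob = 0, move0_prob = 0)
  s2 <- quick_sim(tail = 80, type = "rna", seed = 600, body = long_body,
                  dwell_cv = 0, noise_sd = 0, move2_prob = 0, move0_prob = 0)
  e1 <- estimate_rna_tail(s1$record)
  e2 <- estimate_rna_tail(s2$record)
  expect_true(e1$found && e2$found)
  expect_equal(e1$tail_length_nt, e2$tail_length_nt, tolerance = 0.026)
})

test_that("pipeline failures are reported as rows with reasons", {
  sim <- quick_sim(tail = 50, seed = 601)
  rec <- sim$record
  # strip the adapter+tail structure: pure body-like noise signal
  rec$raw_signal <- as.integer(round(rnorm(length(rec$raw_signal), 500, 30)))
  est <- estimate_rna_tail(rec)
  expect_false(est$found)
  expect_true(nzchar(est$failure_reason))
  # flip-flop RNA is refused unless explicitly allowed
  ff <- quick_sim(tail = 50, type = "rna", seed = 602, basecall_model = "flipflop")
  est_ff <- estimate_rna_tail(ff$record)
  expect_false(est_ff$found)
  expect_equal(est_ff$failure_reason, "flipflop_rna_unsupported")
  est_ok <- estimate_rna_tail(ff$record, rna_config(allow_flipflop = TRUE))
  expect_true(est_ok$found)
})

test_that("found estimates have strictly positive length and exact arithmetic", {
  sim <- quick_sim(tail = 60, type = "rna", seed = 603)
  est <- estimate_rna_tail(sim$record)
  expect_true(est$found)
  expect_gt(est$tail_length_nt, 0)
  expect_identical(est$tail_length_nt,
                   (est$tail_end - est$tail_start) / est$samples_per_nt)
})
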