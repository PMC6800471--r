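---
title: "Estimating poly(A) tails from raw nanopore signal: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating poly(A) tails from raw nanopore signal: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailtrace)
```

## Why measure tails in the raw signal

Nanopore basecallers convert current fluctuations into bases; over a long
homopolymer the current barely fluctuates, so poly(A) stretches are called
far too short. The tail is, however, conspicuous in the raw trace: a long
segment of low variance at the characteristic homopolymer level.
`tailtrace` therefore ignores the called bases *inside* the tail and works
on the raw signal, using the called sequence only where it is reliable —
to locate primers and barcodes, and to calibrate the per-read
translocation rate that converts a segment length in samples into
nucleotides.

Two assumptions carry the whole method:

* **Level assumption.** After per-read z-normalization, homopolymer-A
  signal sits near a known level (≈ 0.89 for native RNA), well separated
  from the adapter and from typical sequence-body signal.
* **Rate assumption.** The per-read average of samples per single
  nucleotide move, taken over the well-behaved part of the read, also
  applies inside the tail. All residual error of the method concentrates
  here: dwell times are heavy-tailed and stall events are stochastic, so
  single-read estimates inherit substantial variance even when the tail
  boundaries are exact.

## The RNA path

Native RNA is sequenced 3'→5', so the raw read begins with the adapter,
then the poly(A) tail, then the transcript body. Processing steps, with
the tunable parameters of `rna_config()`:

1. **Z-normalize and clip** (`znorm_clip = 3`). Whole-read mean and
   population standard deviation; values beyond ±3 are truncated so
   current spikes cannot distort later window means.
2. **Bidirectional smoothing** (`smooth_window = 400` samples,
   `smooth_stride = 1`). A trailing moving average and a leading moving
   average, merged by point-wise maximum. The maximum merge prevents the
   edges of high-level segments from being eroded: near a boundary at
   least one direction still averages over homogeneous signal. Windows
   are truncated at the read edges (averaged over available samples)
   rather than padded, which avoids fabricating edge values.
3. **Threshold segmentation** (`segment_threshold = 0.3`). The smoothed
   trace is cut into runs above/below 0.3. The adapter contributes one
   above- and one below-threshold segment; the next above-threshold
   segment is the rough poly(A) region. A below-threshold segment at the
   very read start (a stall before the adapter) is skipped. The 0.3
   threshold leaves ≈ 0.6 z-units of headroom below the expected tail
   level of 0.89 — about two standard deviations of windowed signal — and
   `adapter_order` can be flipped for chemistries presenting the segments
   the other way around.
4. **Refinement** (`refine_window = refine_stride = 25`,
   `slope_bound = 0.3`). Non-overlapping 25-sample means inside the rough
   region; slopes are differences of consecutive means (per window step,
   not divided by the stride — the 0.3 bound is calibrated to that
   scale). The longest run with |slope| ≤ 0.3 is the precise tail; ties
   go to the earliest run so output is deterministic. Only complete
   windows are used; boundaries are quantized to one window (25 samples,
   i.e. well under 1 nt at typical RNA rates of tens of samples per
   nucleotide).
5. **Normalization.** Tail length = (precise span in samples) / rate,
   with the rate from the events table (below).

Flip-flop basecalled RNA is not an expected input and is refused unless
`allow_flipflop = TRUE`.

## The DNA path

cDNA is double-stranded: one strand carries the tail as poly(A) at its 3'
end, the other as poly(T) right after the end primer. The signal is
co-linear with the called sequence, so primer alignments anchor
everything:

1. **Classification.** Front and end primers are aligned against the
   first 100 bases (`primer_prefix`); the higher normalized score above
   0.6 decides poly(A) vs poly(T). Poly(A) candidates must also contain
   the reverse-complement end primer within the last 50 bases
   (`end_check_suffix`) — otherwise the molecule ended before the tail
   and the read is reported `truncated`. Sequences shorter than 100 bases
   are classified on what is there and flagged `short_read`.
2. **Anchoring.** The tail-adjacent end of the end-primer alignment is
   mapped to a raw-sample coordinate through the cumulative move count of
   the translocation table. Poly(A) signals are index-reversed first
   (reversal commutes with z-normalization), so both read types present
   the tail near the scan start.
3. **Precise boundaries** (`mean_window = mean_stride = 10`,
   `slope_bound = 0.2`, `search_window = 3000`). On 10-sample window
   means of |z| within 3000 samples of the anchor — wide enough for
   ~350 nt tails at typical DNA rates — the first window satisfying the
   slope bound *and* the read-type mean band ((0, 0.3) for poly(T),
   (0, 0.6) for poly(A); the lower bound is vacuous on |z| but retained
   for fidelity to the band definition) starts the tail; the first
   subsequent violation tentatively ends it. The first window has no
   defined slope and is treated as slope 0.
4. **Spike bridging** (`min_tail_run = 60` samples, `max_gap_nt = 120`).
   Brief non-tail-like spikes occur randomly inside real tails. If
   another tail-like run of at least 60 samples starts within
   120 × rate samples of the tentative end, the end moves past the spike.
   Bridging is applied iteratively (each bridged gap individually
   bounded); `bridge_iterative = FALSE` restores a single bridging step.
   The bridging run must satisfy both the slope and the mean criterion,
   matching the tail-start definition.

Reported coordinates are always in forward raw-signal orientation, also
for poly(A) reads scanned in reverse. If the move table claims more
samples than the raw signal contains (beyond `anchor_tolerance = 50`),
the row is flagged `anchor_flagged` rather than silently trusted.

## Translocation rate

`samples_per_single_move()` expands the events/move table into one dwell
per single-nucleotide move: a move of *m* > 1 yields *m* equal entries
(the basecaller missed *m* − 1 translocations; the even split generalizes
the documented move-of-two rule), and move-0 blocks — stalls on the
current nucleotide — merge into the preceding entry, which conserves
total dwell time. Whether stall samples belong to the preceding or
following move is not observable; the preceding-move convention matches
the merge rule used for flip-flop move vectors.

Two estimators:

* `rate_geometric_mean()` — `exp(mean(log(d)))`, used for standard-model
  basecalls. The geometric mean damps heavy-tailed stalls without an
  arbitrary outlier threshold.
* `rate_trimmed_mean()` — arithmetic mean after discarding the
  `ceiling(0.05 n)` largest dwells, used for flip-flop basecalls, whose
  fixed-stride move vectors over-segment homopolymers (too many moves,
  hence many spuriously short dwells plus a surviving tail of long
  ones). The ceiling guarantees at least one discarded entry.

Because the tail span reflects the *arithmetic* sum of dwells while the
normalizer is a *geometric* mean, estimates carry a small positive bias
of order `exp(sigma^2/2)` under log-normal dwell variability (≈ 4% at
CV 0.3). This is a property of the method, not of the implementation.

## Alignment, classification thresholds and demultiplexing

All alignments are Smith–Waterman with match +1, mismatch −1, gap opening
0 and gap extension 1 (a gap of length *k* costs *k*), computed via
Biostrings; scores are normalized by query length. Characters outside
ACGT mismatch everything, including themselves. Hits below 0.6 are
considered unspecific; the DNA orientation test uses 0.5. Whether the
barcode step after DNA orientation should use 0.5 or 0.6 is ambiguous in
the method description; the stricter 0.6 is the default and both are
configurable through `primer_config()`.

RNA demultiplexing locates the probe (the first bases of the known
carrier) within the first 250 bases and scores each barcode on the
preceding subsequence; the best score above threshold wins and exact ties
are reported `ambiguous` rather than broken arbitrarily. For DNA the
orientation is decided first — probe against the first 250 bases versus
reverse-complement probe against the **last** 250 bases. Restricting the
reverse probe to the read start would only work for inserts shorter than
~200 nt; scanning the read end makes the procedure strand-symmetric for
arbitrary insert lengths, and reverse reads are then reverse-complemented
and demultiplexed by the forward routine (front primer before the probe,
barcodes scored between them).

## The squiggle simulator

`simulate_read()` emulates exactly the features the estimators key on:

* a two-level adapter block (above/below the segmentation threshold);
* a tail plateau at `tail_level_z` — 0.89 for RNA (the expected
  normalized homopolymer-A level), +0.30 for DNA poly(A) and −0.15 for
  DNA poly(T), simulator choices placed inside the detector's |z|
  acceptance bands of 0.6 and 0.3, which are stated as two-standard-
  deviation containment bands rather than levels;
* per-base body levels from a fixed four-level table (A 0.45, C −1.05,
  G 2.0, T −0.75 in design units) over a fixed 400 nt synthetic carrier
  plus barcode, probe and, for DNA, primers;
* integer per-base dwells `rate_mean × LogNormal(0, sigma)` with
  `sigma = sqrt(log(1 + dwell_cv^2))`, so the *geometric* mean of dwells
  equals `rate_mean` — aligning the simulator's truth with the
  estimator's normalizer; cumulative rounding preserves totals;
* Gaussian per-sample noise (`noise_sd`, design z units);
* a translocation table in either style: standard events with occasional
  move-2 merges (5%) and move-0 stall splits (5%), or a stride-2
  flip-flop move vector whose spurious extra moves (20% of long dwells)
  emit duplicate called bases — both styles of one seed share the
  identical raw signal, which is what makes basecaller-concordance
  experiments meaningful.

Default conditions: RNA at 40 samples/nt (~70 nt/s at ~3 kHz sampling),
DNA at 8 samples/nt (~450 nt/s at 4 kHz), dwell CV 0.3, noise 0.25.

Two deliberate design choices deserve explanation:

* **Per-read level calibration.** The estimator z-normalizes each read by
  its own mean/sd, so design levels only survive into the detector's
  coordinate system if the emitted trace is itself standardized. The
  simulator therefore recenters/rescales the *body* levels per read so
  the full trace has mean 0 and variance 1 (minus the noise variance) in
  design units; adapter and tail levels are never touched, keeping the
  0.89 plateau exact under estimator normalization.
* **Carrier terminus.** The tail-adjacent end of the carrier is a single
  C behind a G-rich stretch. The C puts a signal step at the tail/body
  junction that is far larger than any slope bound on every read type —
  so boundary windows cannot leak into the body regardless of the
  calibration scale — while the following Gs keep the backward smoothing
  average high enough that even a 10 nt RNA tail (one smoothing window of
  signal) stays above the segmentation threshold throughout. Real
  spike-in constructs give the same kind of guarantee by fixing the
  sequence adjacent to the tail.

What the simulator does **not** emulate: k-mer-dependent levels (each
base has one level), basecall errors beyond over-segmentation duplicates,
current drift, chimeric or adapter-less reads, and the simulated basecall
resolves the tail at the nominal rate (real basecallers under-call it —
immaterial for the estimators, which never read tail bases, but it makes
noise-free recovery exact by construction). Passing tests on simulated
reads therefore demonstrates correctness of the *signal processing*, not
performance on real flowcell data, where boundary noise and rate
variability are larger.

## Validation conditions and problem sizes

The test suite validates, among others: alignment scores against an
independent quadratic DP oracle (200 random pairs); exact noise-free
recovery at tail lengths 10–150 nt on all three paths (tolerance: one
refinement window, i.e. 25/rate nt for RNA and 10/rate nt for DNA);
median recovery within 10% for lengths ≥ 30 nt under dwell CV 0.3 and
noise 0.25 (50 reads per length group and path); rate estimators against
sort/expand oracles including move-of-two splitting; Pearson r ≥ 0.9
between standard and flip-flop renderings of 200 DNA reads; spike
bridging versus the 120 nt gap bound; and ≥ 99% barcode recovery on
error-free reads, strand-symmetric for DNA. `scripts/acceptance.R` reruns
the cohort computations end to end (the RNA cohort through written FAST5
fixtures) and writes the resulting modes, CVs, concordance and demux
accuracy as JSON. Cohort sizes were chosen so the whole suite runs in
about a minute on a single core while keeping 50 reads per group, the
size at which group medians are stable.

## Known limitations

* Single-read estimates are noisy (CVs of tens of percent on real data);
  the method is designed for distributional statements per
  transcript/barcode group.
* RNA tails much shorter than the smoothing window are at the edge of
  detectability; on real data they tend to be overestimated.
* Reads whose adapter was not captured, or DNA reads missing both
  primers, are reported as failures, not estimated.
* The translocation rate is assumed position-independent within a read;
  local rate modelling is out of scope.
* POD5/BLOW5 containers and live (during-run) processing are not
  supported.
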