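test_that("local alignment matches identity and no-match base cases", {
  a <- local_align("ACGT", "ACGT")
  expect_equal(a$score, 4)
  expect_equal(a$normalized_score, 1.0)
  b <- local_align("AAAA", "TTTT")
  expect_equal(b$score, 0)
  expect_equal(b$normalized_score, 0)
  expect_error(local_align("", "ACGT"), "empty_sequence")
})

test_that("local alignment agrees with an independent DP oracle on random pairs", {
  set.seed(42)
  for (i in 1:60) {
    q <- rand_seq(sample(3:20, 1))
    s <- rand_seq(sample(3:20, 1))
    expect_equal(local_align(q, s)$score, sw_oracle(q, s),
                 info = paste(q, s))
  }
})

test_that("normalized score is invariant to padding the subject with unrelated sequence", {
  set.seed(7)
  q <- rand_seq(15)
  subject <- paste0("CCCC", q, "GGGG")
  padded <- paste0(rand_seq(30), subject, rand_seq(30))
  s1 <- local_align(q, subject)$normalized_score
  s2 <- local_align(q, padded)$normalized_score
  expect_equal(s1, 1)
  expect_gte(s2, s1)  # padding can only add, never remove, the exact hit
  expect_equal(s2, 1)
})

test_that("non-ACGT characters act as universal mismatches", {
  expect_equal(local_align("ANNA", "ANNA")$score, sw_oracle("ANNA", "ANNA"))
  expect_equal(local_align("NNNN", "NNNN")$score, 0)
})

test_that("reverse_complement follows the complement rule and is an involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAAC"), "GTTT")
  set.seed(3)
  for (i in 1:10) {
    s <- rand_seq(sample(5:40, 1))
    expect_equal(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("DNA reads are classified by competing primer alignments", {
  primers <- primer_config()
  mk <- function(seq) list(sequence = seq, experiment_type = "dna")
  set.seed(11)
  body <- rand_seq(400)
  polyA_seq <- paste0(primers$front_primer, body,
                      reverse_complement(primers$end_primer))
  expect_equal(classify_dna_read(mk(polyA_seq), primers)$read_type, "polyA")
  polyT_seq <- paste0(primers$end_primer, strrep("T", 30), body)
  expect_equal(classify_dna_read(mk(polyT_seq), primers)$read_type, "polyT")
  truncated_seq <- paste0(primers$front_primer, body)  # no end primer at 3'
  expect_equal(classify_dna_read(mk(truncated_seq), primers)$read_type, "truncated")
  expect_equal(classify_dna_read(mk(body), primers)$read_type, "unclassified")
})

test_that("short DNA reads are classified on the full sequence and flagged", {
  primers <- primer_config()
  seq <- paste0(primers$end_primer, strrep("T", 20))
  cls <- classify_dna_read(list(sequence = seq, experiment_type = "dna"), primers)
  expect_equal(cls$read_type, "polyT")
  expect_true(cls$short_read)
})

test_that("RNA demux recovers the barcode and reports failure reasons", {
  primers <- primer_config()
  set.seed(13)
  body <- rand_seq(300)
  for (bc in names(primers$barcodes)) {
    seq <- paste0(primers$barcodes[[bc]], primers$probe, body)
    got <- demux_barcode_rna(list(sequence = seq), primers)
    expect_equal(as.character(got), bc)
  }
  no_probe <- demux_barcode_rna(list(sequence = body), primers)
  expect_true(is.na(no_probe))
  expect_equal(attr(no_probe, "reason"), "no_probe")
})

test_that("RNA demux prefers the closer barcode and reports exact ties as ambiguous", {
  base <- "ACCATTGCGAAGGTCA"
  mutate_at <- function(s, i, to) { substr(s, i, i) <- to; s }
  bc_far <- "TGGTCATCTCTAGCTG"
  read_bc <- mutate_at(base, 3, "G")  # Hamming 1 from base
  primers <- primer_config(barcodes = c(near = base, far = bc_far))
  seq <- paste0(read_bc, primers$probe, rand_seq(100))
  expect_equal(as.character(demux_barcode_rna(list(sequence = seq), primers)),
               "near")
  # two candidates at the same distance from the read barcode: tie
  primers2 <- primer_config(barcodes = c(
    a = mutate_at(base, 2, "G"), b = mutate_at(base, 5, "G")))
  seq2 <- paste0(base, primers2$probe, rand_seq(100))
  got <- demux_barcode_rna(list(sequence = seq2), primers2)
  expect_true(is.na(got))
  expect_equal(attr(got, "reason"), "ambiguous")
})

test_that("DNA demux is strand-symmetric and fails without orientation", {
  primers <- primer_config()
  set.seed(17)
  body <- rand_seq(350)
  for (bc in names(primers$barcodes)[1:3]) {
    fwd <- paste0(primers$front_primer, primers$barcodes[[bc]], primers$probe,
                  body, strrep("A", 40),
                  reverse_complement(primers$end_primer))
    rec_f <- list(sequence = fwd, experiment_type = "dna")
    rec_r <- list(sequence = reverse_complement(fwd), experiment_type = "dna")
    expect_equal(as.character(demux_barcode_dna(rec_f, primers)), bc)
    expect_equal(as.character(demux_barcode_dna(rec_r, primers)), bc)
  }
  got <- demux_barcode_dna(list(sequence = rand_seq(400)), primers)
  expect_true(is.na(got))
  expect_equal(attr(got, "reason"), "no_orientation")
})

test_that("primer configuration round-trips through FASTA and threshold files", {
  fa <- system.file("extdata", "default_primers.fasta", package = "tailtrace")
  th <- system.file("extdata", "default_thresholds.txt", package = "tailtrace")
  cfg <- read_primer_config(fa, th)
  ref <- primer_config()
  expect_equal(cfg$front_primer, ref$front_primer)
  expect_equal(cfg$end_primer, ref$end_primer)
  expect_equal(cfg$probe, ref$probe)
  expect_equal(cfg$barcodes, ref$barcodes)
  expect_equal(cfg$score_threshold, 0.6)
  expect_equal(cfg$orientation_threshold, 0.5)
  expect_error(read_primer_config(th), "lacks|read")
})
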