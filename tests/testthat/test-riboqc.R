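toy_tx <- function() {
  # one gene: 10 nt 5'UTR, 30 nt CDS, 10 nt 3'UTR
  tx <- data.frame(gene_id = "g1",
                   utr5 = "ACGTACGTAC",
                   cds = "ATGAAACCCGGGTTTAAACCCGGGTTTTAA",
                   utr3 = "ACGTACGTAC", stringsAsFactors = FALSE)
  class(tx) <- c("transcriptome", "data.frame")
  tx
}

test_that("feature mapping rates partition reads by anchor region", {
  tx <- toy_tx()
  reads <- data.frame(gene_id = "g1", pos5 = c(0, 12, 25, 42),
                      length = rep(5, 4))
  r <- feature_mapping_rates(reads, tx, offset = 0)
  expect_equal(sum(r), 1)
  expect_equal(as.numeric(r), c(0.25, 0.5, 0.25))

  cds_only <- data.frame(gene_id = "g1", pos5 = c(10, 20, 39), length = 1)
  expect_equal(as.numeric(feature_mapping_rates(cds_only, tx)),
               c(0, 1, 0))

  expect_error(feature_mapping_rates(reads[0, ], tx), "no reads")
  expect_error(feature_mapping_rates(
    data.frame(gene_id = "g1", pos5 = 49, length = 5), tx), "read 1")
})

test_that("simulator leakage shows up as the expected CDS fraction", {
  tx <- make_transcriptome(20, seed = 2)
  rr <- simulate_rpf_reads(tx, 1, n_reads = 1e5, leakage = 0.05, seed = 3)
  r <- feature_mapping_rates(rr, tx, offset = 12)
  expect_lt(abs(r[["cds"]] - 0.95), 0.01)
})

test_that("metagene normalizes per transcript and is scale invariant", {
  tx <- toy_tx()
  # window of 3 positions at the start codon; counts 0, 2, 2
  reads <- data.frame(gene_id = "g1",
                      pos5 = c(11, 11, 12, 12), length = 3)
  prof <- metagene(reads, tx, "start", window = c(0, 2), offset = 0)
  expect_equal(prof$positions, 0:2)
  expect_equal(prof$density, c(0, 1.5, 1.5))  # counts / mean(4/3)

  doubled <- rbind(reads, reads)
  prof2 <- metagene(doubled, tx, "start", window = c(0, 2), offset = 0)
  expect_equal(prof2$density, prof$density)
})

test_that("metagene start profile is flat inside a uniform CDS and empty upstream", {
  tx <- make_transcriptome(30, seed = 9)
  reg <- transcript_regions(tx)
  set.seed(1)
  reads <- do.call(rbind, lapply(seq_len(nrow(reg)), function(g) {
    p <- reg$cds_start[g] +
      sample.int(reg$cds_length[g] - 30L, 1000, replace = TRUE) - 1L
    data.frame(gene_id = reg$gene_id[g], pos5 = p, length = 30L)
  }))
  prof <- metagene(reads, tx, "start", window = c(-20, 40), offset = 0)
  up <- prof$density[prof$positions < 0]
  down <- prof$density[prof$positions >= 5 & prof$positions <= 35]
  expect_true(all(up == 0))
  expect_true(all(abs(down - mean(down)) / mean(down) < 0.4))
})

test_that("P-site calibration recovers the planted offset and breaks ties low", {
  tx <- make_transcriptome(40, seed = 12)
  rr <- simulate_rpf_reads(tx, 1, offset = 12, frame_fidelity = 0.85,
                           n_reads = 1e5, seed = 13)
  cal <- calibrate_psite(rr, tx)
  expect_true(all(cal$per_length$offset == 12))
  expect_equal(cal$consensus, 12)

  # exact tie: two reads of one length, each hitting the start under a
  # different candidate offset
  tx1 <- toy_tx()
  reads <- data.frame(gene_id = "g1", pos5 = c(0, 5), length = 20)
  cal2 <- calibrate_psite(reads, tx1, candidate_offsets = c(5, 10),
                          min_reads = 1)
  expect_equal(cal2$per_length$offset, 5)
  expect_equal(cal2$consensus, 5)
  expect_error(calibrate_psite(reads, tx1, candidate_offsets = 0,
                               min_reads = 1), "support")
})

test_that("phasing estimates the planted frame fidelity without bias", {
  tx <- make_transcriptome(30, seed = 21)
  pure <- simulate_rpf_reads(tx, 1, frame_fidelity = 1, n_reads = 2e4,
                             leakage = 0, seed = 22)
  ph <- phasing(pure, tx, 12L)
  expect_equal(unname(ph$fractions[1]), 1)
  expect_equal(sum(ph$fractions), 1, tolerance = 1e-12)

  errs <- vapply(1:5, function(s) {
    rr <- simulate_rpf_reads(tx, 1, frame_fidelity = 0.8, n_reads = 1e5,
                             seed = 100 + s)
    abs(phasing(rr, tx, calibrate_psite(rr, tx))$fractions[[1]] - 0.8)
  }, numeric(1))
  expect_lt(mean(errs), 0.01)
})
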