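test_that("transcriptome generation is deterministic and honors CDS grammar", {
  tx1 <- make_transcriptome(40, seed = 7)
  tx2 <- make_transcriptome(40, seed = 7)
  expect_identical(tx1, tx2)
  expect_false(identical(tx1, make_transcriptome(40, seed = 8)))

  reg <- transcript_regions(tx1)
  expect_true(all(reg$cds_length %% 3 == 0))
  expect_true(all(substr(tx1$cds, 1, 3) == "ATG"))
  expect_true(all(substr(tx1$cds, reg$cds_length - 2, reg$cds_length) %in%
                    c("TAA", "TAG", "TGA")))
  internal_stops <- vapply(tx1$cds, function(s) {
    codons <- substring(s, seq(4, nchar(s) - 5, 3), seq(6, nchar(s) - 3, 3))
    any(codons %in% c("TAA", "TAG", "TGA"))
  }, logical(1))
  expect_false(any(internal_stops))
})

test_that("realized GC tracks the per-region target for long regions", {
  tx <- make_transcriptome(30, lengths = list(utr5 = c(300L, 400L),
                                              cds_codons = c(150L, 200L),
                                              utr3 = c(1000L, 1000L)),
                           gc = c(utr5 = 0.6, cds = 0.5, utr3 = 0.7),
                           seed = 11)
  gc3 <- vapply(tx$utr3, function(s) {
    b <- strsplit(s, "")[[1]]; mean(b %in% c("G", "C"))
  }, numeric(1))
  expect_true(all(gc3 >= 0.6 & gc3 <= 0.8))
  expect_error(make_transcriptome(5, gc = c(utr5 = 0.9, cds = 0.5,
                                            utr3 = 0.5)),
               "GC target")
})

test_that("planted modes follow the documented mode-to-effect map", {
  ids <- sprintf("g%03d", 1:400)
  st <- plant_modes(ids, c(stable = 1), seed = 1)
  expect_true(all(st$true_mrna_log2fc == 0 & st$true_rpf_log2fc == 0))

  tr <- plant_modes(ids, c(transcriptional = 1), effect_size = 1, seed = 2)
  expect_true(all(abs(tr$true_mrna_log2fc) == 1 & tr$true_rpf_log2fc == 0))

  mix <- plant_modes(ids, MODE_MIX_0H, effect_size = 1.5, seed = 3)
  consistent <- vapply(seq_len(nrow(mix)), function(i) {
    m <- mix$true_mrna_log2fc[i]; r <- mix$true_rpf_log2fc[i]
    switch(mix$mode[i],
           homodirectional = abs(m) == 1.5 && r == m,
           opposite        = abs(m) == 1.5 && r == -m,
           transcriptional = abs(m) == 1.5 && r == 0,
           translational   = m == 0 && abs(r) == 1.5,
           stable          = m == 0 && r == 0)
  }, logical(1))
  expect_true(all(consistent))
  expect_error(plant_modes(ids, c(stable = 0.5)), "sum to 1")
  expect_error(plant_modes(ids, c(stable = 1.2, transcriptional = -0.2)),
               "non-negative")
})

test_that("realized mode counts stay inside multinomial 99% bands", {
  n <- 2000
  mix <- plant_modes(sprintf("g%d", 1:n), MODE_MIX_0H, seed = 5)
  for (m in names(MODE_MIX_0H)) {
    p <- MODE_MIX_0H[[m]]
    lo <- qbinom(0.005, n, p); hi <- qbinom(0.995, n, p)
    expect_gte(sum(mix$mode == m), lo)
    expect_lte(sum(mix$mode == m), hi)
  }
})

test_that("simulated counts match NB moment identities", {
  n <- 1e6
  pois <- simulate_counts(rep(1 / n, n), 0, n_reps = 1, depth = 100 * n,
                          phi = 0, seed = 9)
  expect_true(var(as.numeric(pois)) / mean(pois) > 0.99 &&
                var(as.numeric(pois)) / mean(pois) < 1.01)

  nb <- simulate_counts(rep(1 / n, n), 0, n_reps = 1, depth = 100 * n,
                        phi = 0.1, seed = 10)
  v <- var(as.numeric(nb))
  expect_lt(abs(v - 1100) / 1100, 0.05)  # mu + phi mu^2 = 1100 at mu = 100

  expect_identical(simulate_counts(rep(0.01, 100), 0, 4, 1e5, 0.05, seed = 3),
                   simulate_counts(rep(0.01, 100), 0, 4, 1e5, 0.05, seed = 3))
})

test_that("RPF read simulator honors offset, fidelity and leakage", {
  tx <- make_transcriptome(20, seed = 2)
  reg <- transcript_regions(tx)

  perfect <- simulate_rpf_reads(tx, 1, offset = 12, frame_fidelity = 1,
                                n_reads = 5000, leakage = 0, seed = 4)
  idx <- match(perfect$gene_id, reg$gene_id)
  p <- perfect$pos5 + 12
  expect_true(all(p >= reg$cds_start[idx] & p < reg$cds_end[idx]))
  expect_true(all((p - reg$cds_start[idx]) %% 3 == 0))
  expect_true(all(perfect$pos5 >= 0 &
                    perfect$pos5 + perfect$length <= reg$tx_length[idx]))

  third <- simulate_rpf_reads(tx, 1, offset = 12, frame_fidelity = 1 / 3,
                              n_reads = 1e5, leakage = 0, seed = 5)
  fr <- (third$pos5 + 12 - reg$cds_start[match(third$gene_id,
                                               reg$gene_id)]) %% 3
  for (f in 0:2) expect_lt(abs(mean(fr == f) - 1 / 3), 0.02)

  expect_error(simulate_rpf_reads(tx, 1, offset = 40), "offset")
})

test_that("miRNA site planting inserts the reverse-complement seed site", {
  tx <- make_transcriptome(30, seed = 6)
  mir <- c(mirA = "AAACCGGUCCAUGGUACGAUCG")  # seed (nt 2-8) = AACCGGU
  res <- plant_mirna_targets(tx, mir, site_count_probs = c(0, 0, 1),
                             seed = 7)
  expect_true(all(vapply(res$transcripts$utr3, function(u)
    grepl("ACCGGTT", u, fixed = TRUE), logical(1))))
  expect_true(all(res$site_counts >= 2))

  none <- plant_mirna_targets(tx, mir, site_count_probs = c(1), seed = 8)
  chance <- count_seed_sites(mir, tx)
  expect_identical(none$site_counts, chance)
  expect_identical(none$transcripts$utr3, tx$utr3)
})

test_that("tsRNA reads are cut at the stated landmarks", {
  refs <- make_trna_references(6, seed = 3)
  five <- simulate_tsrna_reads(refs, data.frame(origin = "5p-mature",
                                                class = "tRH",
                                                fraction = 1),
                               n_reads = 200, seed = 4)
  expect_true(all(five$origin == "5p-mature"))
  expect_true(all(five$start == refs$mature_start[match(five$ref_id,
                                                        refs$ref_id)]))
  expect_true(all(five$class == "tRH"))

  three <- simulate_tsrna_reads(refs, data.frame(origin = "3p-mature",
                                                 class = "tRF",
                                                 fraction = 1),
                                n_reads = 200, seed = 5)
  ends <- three$start + three$length
  ref_len <- nchar(refs$seq[match(three$ref_id, refs$ref_id)])
  expect_true(all(ends == ref_len))  # CCA-tailed 3' terminus
  expect_true(all(substr(three$seq, nchar(three$seq) - 2,
                         nchar(three$seq)) == "CCA"))
  # reads are exact substrings of their reference
  expect_true(all(vapply(seq_len(nrow(three)), function(i)
    grepl(three$seq[i], refs$seq[match(three$ref_id[i], refs$ref_id)],
          fixed = TRUE), logical(1))))

  bad <- refs; bad$acloop_start <- NULL
  expect_error(simulate_tsrna_reads(bad, n_reads = 10, seed = 1),
               "acloop_start")
})
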