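test_that("seed extraction and site counting follow hand examples", {
  expect_equal(seed_region("UAACCGGUCCAUG"), "AACCGGU")
  expect_error(seed_region("UAACNGGUCC"), "position 5")
  expect_error(seed_region("UAACCGG"), ">= 8")

  tx <- data.frame(gene_id = c("g1", "g2"),
                   utr5 = "", cds = "ATGTAA",
                   utr3 = c("TTAACCGGTAA", ""), stringsAsFactors = FALSE)
  class(tx) <- c("transcriptome", "data.frame")
  # smallRNA with seed ACCGGUU (nt 2-8): site = revcomp = AACCGGT
  m <- count_seed_sites(c(s1 = "CACCGGUUAAAA"), tx)
  expect_equal(unname(m["s1", ]), c(1L, 0L))
  # overlapping occurrences all count
  tx$utr3[1] <- "AAAAAAA"
  m2 <- count_seed_sites(c(s2 = "UUUUUUUUUUUU"), tx)  # site AAAAAAA
  expect_equal(unname(m2["s2", "g1"]), 1L)
  tx$utr3[1] <- "AAAAAAAA"
  expect_equal(unname(count_seed_sites(c(s2 = "UUUUUUUUUUUU"),
                                       tx)["s2", "g1"]), 2L)
})

test_that("seed-site counts equal a naive scan on random sequences", {
  set.seed(12)
  for (i in 1:40) {
    mir <- random_rna(20)
    utr <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                 collapse = "")
    tx <- data.frame(gene_id = "g", utr5 = "", cds = "ATGTAA", utr3 = utr,
                     stringsAsFactors = FALSE)
    class(tx) <- c("transcriptome", "data.frame")
    site <- revcomp_dna(rna_to_dna(substr(mir, 2, 8)))
    expect_equal(unname(count_seed_sites(c(m = mir), tx)[1, 1]),
                 oracle_site_scan(site, utr))
  }
})

test_that("KS machinery agrees with the textbook statistic on hand data", {
  x <- c(1.1, 2.3, 0.5, 4.2, 3.3)
  y <- c(2.0, 2.1, 5.5, 0.1, 3.9)
  ks <- suppressWarnings(ks.test(x, y))
  expect_equal(unname(ks$statistic), oracle_ks_D(x, y))
})

test_that("planted per-site repression gives monotone CDF shifts", {
  set.seed(42)
  n <- 2000
  sites <- sample(0:4, n, replace = TRUE, prob = c(0.6, 0.15, 0.1, 0.1,
                                                   0.05))
  resp <- -0.2 * pmin(sites, 3) + rnorm(n, 0, 0.25)
  names(sites) <- names(resp) <- sprintf("g%04d", 1:n)
  cdf <- target_cdf_test(sites, resp)
  expect_equal(cdf$bin, c("1", "2", ">=3"))
  expect_true(all(cdf$p < 0.01))
  expect_true(all(diff(cdf$median_shift) < 0))  # more sites, more repression
  expect_lt(cdf$median_shift[1], 0)

  # identical distributions: D small, p large
  null <- target_cdf_test(sites, setNames(rnorm(n, 0, 0.25), names(sites)))
  expect_true(all(null$p > 0.001))
  expect_true(all(null$D < 0.15))
})

test_that("null CDF p-values are approximately uniform over replicates", {
  set.seed(77)
  ps <- replicate(150, {
    sites <- c(rep(0, 400), rep(1, 150))
    target_cdf_test(sites, rnorm(550),
                    bins = list("1" = c(1, 1)))$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("tsRNA mapping recovers truth for exact cuts and tolerates mismatches", {
  refs <- make_trna_references(10, seed = 8)
  reads <- simulate_tsrna_reads(refs, n_reads = 600, seed = 9)
  ann <- map_tsrna(reads$seq, refs)
  expect_true(all(ann$assigned))
  expect_true(all(ann$mismatch == 0))
  expect_equal(ann$origin, reads$origin)
  expect_equal(ann$class, reads$class)
  expect_equal(ann$aa, reads$aa)

  # single substitution in the middle: still assigned, 1-mismatch tier,
  # origin preserved
  mut <- reads$seq[1:50]
  substr(mut, 8, 8) <- ifelse(substr(mut, 8, 8) == "A", "C", "A")
  ann2 <- map_tsrna(mut, refs)
  expect_true(all(ann2$assigned))
  expect_true(all(ann2$mismatch <= 1))
  expect_gte(mean(ann2$origin == reads$origin[1:50]), 0.95)

  # garbage read ends up in the unassigned bucket
  ann3 <- map_tsrna(c(reads$seq[1], strrep("ACGT", 6)), refs)
  expect_false(ann3$assigned[2])
})

test_that("species merging conserves totals and keys on aa/anticodon", {
  refs <- make_trna_references(12, seed = 10)  # isotype table cycles
  reads <- simulate_tsrna_reads(refs, n_reads = 500, seed = 11)
  merged <- merge_species(reads[, c("aa", "anticodon", "origin", "class")])
  expect_equal(sum(merged$count), 500)
  expect_false(anyDuplicated(merged$species) > 0)
  # species ids mirror the AA + anticodon + class + origin-suffix scheme
  expect_true(all(grepl("^[A-Z][a-z]{2}[ACGT]{3}-(tRF|tRH)-(1|3|5|DA)$",
                        merged$species)))
  # two parent tRNAs with the same aa/anticodon/origin/class merge
  two <- data.frame(aa = "Glu", anticodon = "TTC",
                    origin = c("3p-mature", "3p-mature"),
                    class = "tRF", stringsAsFactors = FALSE)
  expect_equal(nrow(merge_species(two)), 1)
  expect_equal(merge_species(two)$count, 2)
})

test_that("tsRNA DE filters on robust CPM and calls planted changes", {
  sim <- simulate_experiment(list(n_genes = 50), seed = 13)
  cmx <- sim$tsrna_counts
  de <- tsrna_de(cmx$counts, cmx$samples$condition, "t0h", "control")
  truth <- sim$tsrna_truth
  down <- truth$species[truth$true_log2fc_0h == -1]
  down <- intersect(down, de$gene_id)
  expect_gt(length(down), 0)
  hit <- de[match(down, de$gene_id), ]
  expect_true(all(hit$significant))
  expect_true(all(hit$log2fc < -0.5))
  stable <- intersect(truth$species[truth$true_log2fc_0h == 0], de$gene_id)
  expect_gte(mean(!de$significant[match(stable, de$gene_id)]), 0.9)

  # a species below the CPM threshold everywhere is excluded
  low <- rbind(cmx$counts, lowspec = 1L)
  de2 <- tsrna_de(low, cmx$samples$condition, "t0h", "control")
  expect_false("lowspec" %in% de2$gene_id)
})
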