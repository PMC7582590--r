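test_that("CPM normalizes columns to one million", {
  m <- matrix(c(5, 999995, 123, 2e6 - 123), ncol = 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  cc <- cpm(m)
  expect_equal(cc["a", "s1"], 5)
  expect_equal(cc["a", "s2"], 61.5)
  expect_equal(unname(colSums(cc)), c(1e6, 1e6), tolerance = 1e-9)
  m0 <- cbind(m, s3 = c(0, 0))
  expect_error(cpm(m0), "s3")
})

test_that("low-count filter keeps exactly the genes clearing the CPM rule", {
  counts <- matrix(c(100, 10, 0,
                     100, 10, 0,
                     100,  0, 0,
                     100,  0, 0), nrow = 3,
                   dimnames = list(c("hi", "mid", "zero"), NULL))
  tot <- colSums(counts)
  # CPM of 'mid' is 1e6*10/110 in two samples, 0 in two
  kept <- filter_low(counts, cpm_threshold = 1, min_samples = 2)
  expect_identical(rownames(kept), c("hi", "mid"))
  kept2 <- filter_low(counts, cpm_threshold = 1, min_samples = 3)
  expect_identical(rownames(kept2), "hi")
  expect_identical(rownames(filter_low(counts, 0)), rownames(counts))
})

test_that("TMM factors: identity, geometric mean, and pure-scaling closed form", {
  set.seed(42)
  y <- matrix(rpois(4000, 100), ncol = 4)
  same <- cbind(y[, 1], y[, 1], y[, 1])
  expect_equal(unname(tmm_factors(same)), rep(1, 3), tolerance = 1e-9)

  f <- tmm_factors(y)
  expect_equal(geomean <- exp(mean(log(f))), 1, tolerance = 1e-9)

  two <- cbind(a = y[, 1], b = 2L * y[, 1])
  f2 <- tmm_factors(two)
  expect_equal(unname(f2), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-6)
})

test_that("TMM factors relate to edgeR's by the library-size ratio", {
  skip_if_not_installed("edgeR")
  set.seed(7)
  mu <- exp(rnorm(2000, 5, 1))
  y <- cbind(rpois(2000, mu), rpois(2000, 3 * mu), rpois(2000, 0.5 * mu),
             rpois(2000, mu))
  f_edger <- edgeR::calcNormFactors(y, method = "TMM")
  libs <- colSums(y)
  expected <- f_edger * libs / exp(mean(log(f_edger * libs)))
  expect_equal(unname(tmm_factors(y)), unname(expected), tolerance = 0.02)
})

test_that("moment dispersion recovers Poisson and NB truth", {
  base <- rep(1 / 2000, 2000)
  g <- rep(c("a", "b", "c"), each = 4)
  mk <- function(phi, seed) {
    do.call(cbind, lapply(1:3, function(k)
      simulate_counts(base, 0, 4, 1e6, phi, seed = seed + k)))
  }
  pois <- mk(0, 100)
  dp <- estimate_dispersion(pois, g)
  expect_lte(dp$phi_common, 0.01)

  nb <- mk(0.1, 200)
  dn <- estimate_dispersion(nb, g)
  expect_gte(dn$phi_common, 0.08)
  expect_lte(dn$phi_common, 0.12)

  zeros <- rbind(nb, zero = 0)
  expect_equal(unname(estimate_dispersion(zeros, g)$phi_raw[2001]), 0)
})

test_that("exact test equals the enumeration oracle and is symmetric", {
  counts <- matrix(c(10, 10, 10, 10), nrow = 1)
  r <- exact_test(counts, 1:2, 3:4, phi = 0.1, factors = rep(1, 4))
  expect_equal(r$pvalue, 1)
  expect_equal(r$log2fc, 0)

  for (phi in c(0, 0.1)) {
    for (tot in c(5L, 20L, 100L, 200L)) {
      for (sa in unique(c(0L, tot %/% 4, tot %/% 2, tot))) {
        expect_equal(
          ribopost:::nb_exact_pvalue(sa, tot - sa, 4, 4, phi),
          oracle_exact_p(sa, tot - sa, 4, 4, phi),
          tolerance = 1e-10,
          label = sprintf("phi=%g total=%d sa=%d", phi, tot, sa))
      }
    }
  }
})

test_that("exact test is calibrated and powered on planted data", {
  base <- baseline_abundance(2000, seed = 31)
  truth <- plant_modes(sprintf("g%d", 1:2000),
                       c(stable = 0.6, transcriptional = 0.4),
                       effect_size = 1, seed = 32)
  ca <- simulate_counts(base, truth$true_mrna_log2fc, 4, 1e6, 0.01,
                        seed = 33, gene_ids = truth$gene_id)
  cb <- simulate_counts(base, 0, 4, 1e6, 0.01, seed = 34,
                        gene_ids = truth$gene_id)
  counts <- cbind(ca, cb)
  disp <- estimate_dispersion(counts, rep(c("t", "c"), each = 4))
  res <- exact_test(counts, 1:4, 5:8, disp$phi)
  changed <- truth$mode == "transcriptional"
  sens <- mean(res$significant[changed])
  fdr_obs <- sum(res$significant & !changed) / max(1, sum(res$significant))
  expect_gte(sens, 0.9)
  expect_lte(fdr_obs, 0.1)
  # recovered effect sizes track the planted ones
  expect_lt(median(abs(res$log2fc[changed] -
                         truth$true_mrna_log2fc[changed])), 0.15)
})

test_that("BH adjustment leaves sorted FDRs monotone and within [0,1]", {
  base <- rep(1 / 500, 500)
  ca <- simulate_counts(base, 0, 4, 1e5, 0.1, seed = 41)
  cb <- simulate_counts(base, 0, 4, 1e5, 0.1, seed = 42)
  res <- exact_test(cbind(ca, cb), 1:4, 5:8, 0.1)
  o <- order(res$pvalue)
  expect_true(all(diff(res$fdr[o]) >= -1e-12))
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))
})

test_that("TE interaction model recovers planted buffering and ignores scale", {
  base <- baseline_abundance(400, seed = 51)
  lfc <- rep(c(1, -1, 0, 0), each = 100)  # transcriptional up/down, stable
  mode <- rep(c("tr_up", "tr_dn", "st", "st"), each = 100)
  g <- sprintf("g%03d", 1:400)
  mrna <- cbind(
    simulate_counts(base, 0, 4, 1e6, 0.01, seed = 52, gene_ids = g,
                    sample_prefix = "mc"),
    simulate_counts(base, lfc, 4, 1e6, 0.01, seed = 53, gene_ids = g,
                    sample_prefix = "mt"))
  rpf <- cbind(
    simulate_counts(base, 0, 4, 1e6, 0.01, seed = 54, gene_ids = g,
                    sample_prefix = "rc"),
    simulate_counts(base, 0, 4, 1e6, 0.01, seed = 55, gene_ids = g,
                    sample_prefix = "rt"))
  grp <- rep(c("control", "treated"), each = 4)
  te <- te_test(mrna, rpf, grp, grp, "treated", "control")
  err <- te$delta_log2_te + lfc  # expect delta log2 TE = -true mRNA lfc
  expect_lt(median(abs(err[mode == "tr_up"])), 0.15)
  expect_lt(median(abs(err[mode == "tr_dn"])), 0.15)
  # null genes: median |estimate| tracks the theoretical null scale
  # median|N(0, s)| = qnorm(0.75) * s with s^2 = 4 (phi + 1/mu) / n_reps
  mu_med <- median(rowMeans(cbind(mrna, rpf)[mode == "st", ]))
  s_theo <- sqrt(4 * (0.01 + 1 / mu_med) / 4) / log(2)
  expect_lt(median(abs(te$delta_log2_te[mode == "st"])),
            1.3 * qnorm(0.75) * s_theo)

  # doubling every count leaves the interaction unchanged (offset absorbs it)
  te2 <- te_test(2L * mrna, 2L * rpf, grp, grp, "treated", "control",
                 phi = 0.01)
  te1 <- te_test(mrna, rpf, grp, grp, "treated", "control", phi = 0.01)
  expect_equal(te2$delta_log2_te, te1$delta_log2_te, tolerance = 0.02)
})

test_that("TE fit matches an independent NB GLM on a single gene", {
  skip_if_not_installed("MASS")
  set.seed(61)
  y <- c(rpois(4, 200), rpois(4, 190), rpois(4, 210), rpois(4, 400))
  is_rpf <- rep(c(0, 0, 1, 1), each = 4)
  is_trt <- rep(c(0, 1, 0, 1), each = 4)
  off <- rep(0, 16)
  phi <- 0.05
  fit <- ribopost:::nb_irls(y, cbind(1, is_rpf, is_trt, is_rpf * is_trt),
                            off, phi)
  ref <- suppressWarnings(
    stats::glm(y ~ is_rpf * is_trt,
               family = MASS::negative.binomial(theta = 1 / phi)))
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-4)
})

test_that("TE likelihood-ratio p-values are uniform under the null", {
  base <- rep(1 / 400, 400)
  g <- sprintf("g%03d", 1:400)
  mrna <- cbind(simulate_counts(base, 0, 4, 4e5, 0.05, seed = 71,
                                gene_ids = g, sample_prefix = "mc"),
                simulate_counts(base, 0, 4, 4e5, 0.05, seed = 72,
                                gene_ids = g, sample_prefix = "mt"))
  rpf <- cbind(simulate_counts(base, 0, 4, 4e5, 0.05, seed = 73,
                               gene_ids = g, sample_prefix = "rc"),
               simulate_counts(base, 0, 4, 4e5, 0.05, seed = 74,
                               gene_ids = g, sample_prefix = "rt"))
  grp <- rep(c("control", "treated"), each = 4)
  te <- te_test(mrna, rpf, grp, grp, "treated", "control", phi = 0.05)
  ks <- suppressWarnings(ks.test(te$pvalue[te$converged], "punif"))
  expect_gt(ks$p.value, 0.01)
})
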