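#' Default configuration of the synthetic depolarization experiment
#'
#' The study design emulated throughout: three conditions (resting
#' `control`, immediately post-stimulus `t0h`, and after a 2-h rest phase
#' `t2h`), four biological replicates each; per-gene regulatory modes with
#' a transcription-heavy early mixture and a translation-heavy late one;
#' NB counts at a nominal depth of 1e6 with dispersion 0.01 (BCV 0.1, a
#' homogeneous cell line); RPF reads with a 12-nt P-site offset and 0.85
#' frame fidelity; miRNA repression of -`mirna_effect` log2 units per 3'UTR
#' seed site (capped at 3) acting on mRNA abundance at 0 h; and tsRNA reads
#' cut from synthetic tRNA references.
#'
#' @return named list of generator settings.
#' @export
default_sim_config <- function() {
  list(n_genes = 2000L, n_reps = 4L, depth = 1e6, phi = 0.01,
       effect_size = 1,
       mode_mix = list(t0h = MODE_MIX_0H, t2h = MODE_MIX_2H),
       offset = 12L, frame_fidelity = 0.85, leakage = 0.05,
       n_rpf_reads = 1e5,
       n_mirnas = 6L, mirna_site_probs = c(0.80, 0.10, 0.06, 0.04),
       mirna_effect = 0.2,
       n_trnas = 12L, n_tsrna_reads = 1e4, tsrna_depth = 1e6,
       tsrna_down_frac = 0.3, tsrna_up_frac = 0.05)
}

random_mirnas <- function(n, seed) {
  with_seed(seed, {
    setNames(vapply(seq_len(n), function(i)
      dna_to_rna(random_seq(22L, 0.5)), character(1)),
      sprintf("mir%02d", seq_len(n)))
  })
}

#' Simulate the full matched Ribo-seq / mRNA-seq / small-RNA experiment
#'
#' Runs the generator end to end with fully recorded ground truth:
#' transcriptome, planted regulatory modes per time point, miRNA seed sites
#' (with per-site mRNA repression at 0 h), NB count matrices for the mRNA
#' and RPF assays across control/t0h/t2h, RPF and mRNA aligned reads for
#' the QC module, and tRNA references with tsRNA reads and species-level
#' small-RNA counts.
#'
#' @param config list as from [default_sim_config()] (entries override the
#'   defaults).
#' @param seed master integer seed; all component seeds derive from it.
#' @return list with elements `transcripts`, `truth` (per gene x time
#'   point, all planted quantities), `site_counts`, `mirnas`, `mrna`
#'   (count_matrix), `rpf` (count_matrix), `rpf_reads`, `mrna_reads`,
#'   `trna_refs`, `tsrna_reads`, `tsrna_truth`, `tsrna_counts`, `config`.
#' @export
simulate_experiment <- function(config = list(), seed = 1L) {
  cfg <- utils::modifyList(default_sim_config(), config)
  sd <- function(k) as.integer((as.double(seed) * 113 + k) %% 2147480000)

  tx <- make_transcriptome(cfg$n_genes, seed = sd(1))
  mirnas <- random_mirnas(cfg$n_mirnas, sd(2))
  planted <- plant_mirna_targets(tx, mirnas, cfg$mirna_site_probs, sd(3))
  tx <- planted$transcripts
  pooled_sites <- colSums(planted$site_counts)

  modes0 <- plant_modes(tx, cfg$mode_mix$t0h, cfg$effect_size, sd(4))
  modes2 <- plant_modes(tx, cfg$mode_mix$t2h, cfg$effect_size, sd(5))
  mirna_l2fc <- -cfg$mirna_effect * pmin(pooled_sites, 3)

  truth <- data.frame(
    gene_id = tx$gene_id,
    mode_0h = modes0$mode, mode_2h = modes2$mode,
    mode_mrna_log2fc_0h = modes0$true_mrna_log2fc,
    mode_rpf_log2fc_0h = modes0$true_rpf_log2fc,
    mode_mrna_log2fc_2h = modes2$true_mrna_log2fc,
    mode_rpf_log2fc_2h = modes2$true_rpf_log2fc,
    mirna_sites = pooled_sites,
    mirna_log2fc_0h = mirna_l2fc,
    stringsAsFactors = FALSE)
  truth$true_mrna_log2fc_0h <- truth$mode_mrna_log2fc_0h + mirna_l2fc
  truth$true_rpf_log2fc_0h <- truth$mode_rpf_log2fc_0h
  truth$true_mrna_log2fc_2h <- truth$mode_mrna_log2fc_2h
  truth$true_rpf_log2fc_2h <- truth$mode_rpf_log2fc_2h

  base <- baseline_abundance(cfg$n_genes, seed = sd(6))
  mk <- function(assay, lfc_by_cond, k0) {
    mats <- lapply(seq_along(lfc_by_cond), function(i)
      simulate_counts(base, lfc_by_cond[[i]], cfg$n_reps, cfg$depth,
                      cfg$phi, seed = sd(k0 + i), gene_ids = tx$gene_id,
                      sample_prefix = paste0(assay, "_",
                                             names(lfc_by_cond)[i], "_")))
    counts <- do.call(cbind, mats)
    count_matrix(counts, assay,
                 rep(names(lfc_by_cond), each = cfg$n_reps),
                 rep(seq_len(cfg$n_reps), length(lfc_by_cond)))
  }
  mrna <- mk("mRNA", list(control = 0,
                          t0h = truth$true_mrna_log2fc_0h,
                          t2h = truth$true_mrna_log2fc_2h), 10L)
  rpf <- mk("RPF", list(control = 0,
                        t0h = truth$true_rpf_log2fc_0h,
                        t2h = truth$true_rpf_log2fc_2h), 20L)

  rpf_reads <- simulate_rpf_reads(tx, base, cfg$offset, cfg$frame_fidelity,
                                  n_reads = cfg$n_rpf_reads,
                                  leakage = cfg$leakage, seed = sd(30))
  mrna_reads <- simulate_mrna_reads(tx, base, n_reads = cfg$n_rpf_reads,
                                    seed = sd(31))

  trna_refs <- make_trna_references(cfg$n_trnas, seed = sd(40))
  tsrna_reads <- simulate_tsrna_reads(trna_refs, n_reads = cfg$n_tsrna_reads,
                                      seed = sd(41))
  species <- merge_species(tsrna_reads[, c("aa", "anticodon", "origin",
                                           "class")])
  ns <- nrow(species)
  tsrna_lfc <- with_seed(sd(42), {
    l <- numeric(ns)
    state <- runif(ns)
    l[state < cfg$tsrna_down_frac] <- -1
    l[state > 1 - cfg$tsrna_up_frac] <- 1
    l
  })
  ts_base <- species$count / sum(species$count)
  ts_counts <- cbind(
    simulate_counts(ts_base, 0, cfg$n_reps, cfg$tsrna_depth, cfg$phi,
                    seed = sd(43), gene_ids = species$species,
                    sample_prefix = "smallRNA_control_"),
    simulate_counts(ts_base, tsrna_lfc, cfg$n_reps, cfg$tsrna_depth,
                    cfg$phi, seed = sd(44), gene_ids = species$species,
                    sample_prefix = "smallRNA_t0h_"))
  tsrna_counts <- count_matrix(ts_counts, "smallRNA",
                               rep(c("control", "t0h"), each = cfg$n_reps),
                               rep(seq_len(cfg$n_reps), 2))
  tsrna_truth <- cbind(species[, c("species", "aa", "anticodon", "origin",
                                   "class")],
                       baseline = ts_base, true_log2fc_0h = tsrna_lfc)

  list(transcripts = tx, truth = truth,
       site_counts = planted$site_counts, mirnas = mirnas,
       mrna = mrna, rpf = rpf,
       rpf_reads = rpf_reads, mrna_reads = mrna_reads,
       trna_refs = trna_refs, tsrna_reads = tsrna_reads,
       tsrna_truth = tsrna_truth, tsrna_counts = tsrna_counts,
       config = cfg, seed = seed)
}
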