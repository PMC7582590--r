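#' Regulatory modes distinguished by the classifier and simulator
#' @export
REGULATORY_MODES <- c("homodirectional", "opposite", "transcriptional",
                      "translational", "stable")

#' Default regulatory-mode mixtures for the two post-stimulus time points
#'
#' The early (0 h) mixture is transcription-heavy (pervasive
#' post-transcriptional buffering: many genes change at the mRNA level only),
#' the late (2 h) mixture is translation-heavy, reproducing the qualitative
#' asymmetry between the two time points without copying dataset-dependent
#' counts.
#' @name mode_mixtures
#' @export
MODE_MIX_0H <- c(homodirectional = 0.04, opposite = 0.02,
                 transcriptional = 0.35, translational = 0.17, stable = 0.42)

#' @rdname mode_mixtures
#' @export
MODE_MIX_2H <- c(homodirectional = 0.04, opposite = 0.02,
                 transcriptional = 0.17, translational = 0.35, stable = 0.42)

# The fixed mode -> (mRNA, RPF) effect map: s is a +/-1 sign drawn 50/50,
# e the effect size in log2 units.
mode_effects <- function(mode, s, e) {
  switch(mode,
         homodirectional = c(s * e, s * e),
         opposite        = c(s * e, -s * e),
         transcriptional = c(s * e, 0),
         translational   = c(0, s * e),
         stable          = c(0, 0),
         stopf("unknown mode '%s'", mode))
}

#' Plant per-gene regulatory modes and true fold changes
#'
#' Assigns each gene one of five regulatory modes and the implied true
#' (mRNA, RPF) log2 fold changes: homodirectional -> (+-e, +-e) same sign;
#' opposite -> (+-e, -+e); transcriptional -> (+-e, 0); translational ->
#' (0, +-e); stable -> (0, 0). Signs are drawn 50/50.
#'
#' @param gene_ids character vector of gene identifiers (or a
#'   `transcriptome`, whose `gene_id` column is used).
#' @param proportions named numeric over [REGULATORY_MODES], summing to 1
#'   within 1e-9; missing modes count as 0.
#' @param effect_size positive effect magnitude e in log2 units.
#' @param seed integer RNG seed.
#' @return data.frame: `gene_id`, `mode`, `true_mrna_log2fc`,
#'   `true_rpf_log2fc`.
#' @export
plant_modes <- function(gene_ids, proportions = MODE_MIX_0H,
                        effect_size = 1, seed = 1L) {
  if (is.data.frame(gene_ids)) gene_ids <- gene_ids$gene_id
  p <- setNames(numeric(length(REGULATORY_MODES)), REGULATORY_MODES)
  if (is.null(names(proportions)))
    stopf("proportions must be a named vector over the mode labels")
  bad <- setdiff(names(proportions), REGULATORY_MODES)
  if (length(bad)) stopf("unknown mode(s): %s", paste(bad, collapse = ", "))
  p[names(proportions)] <- proportions
  if (any(p < 0)) stopf("mode proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stopf("mode proportions must sum to 1")
  if (effect_size <= 0) stopf("effect_size must be > 0")

  with_seed(seed, {
    n <- length(gene_ids)
    modes <- sample(REGULATORY_MODES, n, replace = TRUE, prob = p)
    signs <- sample(c(-1, 1), n, replace = TRUE)
    eff <- t(vapply(seq_len(n),
                    function(i) mode_effects(modes[i], signs[i], effect_size),
                    numeric(2)))
    data.frame(gene_id = gene_ids, mode = modes,
               true_mrna_log2fc = eff[, 1], true_rpf_log2fc = eff[, 2],
               stringsAsFactors = FALSE)
  })
}

#' Draw per-gene baseline relative abundances
#'
#' Log-normal relative abundances (heavy-tailed, as in real expression
#' profiles), normalized to sum to 1.
#'
#' @param n_genes number of genes.
#' @param sdlog log-scale standard deviation.
#' @param seed integer RNG seed.
#' @return numeric vector summing to 1.
#' @export
baseline_abundance <- function(n_genes, sdlog = 1, seed = 1L) {
  with_seed(seed, {
    x <- exp(rnorm(n_genes, 0, sdlog))
    x / sum(x)
  })
}
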