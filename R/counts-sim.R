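#' Simulate a negative-binomial count matrix
#'
#' Counts are drawn NB(mean = baseline * 2^log2fc * depth, dispersion phi),
#' parameterized so that Var = mu + phi * mu^2. `phi = 0` degenerates to
#' Poisson. Library sizes are not renormalized after applying fold changes,
#' so large asymmetric effects induce the composition bias that TMM
#' normalization is designed to remove.
#'
#' @param baseline per-gene relative abundance (positive; typically sums
#'   to 1).
#' @param log2fc per-gene true log2 fold change (0 for a reference
#'   condition).
#' @param n_reps number of replicate libraries.
#' @param depth nominal library depth (scalar or per-replicate).
#' @param phi NB dispersion, scalar or per-gene; >= 0.
#' @param seed integer RNG seed.
#' @param gene_ids optional rownames.
#' @param sample_prefix prefix for column names.
#' @return integer matrix genes x replicates.
#' @export
simulate_counts <- function(baseline, log2fc = 0, n_reps = 4L, depth = 1e6,
                            phi = 0.01, seed = 1L, gene_ids = NULL,
                            sample_prefix = "s") {
  if (any(depth <= 0)) stopf("depth must be > 0")
  if (any(phi < 0)) stopf("dispersion phi must be >= 0")
  n <- length(baseline)
  log2fc <- rep_len(log2fc, n)
  phi <- rep_len(phi, n)
  depth <- rep_len(depth, n_reps)
  mu <- baseline * 2^log2fc
  with_seed(seed, {
    m <- vapply(seq_len(n_reps), function(j) {
      mj <- mu * depth[j]
      y <- numeric(n)
      pois <- phi == 0
      if (any(pois)) y[pois] <- rpois(sum(pois), mj[pois])
      if (any(!pois)) y[!pois] <- rnbinom(sum(!pois), mu = mj[!pois],
                                          size = 1 / phi[!pois])
      y
    }, numeric(n))
    storage.mode(m) <- "integer"
    rownames(m) <- gene_ids
    colnames(m) <- paste0(sample_prefix, seq_len(n_reps))
    m
  })
}

#' Assemble a tagged count matrix with sample metadata
#'
#' Lightweight container pairing an integer genes x samples matrix with its
#' sample annotation (assay, condition, replicate), the substrate for the
#' differential-expression and translational-efficiency functions.
#'
#' @param counts integer matrix, genes in rows.
#' @param assay assay label per sample (`mRNA`, `RPF` or `smallRNA`).
#' @param condition condition label per sample.
#' @param replicate replicate index per sample.
#' @return object of class `count_matrix`: list(counts, samples).
#' @export
count_matrix <- function(counts, assay, condition, replicate) {
  if (any(is.na(counts))) stopf("count matrix must not contain missing cells")
  if (any(counts < 0)) stopf("counts must be non-negative")
  samples <- data.frame(sample = colnames(counts),
                        assay = rep_len(assay, ncol(counts)),
                        condition = rep_len(condition, ncol(counts)),
                        replicate = rep_len(replicate, ncol(counts)),
                        stringsAsFactors = FALSE)
  if (anyDuplicated(samples$sample)) stopf("sample names must be unique")
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$assay), collapse = ", ")))
  invisible(x)
}
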