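#' Default rare-codon set
#'
#' The bottom decile (6 of 61 sense codons) of a bundled human codon-usage
#' table (frequencies per 1000 codons); fully user-replaceable wherever a
#' rare-codon set is accepted.
#'
#' @param usage_file TSV with columns `codon`, `freq_per_1000`.
#' @param quantile_cut usage quantile below which a codon counts as rare.
#' @return character vector of rare codons (DNA alphabet).
#' @export
rare_codons <- function(usage_file = system.file("extdata",
                                                 "codon_usage_human.tsv",
                                                 package = "ribopost"),
                        quantile_cut = 0.1) {
  tab <- read.delim(usage_file, stringsAsFactors = FALSE)
  n_rare <- floor(nrow(tab) * quantile_cut)
  sort(tab$codon[order(tab$freq_per_1000)][seq_len(n_rare)])
}

#' Minimum free energy of a pseudoknot-free secondary structure
#'
#' Nussinov-style dynamic program minimizing the sum of base-pair energies
#' (defaults GC -3, AU -2, GU -1; hairpin loops enclose at least
#' `min_loop` unpaired bases; no pseudoknots). Deterministic; intended as
#' an oracle-testable structure score, not a thermodynamic model.
#'
#' @param sequence single nucleotide string (A/C/G/T/U, case-insensitive).
#' @param energies named numeric: `GC`, `AU`, `GU` pair energies (<= 0).
#' @param min_loop minimum unpaired bases in a hairpin loop.
#' @return list: `mfe` (<= 0) and `nmfe` = mfe / length.
#' @export
fold_energy <- function(sequence, energies = c(GC = -3, AU = -2, GU = -1),
                        min_loop = 3L) {
  if (nchar(sequence) < 1) stopf("sequence must have length >= 1")
  s <- toupper(rna_to_dna(sequence))
  codes <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  if (anyNA(codes))
    stopf("non-ACGT(U) symbol at position %d", which(is.na(codes))[1])
  mfe <- .nussinov_mfe(codes - 1L, energies[["GC"]], energies[["AU"]],
                       energies[["GU"]], as.integer(min_loop))
  list(mfe = mfe, nmfe = mfe / nchar(sequence))
}

#' Count G-quadruplex-prone regions by run scoring
#'
#' G4Hunter-style deterministic score: bases inside a run of k consecutive
#' G score +min(k, 4), bases in C runs score -min(k, 4), others 0. Sliding
#' windows (step 1) whose mean score is >= `threshold` are G4-positive;
#' overlapping positive windows merge into a single counted region.
#' Sequences shorter than the window are scored as one full-length window.
#'
#' @param sequence nucleotide string.
#' @param window window width in nt (>= 10).
#' @param threshold mean-score threshold for a positive window.
#' @return integer count of merged G4-positive regions.
#' @export
g4_count <- function(sequence, window = 25L, threshold = 1.2) {
  if (window < 10) stopf("window must be >= 10")
  n <- nchar(sequence)
  if (n == 0L) return(0L)
  b <- strsplit(toupper(rna_to_dna(sequence)), "", fixed = TRUE)[[1]]
  r <- rle(b)
  val <- ifelse(r$values == "G", pmin(r$lengths, 4),
                ifelse(r$values == "C", -pmin(r$lengths, 4), 0))
  score <- rep(val, r$lengths)
  if (n < window) return(if (mean(score) >= threshold) 1L else 0L)
  cs <- c(0, cumsum(score))
  means <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  pos <- which(means >= threshold)
  if (!length(pos)) return(0L)
  # merge overlapping windows [p, p + window - 1]
  sum(diff(pos) >= window) + 1L
}

#' Per-gene, per-region sequence feature table
#'
#' Computes, for each transcript region (5'UTR, CDS, 3'UTR): length, GC
#' fraction, G4 region count and (optionally, it is the expensive step)
#' length-normalized minimum free energy; plus the per-gene upstream-AUG
#' count (overlapping ATG occurrences in the 5'UTR) and rare-codon
#' frequency (fraction of CDS codons in `rare_set`). Absent regions yield
#' `NA`, not 0.
#'
#' @param transcripts a `transcriptome` data.frame.
#' @param rare_set character vector of rare codons.
#' @param compute_mfe logical; compute the folding DP (O(n^3) per region)?
#' @param mfe_values optional externally computed MFE hook: named list of
#'   per-region numeric vectors (`utr5`, `cds`, `utr3`) used instead of the
#'   internal DP.
#' @return data.frame of class `feature_table`, one row per gene.
#' @export
compute_features <- function(transcripts, rare_set = rare_codons(),
                             compute_mfe = FALSE, mfe_values = NULL) {
  regions <- c("utr5", "cds", "utr3")
  n <- nrow(transcripts)
  out <- data.frame(gene_id = transcripts$gene_id, stringsAsFactors = FALSE)
  for (r in regions) {
    seqs <- transcripts[[r]]
    len <- nchar(seqs)
    absent <- len == 0L
    out[[paste0(r, "_length")]] <- ifelse(absent, NA_integer_, len)
    out[[paste0(r, "_gc")]] <-
      vapply(seq_len(n), function(i)
        if (absent[i]) NA_real_ else gc_fraction(seqs[i]), numeric(1))
    out[[paste0(r, "_g4")]] <-
      vapply(seq_len(n), function(i)
        if (absent[i]) NA_integer_ else g4_count(seqs[i]), integer(1))
    nmfe <- rep(NA_real_, n)
    if (!is.null(mfe_values) && !is.null(mfe_values[[r]])) {
      nmfe <- ifelse(absent, NA_real_, mfe_values[[r]] / pmax(len, 1L))
    } else if (compute_mfe) {
      for (i in seq_len(n))
        if (!absent[i]) nmfe[i] <- fold_energy(seqs[i])$nmfe
    }
    out[[paste0(r, "_nmfe")]] <- nmfe
  }
  out$uaug_count <- vapply(seq_len(n), function(i) {
    if (nchar(transcripts$utr5[i]) == 0L) NA_integer_
    else count_overlapping("ATG", toupper(transcripts$utr5[i]))
  }, integer(1))
  out$rcf <- vapply(seq_len(n), function(i) {
    cds <- toupper(transcripts$cds[i])
    if (nchar(cds) == 0L) return(NA_real_)
    codons <- substring(cds, seq(1, nchar(cds) - 2, by = 3),
                        seq(3, nchar(cds), by = 3))
    mean(codons %in% rare_set)
  }, numeric(1))
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Quartile stratification with a Kruskal-Wallis test
#'
#' Genes are binned into quartiles of a sequence feature (edges at the
#' 25/50/75 empirical percentiles, ties assigned to the lower bin) and the
#' fold-change response distributions across bins are compared by
#' Kruskal-Wallis (rank H with tie correction, chi-squared with 3 df).
#'
#' @param feature numeric feature values per gene.
#' @param response numeric response (e.g. a log2FC) per gene, same order.
#' @param n_bins number of quantile bins (default quartiles).
#' @param min_genes minimum non-NA genes required.
#' @return list of class `stratified_comparison`: `H`, `p`, `bins`
#'   (assignment per gene, NA where input was NA), `medians` (per bin),
#'   `n`.
#' @export
stratify_and_test <- function(feature, response, n_bins = 4L,
                              min_genes = 40L) {
  ok <- !is.na(feature) & !is.na(response)
  if (sum(ok) < min_genes)
    stopf("need at least %d genes with non-missing feature and response",
          min_genes)
  x <- feature[ok]; y <- response[ok]
  if (length(unique(x)) < n_bins)
    stopf("feature is (nearly) constant; quantile bins are undefined")
  edges <- quantile(x, probs = seq_len(n_bins - 1) / n_bins, names = FALSE)
  bin <- 1L + vapply(x, function(v) sum(v > edges), integer(1))
  if (length(unique(bin)) < 2)
    stopf("feature is too discrete to form distinct quantile bins")
  kw <- kruskal.test(y, factor(bin, levels = seq_len(n_bins)))
  bins_full <- rep(NA_integer_, length(feature))
  bins_full[ok] <- bin
  structure(list(H = unname(kw$statistic), p = kw$p.value,
                 bins = bins_full,
                 medians = tapply(y, factor(bin, levels = seq_len(n_bins)),
                                  median),
                 n = length(y)),
            class = "stratified_comparison")
}

#' Stratify a feature-table column against a DE/TE response
#'
#' Convenience wrapper around [stratify_and_test()] addressing features by
#' region and name, mirroring how the comparisons are usually requested
#' (e.g. 3'UTR GC vs mRNA log2FC).
#'
#' @param features a `feature_table`.
#' @param responses data.frame with `gene_id` and the response column.
#' @param feature feature name: one of `length`, `gc`, `nmfe`, `g4`,
#'   `uaug`, `rcf`.
#' @param region `utr5`, `cds` or `utr3` (ignored for `uaug`/`rcf`).
#' @param response name of the response column in `responses`.
#' @param ... passed to [stratify_and_test()].
#' @return a `stratified_comparison`.
#' @export
stratify_feature <- function(features, responses, feature, region = "cds",
                             response = "log2fc", ...) {
  col <- switch(feature,
                uaug = "uaug_count", rcf = "rcf",
                paste0(region, "_", feature))
  if (is.null(features[[col]])) stopf("unknown feature column '%s'", col)
  idx <- match(features$gene_id, responses$gene_id)
  stratify_and_test(features[[col]], responses[[response]][idx], ...)
}
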