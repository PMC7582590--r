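#' Generate a synthetic transcriptome
#'
#' Emits single-isoform transcript models in transcript space. Each model is
#' a 5'UTR + CDS + 3'UTR concatenation (0-based, half-open coordinates). The
#' CDS always starts with ATG, ends with a stop codon, and contains no
#' internal in-frame stop. Bases are drawn i.i.d. with per-region GC targets,
#' so realized GC concentrates around the target for long regions.
#'
#' @param n_genes number of transcripts to generate (>= 1).
#' @param lengths list with elements `utr5`, `utr3` (integer ranges, nt) and
#'   `cds_codons` (integer range, codons including start and stop). A length
#'   range `c(lo, hi)` is sampled uniformly per gene.
#' @param gc named numeric vector of per-region GC targets in (0.2, 0.8),
#'   names `utr5`, `cds`, `utr3`.
#' @param seed integer RNG seed; output is a pure function of the arguments.
#' @return data.frame with columns `gene_id`, `utr5`, `cds`, `utr3` of class
#'   `transcriptome`.
#' @export
make_transcriptome <- function(n_genes,
                               lengths = list(utr5 = c(100L, 300L),
                                              cds_codons = c(100L, 220L),
                                              utr3 = c(150L, 450L)),
                               gc = c(utr5 = 0.60, cds = 0.52, utr3 = 0.44),
                               seed = 1L) {
  if (n_genes < 1) stopf("n_genes must be >= 1")
  for (r in c("utr5", "cds", "utr3")) {
    if (is.na(gc[r]) || gc[r] <= 0.2 || gc[r] >= 0.8)
      stopf("GC target for %s must lie in (0.2, 0.8)", r)
  }
  for (nm in names(lengths)) {
    if (any(lengths[[nm]] < 0) || max(lengths[[nm]]) == 0)
      stopf("length range for %s must be positive", nm)
  }
  if (min(lengths$cds_codons) < 2)
    stopf("cds_codons must allow at least a start and a stop codon")

  with_seed(seed, {
    utr5 <- random_region(n_genes, lengths$utr5, gc[["utr5"]])
    utr3 <- random_region(n_genes, lengths$utr3, gc[["utr3"]])
    cds <- random_cds(n_genes, lengths$cds_codons, gc[["cds"]])
    out <- data.frame(gene_id = sprintf("gene%04d", seq_len(n_genes)),
                      utr5 = utr5, cds = cds, utr3 = utr3,
                      stringsAsFactors = FALSE)
    class(out) <- c("transcriptome", "data.frame")
    out
  })
}

random_seq <- function(len, gc) {
  if (len == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, len, replace = TRUE, prob = p), collapse = "")
}

random_region <- function(n, range, gc) {
  lens <- sample(seq.int(range[1], range[2]), n, replace = TRUE)
  vapply(lens, random_seq, character(1), gc = gc)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_cds <- function(n, codon_range, gc) {
  vapply(seq_len(n), function(i) {
    n_codons <- sample(seq.int(codon_range[1], codon_range[2]), 1L)
    n_internal <- n_codons - 2L
    internal <- character(n_internal)
    k <- 0L
    while (k < n_internal) {
      cand <- random_seq(3L, gc)
      if (!cand %in% STOP_CODONS) {
        k <- k + 1L
        internal[k] <- cand
      }
    }
    paste0("ATG", paste(internal, collapse = ""), sample(STOP_CODONS, 1L))
  }, character(1))
}

#' Region coordinates of transcript models
#'
#' @param transcripts a `transcriptome` data.frame.
#' @return data.frame with `gene_id`, `cds_start`, `cds_end`, `tx_length`
#'   and per-region lengths; coordinates 0-based half-open on the
#'   utr5+cds+utr3 concatenation.
#' @export
transcript_regions <- function(transcripts) {
  l5 <- nchar(transcripts$utr5)
  lc <- nchar(transcripts$cds)
  l3 <- nchar(transcripts$utr3)
  data.frame(gene_id = transcripts$gene_id,
             utr5_length = l5, cds_length = lc, utr3_length = l3,
             cds_start = l5, cds_end = l5 + lc, tx_length = l5 + lc + l3,
             stringsAsFactors = FALSE)
}

#' Full transcript sequences
#' @param transcripts a `transcriptome` data.frame.
#' @return named character vector of utr5+cds+utr3 concatenations.
#' @export
transcript_sequences <- function(transcripts) {
  setNames(paste0(transcripts$utr5, transcripts$cds, transcripts$utr3),
           transcripts$gene_id)
}

#' Plant miRNA/tRF seed-match sites into 3'UTRs
#'
#' For each gene a number of target sites is drawn from `site_count_probs`;
#' each site is the DNA reverse complement of the small RNA's seed
#' (nucleotides 2-8), spliced into the 3'UTR at a random position. Recorded
#' site counts are *recounted* after insertion, so pre-existing chance
#' matches are included.
#'
#' @param transcripts a `transcriptome` data.frame.
#' @param mirnas named character vector of small RNA sequences (RNA or DNA
#'   alphabet, length >= 8).
#' @param site_count_probs probabilities for 0, 1, 2, ... planted sites per
#'   gene (normalized internally).
#' @param seed integer RNG seed.
#' @return list with `transcripts` (3'UTRs updated), `site_counts` (matrix
#'   smallRNA x gene of recounted seed matches), `planted` (data.frame of
#'   insertions: gene_id, mirna, position) and `planted_per_gene` (total
#'   insertions per gene).
#' @export
plant_mirna_targets <- function(transcripts, mirnas,
                                site_count_probs = c(0.80, 0.10, 0.06, 0.04),
                                seed = 1L) {
  if (any(nchar(mirnas) < 8)) stopf("all small RNA sequences must be >= 8 nt")
  if (is.null(names(mirnas)))
    names(mirnas) <- sprintf("mir%02d", seq_along(mirnas))
  sites <- vapply(mirnas, function(m) seed_match_site(m), character(1))
  probs <- site_count_probs / sum(site_count_probs)

  with_seed(seed, {
    n <- nrow(transcripts)
    n_sites <- sample(seq_along(probs) - 1L, n, replace = TRUE, prob = probs)
    planted <- list()
    utr3 <- transcripts$utr3
    for (i in seq_len(n)) {
      k <- n_sites[i]
      if (k == 0L) next
      if (nchar(utr3[i]) < 7L * k) {
        warnf("gene %s: 3'UTR too short to host %d sites; skipped",
              transcripts$gene_id[i], k)
        n_sites[i] <- 0L
        next
      }
      for (j in seq_len(k)) {
        mi <- sample(seq_along(mirnas), 1L)
        pos <- sample.int(nchar(utr3[i]) + 1L, 1L) - 1L  # 0-based insert point
        utr3[i] <- paste0(substr(utr3[i], 1L, pos), sites[mi],
                          substr(utr3[i], pos + 1L, nchar(utr3[i])))
        planted[[length(planted) + 1L]] <-
          data.frame(gene_id = transcripts$gene_id[i],
                     mirna = names(mirnas)[mi], position = pos,
                     stringsAsFactors = FALSE)
      }
    }
    out <- transcripts
    out$utr3 <- utr3
    counts <- count_seed_sites(mirnas, out)
    list(transcripts = out,
         site_counts = counts,
         planted = if (length(planted)) do.call(rbind, planted) else
           data.frame(gene_id = character(), mirna = character(),
                      position = integer()),
         planted_per_gene = setNames(n_sites, transcripts$gene_id))
  })
}
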