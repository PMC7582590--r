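#' Simulate ribosome-protected fragment (RPF) reads
#'
#' Each read is placed so that its P-site (5' end + `offset`) falls inside
#' the CDS with probability `1 - leakage` (the remainder split evenly
#' between the UTRs). In-CDS P-sites sit on a uniformly chosen codon --
#' except codon 0, which carries an initiation-peak weight (`init_boost`),
#' as seen in real metagene profiles -- and occupy frame 0 with probability
#' `frame_fidelity`, otherwise frames 1 or 2 equally. Read counts per gene
#' are proportional to `expression`.
#'
#' @param transcripts a `transcriptome` data.frame.
#' @param expression per-gene expression weights (recycled; need not sum
#'   to 1).
#' @param offset P-site offset o in nt (>= 0): P-site = pos5 + o.
#' @param frame_fidelity probability f in \[0, 1\] that an in-CDS P-site is
#'   in frame 0.
#' @param read_lengths integer vector of candidate read lengths.
#' @param read_length_probs sampling weights for `read_lengths`.
#' @param n_reads total number of reads.
#' @param leakage probability a P-site falls outside the CDS.
#' @param init_boost relative sampling weight of codon 0.
#' @param seed integer RNG seed.
#' @return data.frame of aligned reads: `gene_id`, `pos5` (0-based
#'   transcript coordinate of the read 5' end), `length`.
#' @export
simulate_rpf_reads <- function(transcripts, expression = 1, offset = 12L,
                               frame_fidelity = 0.85,
                               read_lengths = 26:32,
                               read_length_probs = c(1, 2, 4, 6, 4, 2, 1),
                               n_reads = 1e5, leakage = 0.05,
                               init_boost = 5, seed = 1L) {
  if (frame_fidelity < 0 || frame_fidelity > 1)
    stopf("frame_fidelity must lie in [0, 1]")
  if (offset < 0) stopf("offset must be >= 0")
  if (offset >= min(read_lengths))
    stopf("offset (%d) must be smaller than the minimum read length (%d)",
          offset, min(read_lengths))
  if (leakage < 0 || leakage > 1) stopf("leakage must lie in [0, 1]")

  reg <- transcript_regions(transcripts)
  n_genes <- nrow(reg)
  expression <- rep_len(expression, n_genes)

  with_seed(seed, {
    per_gene <- as.vector(rmultinom(1, n_reads, expression / sum(expression)))
    out <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      k <- per_gene[g]
      if (k == 0L) next
      lens <- sample(read_lengths, k, replace = TRUE,
                     prob = read_length_probs)
      in_cds <- runif(k) >= leakage
      psite <- integer(k)

      n_codons <- reg$cds_length[g] %/% 3L
      cw <- c(init_boost, rep(1, n_codons - 1L))
      nc <- sum(in_cds)
      if (nc > 0L) {
        codon <- sample.int(n_codons, nc, replace = TRUE, prob = cw) - 1L
        fr <- ifelse(runif(nc) < frame_fidelity, 0L,
                     sample(1:2, nc, replace = TRUE))
        psite[in_cds] <- reg$cds_start[g] + 3L * codon + fr
      }
      nu <- sum(!in_cds)
      if (nu > 0L) {
        to5 <- runif(nu) < 0.5
        p <- integer(nu)
        # 5'UTR P-sites: keep pos5 >= 0
        lo5 <- min(offset, reg$cds_start[g])
        if (reg$cds_start[g] > lo5) {
          p[to5] <- lo5 + sample.int(reg$cds_start[g] - lo5, sum(to5),
                                     replace = TRUE) - 1L
        } else to5[] <- FALSE
        # 3'UTR P-sites: keep the read inside the transcript
        hi3 <- reg$tx_length[g] - (max(read_lengths) - offset)
        if (hi3 > reg$cds_end[g]) {
          p[!to5] <- reg$cds_end[g] +
            sample.int(hi3 - reg$cds_end[g], sum(!to5), replace = TRUE) - 1L
        } else p[!to5] <- reg$cds_end[g] - 1L  # degenerate; stay in bounds
        psite[!in_cds] <- p
      }
      pos5 <- psite - offset
      # guard transcript bounds (construction keeps these no-ops for
      # default geometries)
      pos5 <- pmax(pos5, 0L)
      pos5 <- pmin(pos5, reg$tx_length[g] - lens)
      out[[g]] <- data.frame(gene_id = reg$gene_id[g], pos5 = pos5,
                             length = lens, stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    rownames(res) <- NULL
    res
  })
}

#' Simulate mRNA-seq reads (random fragmentation)
#'
#' mRNA fragments have no P-site; 5' ends are uniform over the transcript,
#' giving flat metagene profiles and even frame usage.
#'
#' @inheritParams simulate_rpf_reads
#' @return data.frame of aligned reads: `gene_id`, `pos5`, `length`.
#' @export
simulate_mrna_reads <- function(transcripts, expression = 1,
                                read_lengths = 26:32, n_reads = 1e5,
                                seed = 1L) {
  reg <- transcript_regions(transcripts)
  n_genes <- nrow(reg)
  expression <- rep_len(expression, n_genes)
  with_seed(seed, {
    per_gene <- as.vector(rmultinom(1, n_reads, expression / sum(expression)))
    out <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      k <- per_gene[g]
      if (k == 0L) next
      lens <- sample(read_lengths, k, replace = TRUE)
      pos5 <- vapply(lens, function(l)
        sample.int(reg$tx_length[g] - l + 1L, 1L) - 1L, integer(1))
      out[[g]] <- data.frame(gene_id = reg$gene_id[g], pos5 = pos5,
                             length = lens, stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    rownames(res) <- NULL
    res
  })
}
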