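valid_reads <- function(reads, reg) {
  if (is.null(reads) || nrow(reads) == 0L) stopf("no reads supplied")
  idx <- match(reads$gene_id, reg$gene_id)
  if (anyNA(idx))
    stopf("read(s) reference unknown gene(s), e.g. '%s'",
          reads$gene_id[which(is.na(idx))[1]])
  bad <- which(reads$pos5 < 0 | reads$pos5 + reads$length > reg$tx_length[idx])
  if (length(bad))
    stopf("read %d lies outside its transcript bounds", bad[1])
  idx
}

#' Fraction of reads mapping to each transcript region
#'
#' Each read is assigned to the region (5'UTR, CDS or 3'UTR) containing its
#' anchor point: the P-site (5' end + `offset`) for RPF libraries, the raw
#' 5' end (`offset = 0`) for mRNA libraries, which have no biological
#' P-site.
#'
#' @param reads data.frame with `gene_id`, `pos5`, `length`.
#' @param transcripts a `transcriptome` data.frame.
#' @param offset anchor offset in nt (P-site offset for RPFs, 0 for mRNA).
#' @return named numeric fractions over `utr5`, `cds`, `utr3` (summing
#'   to 1), with read counts in attribute `counts`.
#' @export
feature_mapping_rates <- function(reads, transcripts, offset = 0L) {
  reg <- transcript_regions(transcripts)
  idx <- valid_reads(reads, reg)
  anchor <- reads$pos5 + offset
  region <- ifelse(anchor < reg$cds_start[idx], "utr5",
                   ifelse(anchor < reg$cds_end[idx], "cds", "utr3"))
  counts <- c(utr5 = sum(region == "utr5"), cds = sum(region == "cds"),
              utr3 = sum(region == "utr3"))
  structure(counts / sum(counts), counts = counts)
}

#' Metagene density profile around the start or stop codon
#'
#' Per transcript, anchored positional counts are normalized by that
#' transcript's mean count over the window (transcripts with zero coverage
#' in the window are skipped), then averaged across transcripts. The
#' normalization makes the profile invariant to per-transcript expression
#' scale.
#'
#' @param reads data.frame with `gene_id`, `pos5`, `length`.
#' @param transcripts a `transcriptome` data.frame.
#' @param anchor `"start"` (first nt of the start codon) or `"stop"` (first
#'   nt of the stop codon).
#' @param window integer c(lo, hi): positions lo..hi relative to the anchor.
#' @param offset anchor offset applied to read 5' ends (P-site offset).
#' @return list of class `metagene_profile`: `anchor`, `positions`,
#'   `density`, `n_transcripts`.
#' @export
metagene <- function(reads, transcripts, anchor = c("start", "stop"),
                     window = c(-30L, 60L), offset = 0L) {
  anchor <- match.arg(anchor)
  reg <- transcript_regions(transcripts)
  idx <- valid_reads(reads, reg)
  positions <- seq.int(window[1], window[2])
  w <- length(positions)

  anchor_pos <- if (anchor == "start") reg$cds_start else reg$cds_end - 3L
  # transcripts for which the whole window lies inside the transcript
  eligible <- which(anchor_pos + window[1] >= 0 &
                    anchor_pos + window[2] < reg$tx_length)
  if (!length(eligible)) stopf("no transcripts can host the window")
  keep <- idx %in% eligible
  rel <- (reads$pos5[keep] + offset) - anchor_pos[idx[keep]]
  gi <- idx[keep]

  inside <- rel >= window[1] & rel <= window[2]
  rel <- rel[inside]; gi <- gi[inside]
  if (!length(rel)) stopf("no reads fall inside the metagene window")

  tab <- table(factor(gi, levels = eligible),
               factor(rel, levels = positions))
  m <- matrix(as.numeric(tab), nrow = length(eligible), ncol = w)
  means <- rowMeans(m)
  use <- means > 0
  if (!any(use)) stopf("all eligible transcripts have zero coverage")
  norm <- m[use, , drop = FALSE] / means[use]
  structure(list(anchor = anchor, positions = positions,
                 density = colMeans(norm), n_transcripts = sum(use)),
            class = "metagene_profile")
}

#' Calibrate P-site offsets per read length
#'
#' For each read-length group the chosen offset maximizes the number of
#' reads whose shifted 5' end (pos5 + offset) lands exactly on its gene's
#' CDS start codon; ties are broken toward the smaller offset. The
#' initiation peak present in ribosome-profiling coverage is what makes the
#' true offset identifiable. The consensus is the read-count-weighted mode
#' of the per-length offsets.
#'
#' @param reads data.frame with `gene_id`, `pos5`, `length`.
#' @param transcripts a `transcriptome` data.frame.
#' @param candidate_offsets integer vector of offsets to score.
#' @param min_reads minimum reads for a length group to be calibrated.
#' @return list of class `psite_calibration`: `per_length` (data.frame
#'   `length`, `offset`, `sharpness`, `n_reads`), `consensus`.
#' @export
calibrate_psite <- function(reads, transcripts, candidate_offsets = 0:18,
                            min_reads = 100L) {
  reg <- transcript_regions(transcripts)
  idx <- valid_reads(reads, reg)
  candidate_offsets <- sort(unique(as.integer(candidate_offsets)))
  starts <- reg$cds_start[idx]
  lens <- sort(unique(reads$length))
  rows <- list()
  for (L in lens) {
    sel <- reads$length == L
    if (sum(sel) < min_reads) next
    score <- vapply(candidate_offsets, function(o)
      sum(reads$pos5[sel] + o == starts[sel]), numeric(1))
    if (all(score == 0)) next
    best <- candidate_offsets[which.max(score)]  # which.max takes first tie
    rows[[length(rows) + 1L]] <-
      data.frame(length = L, offset = best,
                 sharpness = max(score) / sum(score), n_reads = sum(sel))
  }
  if (!length(rows))
    stopf(paste("no candidate offset received any start-codon support;",
                "widen candidate_offsets or lower min_reads"))
  per_length <- do.call(rbind, rows)
  support <- tapply(per_length$n_reads, per_length$offset, sum)
  winners <- as.integer(names(support)[support == max(support)])
  structure(list(per_length = per_length, consensus = min(winners)),
            class = "psite_calibration")
}

#' Sub-codon phasing of P-sites
#'
#' Computes frame = (P-site - cds_start) mod 3 for all P-sites inside the
#' CDS. Frames are 0-based: the canonical reading frame is frame 0.
#'
#' @param reads data.frame with `gene_id`, `pos5`, `length`.
#' @param transcripts a `transcriptome` data.frame.
#' @param calibration a `psite_calibration`, or a single integer offset.
#' @return list of class `phasing_summary`: `fractions` (length 3, sums
#'   to 1), `counts`, `n_used`.
#' @export
phasing <- function(reads, transcripts, calibration) {
  reg <- transcript_regions(transcripts)
  idx <- valid_reads(reads, reg)
  if (inherits(calibration, "psite_calibration")) {
    off <- calibration$per_length$offset[
      match(reads$length, calibration$per_length$length)]
    off[is.na(off)] <- calibration$consensus
  } else {
    off <- rep_len(as.integer(calibration), nrow(reads))
  }
  p <- reads$pos5 + off
  in_cds <- p >= reg$cds_start[idx] & p < reg$cds_end[idx]
  if (!any(in_cds)) stopf("no P-sites fall inside a CDS")
  fr <- (p[in_cds] - reg$cds_start[idx][in_cds]) %% 3L
  counts <- vapply(0:2, function(f) sum(fr == f), numeric(1))
  names(counts) <- paste0("frame", 0:2)
  structure(list(fractions = counts / sum(counts), counts = counts,
                 n_used = sum(in_cds)),
            class = "phasing_summary")
}
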