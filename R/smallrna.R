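#' Seed region of a small RNA
#'
#' Nucleotides 2-8 (7 nt) of the small RNA, the canonical
#' target-recognition element of miRNAs and the analogous region used for
#' tRNA-derived fragments.
#'
#' @param x small RNA sequence(s), RNA or DNA alphabet, length >= 8.
#' @return character vector of 7-nt seeds (RNA alphabet).
#' @export
seed_region <- function(x) {
  if (any(nchar(x) < 8)) stopf("sequences must be >= 8 nt to have a seed")
  s <- toupper(dna_to_rna(x))
  bad <- regexpr("[^ACGU]", s)
  if (any(bad > 0))
    stopf("seed contains non-ACGU symbol at position %d",
          bad[bad > 0][1])
  substr(s, 2, 8)
}

# DNA sequence of the target site complementary to a small RNA's seed.
seed_match_site <- function(x) revcomp_dna(rna_to_dna(seed_region(x)))

#' Count seed-match target sites in 3'UTRs
#'
#' For each small RNA, counts (overlapping) occurrences of the DNA reverse
#' complement of its seed (nucleotides 2-8) in each gene's 3'UTR.
#'
#' @param smallrnas named character vector of small RNA sequences.
#' @param transcripts a `transcriptome` data.frame (3'UTRs used).
#' @return integer matrix, small RNAs x genes.
#' @export
count_seed_sites <- function(smallrnas, transcripts) {
  if (is.null(names(smallrnas)))
    names(smallrnas) <- sprintf("sRNA%02d", seq_along(smallrnas))
  sites <- vapply(smallrnas, seed_match_site, character(1))
  utr3 <- toupper(transcripts$utr3)
  m <- t(vapply(sites, function(site)
    vapply(utr3, count_overlapping, integer(1), pattern = site,
           USE.NAMES = FALSE),
    integer(nrow(transcripts))))
  dimnames(m) <- list(names(smallrnas), transcripts$gene_id)
  m
}

#' Site-count-stratified CDF comparison of target responses
#'
#' Genes are stratified by their (pooled) seed-site count into bins
#' (default 1, 2, >= 3) and each bin's response distribution (e.g. mRNA
#' log2FC) is compared to the background of genes with zero sites by a
#' two-sided two-sample Kolmogorov-Smirnov test. The median shift vs
#' background summarizes the direction of regulation.
#'
#' @param site_counts integer per-gene site counts (a single small RNA's
#'   row, or a column sum over a set for the aggregate analysis).
#' @param response named numeric response per gene (names matched to
#'   `names(site_counts)` when both are named).
#' @param bins list of bin definitions: each element `c(lo, hi)` inclusive.
#' @param min_genes bins with fewer targeted genes are skipped (with a
#'   message).
#' @return data.frame of class `target_cdf`: `bin`, `n`, `D`, `p`,
#'   `median_shift`; attribute `n_background`.
#' @export
target_cdf_test <- function(site_counts, response,
                            bins = list("1" = c(1, 1), "2" = c(2, 2),
                                        ">=3" = c(3, Inf)),
                            min_genes = 20L) {
  if (!is.null(names(site_counts)) && !is.null(names(response)))
    response <- response[names(site_counts)]
  ok <- !is.na(site_counts) & !is.na(response)
  site_counts <- site_counts[ok]; response <- response[ok]
  bg <- response[site_counts == 0]
  if (length(bg) < min_genes)
    stopf("background (zero-site genes) too small: %d", length(bg))
  rows <- list()
  for (b in names(bins)) {
    sel <- site_counts >= bins[[b]][1] & site_counts <= bins[[b]][2]
    if (sum(sel) < min_genes) {
      message(sprintf("bin '%s' skipped: only %d genes", b, sum(sel)))
      next
    }
    ks <- suppressWarnings(ks.test(response[sel], bg))
    rows[[b]] <- data.frame(bin = b, n = sum(sel),
                            D = unname(ks$statistic), p = ks$p.value,
                            median_shift = median(response[sel]) - median(bg),
                            stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(bin = character(), n = integer(), D = numeric(),
               p = numeric(), median_shift = numeric())
  rownames(out) <- NULL
  class(out) <- c("target_cdf", "data.frame")
  attr(out, "n_background") <- length(bg)
  out
}

#' Map small RNA reads to tRNA references and classify tsRNA origin
#'
#' Tiered matching: exact substring first, then Hamming distance 1, 2 and 3
#' over all gapless offsets (deletions are approximated by the shifted
#' offset scan, a documented simplification). Each read is assigned to the
#' first reference hit at its best tier. Origin rules, applied in order:
#' read starts at the mature 5' end -> `5p-mature`; read ends at the mature
#' 3' terminus (CCA included) -> `3p-mature`; read contained in the
#' precursor leader -> `5p-precursor`; read overlapping the D- or
#' anticodon-loop without touching either terminus -> `DA-loop`. Length
#' class: >= 31 nt -> tRH; 28-30 nt -> tRH iff the read overlaps the
#' anticodon-loop span, else tRF; <= 27 nt -> tRF.
#'
#' @param read_seqs character vector of small RNA read sequences (DNA or
#'   RNA alphabet).
#' @param refs tRNA references from [make_trna_references()] (landmark
#'   columns required).
#' @param max_mismatch deepest mismatch tier to attempt.
#' @return data.frame: one row per read with `seq`, `ref_id`, `aa`,
#'   `anticodon`, `start` (0-based, NA if unassigned), `length`,
#'   `mismatch`, `origin`, `class`, `assigned`. Unassigned reads are
#'   reported, not dropped.
#' @export
map_tsrna <- function(read_seqs, refs, max_mismatch = 3L) {
  check_landmarks(refs)
  subjects <- Biostrings::DNAStringSet(rna_to_dna(toupper(refs$seq)))
  uniq <- unique(rna_to_dna(toupper(read_seqs)))
  hit <- data.frame(seq = uniq, ref = NA_integer_, start = NA_integer_,
                    mismatch = NA_integer_, stringsAsFactors = FALSE)
  for (u in seq_along(uniq)) {
    pat <- Biostrings::DNAString(uniq[u])
    for (k in 0:max_mismatch) {
      cnt <- Biostrings::vcountPattern(pat, subjects, max.mismatch = k)
      if (any(cnt > 0)) {
        ref <- which(cnt > 0)[1]
        m <- Biostrings::matchPattern(pat, subjects[[ref]], max.mismatch = k)
        hit$ref[u] <- ref
        hit$start[u] <- Biostrings::start(m)[1] - 1L  # 0-based
        hit$mismatch[u] <- k
        break
      }
    }
  }
  idx <- match(rna_to_dna(toupper(read_seqs)), hit$seq)
  h <- hit[idx, ]
  len <- nchar(read_seqs)
  n <- length(read_seqs)
  origin <- rep(NA_character_, n)
  cls <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (is.na(h$ref[i])) next
    r <- refs[h$ref[i], ]
    origin[i] <- tsrna_origin(h$start[i], len[i], r)
    cls[i] <- tsrna_class(h$start[i], len[i], r)
  }
  data.frame(seq = read_seqs,
             ref_id = ifelse(is.na(h$ref), NA, refs$ref_id[h$ref]),
             aa = ifelse(is.na(h$ref), NA, refs$aa[h$ref]),
             anticodon = ifelse(is.na(h$ref), NA, refs$anticodon[h$ref]),
             start = h$start, length = len, mismatch = h$mismatch,
             origin = origin, class = cls, assigned = !is.na(h$ref),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Merge tsRNA annotations into species
#'
#' tsRNAs from parent tRNAs bearing the same amino acid and anticodon, with
#' the same origin and length class, are merged into one species named
#' `<AA><anticodon>-<class>-<suffix>` (suffix 5 = 5' mature, 3 = 3' mature,
#' DA = D/anticodon loop, 1 = 5' precursor). Counts are summed, so merged
#' totals conserve the input total.
#'
#' @param annotations data.frame with `aa`, `anticodon`, `origin`, `class`
#'   (e.g. from [map_tsrna()]); unassigned/unclassified rows are dropped
#'   (their number is reported in attribute `n_dropped`).
#' @param counts optional numeric matrix/data.frame of per-sample counts,
#'   one row per annotation row; defaults to a single column of 1s (read
#'   multiplicities).
#' @return data.frame: `species`, `aa`, `anticodon`, `origin`, `class`,
#'   then one count column per sample.
#' @export
merge_species <- function(annotations, counts = NULL) {
  if (is.null(counts))
    counts <- matrix(1, nrow(annotations), 1,
                     dimnames = list(NULL, "count"))
  counts <- as.matrix(counts)
  keep <- !is.na(annotations$aa) & !is.na(annotations$origin) &
    annotations$origin %in% names(ORIGIN_SUFFIX)
  dropped <- sum(!keep)
  ann <- annotations[keep, , drop = FALSE]
  counts <- counts[keep, , drop = FALSE]
  key <- paste0(ann$aa, ann$anticodon, "-", ann$class, "-",
                ORIGIN_SUFFIX[ann$origin])
  agg <- rowsum(counts, group = key)
  first <- !duplicated(key)
  meta <- ann[first, c("aa", "anticodon", "origin", "class")]
  meta$species <- key[first]
  meta <- meta[match(rownames(agg), meta$species), ]
  out <- cbind(meta[, c("species", "aa", "anticodon", "origin", "class")],
               as.data.frame(agg))
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

#' Differential expression of merged tsRNA species
#'
#' Applies the robust-expression filter (CPM > `cpm_threshold` in every
#' sample of at least one condition), then the exact-test differential
#' expression path.
#'
#' @param counts species x samples count matrix (rownames = species ids).
#' @param group condition label per sample.
#' @param treated,control condition labels to contrast.
#' @param cpm_threshold robust-expression CPM cutoff.
#' @param ... passed to [exact_test()] (alpha, lfc, ...).
#' @return a `de_result` over the surviving species.
#' @export
tsrna_de <- function(counts, group, treated, control, cpm_threshold = 100,
                     ...) {
  counts <- as_counts(counts)
  cc <- cpm(counts)
  robust <- rep(FALSE, nrow(counts))
  for (g in unique(group)) {
    sel <- group == g
    robust <- robust | rowSums(cc[, sel, drop = FALSE] > cpm_threshold) ==
      sum(sel)
  }
  counts <- counts[robust, , drop = FALSE]
  if (!nrow(counts)) stopf("no species passes the CPM > %g filter",
                           cpm_threshold)
  factors <- tmm_factors(counts)
  disp <- estimate_dispersion(counts, group, factors)
  exact_test(counts, which(group == treated), which(group == control),
             disp$phi, factors, ...)
}
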