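#' Classify per-gene regulatory modes from paired mRNA/RPF DE results
#'
#' Deterministic rule over the two significance calls and fold-change
#' signs: both significant and same sign -> `homodirectional`; both and
#' opposite sign -> `opposite`; mRNA only -> `transcriptional` (candidate
#' post-transcriptional buffering); RPF only -> `translational`; neither ->
#' `stable`. A log2FC of exactly 0 carried by a significant call is
#' treated as positive and flagged in `zero_sign_flag`.
#'
#' @param mrna_de,rpf_de `de_result` data.frames; the gene universe is
#'   their intersection (size reported in attribute `n_shared`).
#' @return data.frame of class `regmode_table`: `gene_id`, `mode`,
#'   `mrna_log2fc`, `rpf_log2fc`, `mrna_significant`, `rpf_significant`,
#'   `zero_sign_flag`.
#' @export
classify_modes <- function(mrna_de, rpf_de) {
  genes <- intersect(mrna_de$gene_id, rpf_de$gene_id)
  if (!length(genes)) stopf("no shared genes between the DE tables")
  m <- mrna_de[match(genes, mrna_de$gene_id), ]
  r <- rpf_de[match(genes, rpf_de$gene_id), ]
  sgn <- function(x) ifelse(x >= 0, 1, -1)  # zero counts as positive
  zero_flag <- (m$log2fc == 0 & m$significant) |
               (r$log2fc == 0 & r$significant)
  mode <- ifelse(m$significant & r$significant,
                 ifelse(sgn(m$log2fc) == sgn(r$log2fc),
                        "homodirectional", "opposite"),
                 ifelse(m$significant, "transcriptional",
                        ifelse(r$significant, "translational", "stable")))
  out <- data.frame(gene_id = genes, mode = mode,
                    mrna_log2fc = m$log2fc, rpf_log2fc = r$log2fc,
                    mrna_significant = m$significant,
                    rpf_significant = r$significant,
                    zero_sign_flag = zero_flag,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("regmode_table", "data.frame")
  attr(out, "n_shared") <- length(genes)
  out
}

#' Summarize regulatory-mode counts and post-transcriptional buffering
#'
#' @param modes a `regmode_table`.
#' @return list: `counts` (named over all five modes), `fractions`,
#'   `n_genes`, and `transcriptional_translational_ratio` (the
#'   buffering indicator; `NA` when no gene is translational-only).
#' @export
buffering_summary <- function(modes) {
  if (!nrow(modes)) stopf("empty mode table")
  counts <- vapply(REGULATORY_MODES, function(m) sum(modes$mode == m),
                   numeric(1))
  ratio <- if (counts[["translational"]] == 0) NA_real_ else
    counts[["transcriptional"]] / counts[["translational"]]
  list(counts = counts, fractions = counts / sum(counts),
       n_genes = nrow(modes),
       transcriptional_translational_ratio = ratio)
}

#' Overlap of significant gene sets across contrasts
#'
#' Venn-style persistence summary for two DE results from different time
#' points: how many genes are significant in one only, persistently up or
#' down in both, or change direction.
#'
#' @param de1,de2 `de_result` data.frames.
#' @return list of counts: `only1`, `only2`, `both_up`, `both_down`,
#'   `opposite`, plus the significant-gene totals.
#' @export
persistence_overlap <- function(de1, de2) {
  s1 <- de1$gene_id[de1$significant]
  s2 <- de2$gene_id[de2$significant]
  both <- intersect(s1, s2)
  d1 <- setNames(sign(de1$log2fc), de1$gene_id)[both]
  d2 <- setNames(sign(de2$log2fc), de2$gene_id)[both]
  list(n_sig1 = length(s1), n_sig2 = length(s2),
       only1 = length(setdiff(s1, s2)), only2 = length(setdiff(s2, s1)),
       both_up = sum(d1 > 0 & d2 > 0), both_down = sum(d1 < 0 & d2 < 0),
       opposite = sum(d1 * d2 < 0))
}
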