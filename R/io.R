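#' Write/read count matrices as TSV
#'
#' Plain-text interchange: first column `gene_id`, then one column per
#' sample named `assay_condition_rep`.
#'
#' @param cm a `count_matrix` (or plain matrix for `write_counts_tsv`).
#' @param path file path.
#' @return `read_counts_tsv` returns a `count_matrix` when the column
#'   names parse as `assay_condition_rep`, else a plain matrix.
#' @export
write_counts_tsv <- function(cm, path) {
  counts <- as_counts(cm)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  parts <- strsplit(colnames(m), "_")
  if (all(lengths(parts) == 3)) {
    count_matrix(m, vapply(parts, `[`, "", 1), vapply(parts, `[`, "", 2),
                 vapply(parts, `[`, "", 3))
  } else m
}

#' Write/read aligned-read tables as TSV
#'
#' Columns: `gene_id`, `pos5` (0-based 5' position), `length`.
#' @param reads data.frame of aligned reads.
#' @param path file path.
#' @export
write_reads_tsv <- function(reads, path) {
  write.table(reads[, c("gene_id", "pos5", "length")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reads_tsv
#' @export
read_reads_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write transcript regions as FASTA plus a region-length table
#'
#' One FASTA record per non-empty region, id `gene|region`; the companion
#' TSV carries the per-region lengths and CDS coordinates.
#'
#' @param transcripts a `transcriptome` data.frame.
#' @param fasta_path,regions_path output paths.
#' @export
write_transcriptome <- function(transcripts, fasta_path, regions_path) {
  seqs <- character(0)
  for (r in c("utr5", "cds", "utr3")) {
    s <- transcripts[[r]]
    keep <- nchar(s) > 0
    seqs <- c(seqs, setNames(s[keep],
                             paste0(transcripts$gene_id[keep], "|", r)))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta_path)
  write.table(transcript_regions(transcripts), regions_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}

#' Read a region FASTA (ids `gene|region`) back into a transcriptome
#' @param fasta_path FASTA written by [write_transcriptome()].
#' @return a `transcriptome` data.frame (absent regions become "").
#' @export
read_transcriptome <- function(fasta_path) {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  parts <- strsplit(names(ss), "|", fixed = TRUE)
  gene <- vapply(parts, `[`, "", 1)
  region <- vapply(parts, `[`, "", 2)
  genes <- unique(gene)
  out <- data.frame(gene_id = genes, utr5 = "", cds = "", utr3 = "",
                    stringsAsFactors = FALSE)
  for (i in seq_along(ss)) {
    out[[region[i]]][out$gene_id == gene[i]] <- as.character(ss[[i]])
  }
  class(out) <- c("transcriptome", "data.frame")
  out
}

#' Serialize simulation ground truth to JSON
#' @param sim result of [simulate_experiment()].
#' @param path output path.
#' @export
write_truth_json <- function(sim, path) {
  jsonlite::write_json(
    list(seed = sim$seed,
         config = sim$config[setdiff(names(sim$config), "mode_mix")],
         mode_mix = sim$config$mode_mix,
         offset = sim$config$offset,
         frame_fidelity = sim$config$frame_fidelity,
         truth = sim$truth,
         mirnas = as.list(sim$mirnas),
         tsrna_truth = sim$tsrna_truth),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
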