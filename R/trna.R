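#' tsRNA origin labels and Fig-style suffixes
#'
#' Origins: cut at the mature 5' end (`5p-mature`), at the mature 3'
#' terminus including the CCA tail (`3p-mature`), contained in the precursor
#' leader (`5p-precursor`), or overlapping the D- or anticodon(A)-loop
#' without touching either terminus (`DA-loop`).
#' @export
TSRNA_ORIGINS <- c("5p-mature", "3p-mature", "DA-loop", "5p-precursor")

ORIGIN_SUFFIX <- c("5p-mature" = "5", "3p-mature" = "3",
                   "DA-loop" = "DA", "5p-precursor" = "1")

# amino acid / anticodon pairs sampled for synthetic references
TRNA_ISOTYPES <- data.frame(
  aa = c("Glu", "Glu", "Leu", "Leu", "Ala", "Ala", "Cys", "Gly", "Lys",
         "Val", "Asp", "His"),
  anticodon = c("TTC", "CTC", "TAA", "CAA", "AGC", "TGC", "GCA", "GCC",
                "CTT", "AAC", "GTC", "GTG"),
  stringsAsFactors = FALSE)

#' Generate synthetic tRNA references with cloverleaf landmarks
#'
#' Each reference is a precursor leader followed by the mature sequence with
#' the CCA tail appended (mature length 72 + CCA = 75 nt). Landmarks are
#' given in 0-based half-open reference coordinates: `mature_start`/
#' `mature_end` delimit the mature body (including CCA), `dloop_*` the
#' D-loop and `acloop_*` the anticodon loop; the anticodon itself occupies
#' mature positions 34-36.
#'
#' @param n number of references (cycled over a table of amino
#'   acid/anticodon isotypes).
#' @param leader_len 5' precursor leader length in nt.
#' @param seed integer RNG seed.
#' @return data.frame: `ref_id`, `aa`, `anticodon`, `seq`, `leader_len`,
#'   `mature_start`, `mature_end`, `dloop_start`, `dloop_end`,
#'   `acloop_start`, `acloop_end`.
#' @export
make_trna_references <- function(n = 12L, leader_len = 50L, seed = 1L) {
  iso <- TRNA_ISOTYPES[rep_len(seq_len(nrow(TRNA_ISOTYPES)), n), ]
  with_seed(seed, {
    mature_body <- 72L
    refs <- lapply(seq_len(n), function(i) {
      body <- strsplit(random_seq(mature_body, 0.5), "")[[1]]
      body[35:37] <- strsplit(iso$anticodon[i], "")[[1]]  # mature pos 34-36
      mature <- paste0(paste(body, collapse = ""), "CCA")
      leader <- random_seq(leader_len, 0.45)
      data.frame(
        ref_id = sprintf("tRNA-%s-%s-%d", iso$aa[i], iso$anticodon[i], i),
        aa = iso$aa[i], anticodon = iso$anticodon[i],
        seq = paste0(leader, mature),
        leader_len = leader_len,
        mature_start = leader_len,
        mature_end = leader_len + mature_body + 3L,
        dloop_start = leader_len + 13L, dloop_end = leader_len + 22L,
        acloop_start = leader_len + 31L, acloop_end = leader_len + 40L,
        stringsAsFactors = FALSE)
    })
    do.call(rbind, refs)
  })
}

LANDMARK_COLS <- c("leader_len", "mature_start", "mature_end", "dloop_start",
                   "dloop_end", "acloop_start", "acloop_end")

check_landmarks <- function(refs) {
  for (col in LANDMARK_COLS) {
    if (is.null(refs[[col]]) || anyNA(refs[[col]])) {
      bad <- if (is.null(refs[[col]])) refs$ref_id else
        refs$ref_id[is.na(refs[[col]])]
      stopf("landmark '%s' missing for tRNA reference(s): %s", col,
            paste(head(bad, 5), collapse = ", "))
    }
  }
  invisible(TRUE)
}

# One documented rule shared by the simulator (truth labels) and the mapper:
# length >= 31 -> tRH; 28-30 -> tRH iff the read overlaps the
# anticodon-loop span; otherwise tRF.
tsrna_class <- function(start0, len, ref_row) {
  end0 <- start0 + len
  overlaps_ac <- start0 < ref_row$acloop_end & end0 > ref_row$acloop_start
  ifelse(len >= 31L, "tRH",
         ifelse(len >= 28L & overlaps_ac, "tRH", "tRF"))
}

tsrna_origin <- function(start0, len, ref_row) {
  end0 <- start0 + len
  if (start0 == ref_row$mature_start) return("5p-mature")
  if (end0 == ref_row$mature_end) return("3p-mature")
  if (end0 <= ref_row$mature_start) return("5p-precursor")
  inside <- start0 > ref_row$mature_start & end0 < ref_row$mature_end
  hits_loop <-
    (start0 < ref_row$dloop_end & end0 > ref_row$dloop_start) ||
    (start0 < ref_row$acloop_end & end0 > ref_row$acloop_start)
  if (inside && hits_loop) return("DA-loop")
  "other"
}

#' Default tsRNA cut plan
#'
#' tRFs are cut predominantly from tRNA 3' ends and tRHs from 5' ends, the
#' biases reported for stimulated neuronal cells.
#' @export
default_cut_plan <- function() {
  data.frame(
    origin = c("3p-mature", "5p-mature", "DA-loop", "5p-precursor",
               "5p-mature", "3p-mature"),
    class = c("tRF", "tRF", "tRF", "tRF", "tRH", "tRH"),
    fraction = c(0.45, 0.15, 0.10, 0.08, 0.20, 0.02),
    stringsAsFactors = FALSE)
}

#' Simulate tRNA-derived small RNA reads
#'
#' Reads are exact substrings of the references, cut at the landmark implied
#' by the requested origin, with lengths drawn from the class range (tRF
#' 14-30 nt, tRH 28-36 nt, restricted where needed so the documented length/
#' loop classification rule reproduces the requested class).
#'
#' @param refs tRNA references from [make_trna_references()] (landmark
#'   columns required).
#' @param cut_plan data.frame with columns `origin`, `class`, `fraction`
#'   (fractions normalized internally).
#' @param n_reads number of reads.
#' @param seed integer RNG seed.
#' @return data.frame of reads with recorded truth: `read_id`, `seq`,
#'   `ref_id`, `aa`, `anticodon`, `start` (0-based in the reference),
#'   `length`, `origin`, `class`.
#' @export
simulate_tsrna_reads <- function(refs, cut_plan = default_cut_plan(),
                                 n_reads = 1e4, seed = 1L) {
  check_landmarks(refs)
  if (any(cut_plan$fraction < 0)) stopf("cut_plan fractions must be >= 0")
  frac <- cut_plan$fraction / sum(cut_plan$fraction)
  with_seed(seed, {
    rows <- sample.int(nrow(cut_plan), n_reads, replace = TRUE, prob = frac)
    ref_idx <- sample.int(nrow(refs), n_reads, replace = TRUE)
    start0 <- integer(n_reads)
    len <- integer(n_reads)
    for (i in seq_len(n_reads)) {
      r <- refs[ref_idx[i], ]
      origin <- cut_plan$origin[rows[i]]
      cls <- cut_plan$class[rows[i]]
      if (origin == "5p-mature") {
        len[i] <- if (cls == "tRH") sample(32:36, 1L) else sample(14:27, 1L)
        start0[i] <- r$mature_start
      } else if (origin == "3p-mature") {
        len[i] <- if (cls == "tRH") sample(31:36, 1L) else sample(14:27, 1L)
        start0[i] <- r$mature_end - len[i]
      } else if (origin == "5p-precursor") {
        len[i] <- sample(14:27, 1L)
        start0[i] <- sample.int(r$leader_len - len[i] + 1L, 1L) - 1L
      } else if (origin == "DA-loop") {
        len[i] <- sample(14:27, 1L)
        loop <- if (runif(1) < 0.5) c(r$dloop_start, r$dloop_end) else
          c(r$acloop_start, r$acloop_end)
        lo <- max(r$mature_start + 1L, loop[1] - len[i] + 1L)
        hi <- min(r$mature_end - len[i] - 1L, loop[2] - 1L)
        start0[i] <- if (hi <= lo) lo else
          lo + sample.int(hi - lo + 1L, 1L) - 1L
      } else stopf("unknown origin '%s' in cut_plan", origin)
    }
    r <- refs[ref_idx, ]
    truth_origin <- vapply(seq_len(n_reads), function(i)
      tsrna_origin(start0[i], len[i], refs[ref_idx[i], ]), character(1))
    truth_class <- vapply(seq_len(n_reads), function(i)
      tsrna_class(start0[i], len[i], refs[ref_idx[i], ]), character(1))
    data.frame(read_id = sprintf("tsr%05d", seq_len(n_reads)),
               seq = substr(r$seq, start0 + 1L, start0 + len),
               ref_id = r$ref_id, aa = r$aa, anticodon = r$anticodon,
               start = start0, length = len,
               origin = truth_origin, class = truth_class,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}
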