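#' @useDynLib ribopost, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnbinom rpois runif rnorm rmultinom quantile median
#'   p.adjust pchisq ks.test kruskal.test dnbinom dpois setNames lm.wfit
#' @importFrom utils head read.delim write.table modifyList
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA sequence
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp_dna <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(x, function(s) {
    b <- rev(strsplit(toupper(s), "", fixed = TRUE)[[1]])
    paste(comp[b], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Convert between RNA and DNA alphabets
#'
#' @param x character vector of sequences.
#' @return `rna_to_dna()` replaces U with T; `dna_to_rna()` replaces T with U.
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

#' @rdname rna_to_dna
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

# Count (possibly overlapping) occurrences of a literal pattern.
count_overlapping <- function(pattern, subject) {
  if (nchar(pattern) == 0L || nchar(subject) < nchar(pattern)) return(0L)
  m <- gregexpr(paste0("(?=", pattern, ")"), subject, perl = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

geomean <- function(x) exp(mean(log(x)))

gc_fraction <- function(seq) {
  n <- nchar(seq)
  if (is.na(seq) || n == 0L) return(NA_real_)
  b <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  sum(b %in% c("G", "C")) / n
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
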