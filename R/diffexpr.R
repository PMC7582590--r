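#' Counts per million
#'
#' @param counts genes x samples matrix (or `count_matrix`).
#' @return numeric matrix; each column sums to 1e6.
#' @export
cpm <- function(counts) {
  counts <- as_counts(counts)
  tot <- colSums(counts)
  if (any(tot == 0))
    stopf("library '%s' has zero total count",
          colnames(counts)[which(tot == 0)[1]])
  sweep(counts, 2, tot, "/") * 1e6
}

as_counts <- function(x) if (inherits(x, "count_matrix")) x$counts else x

#' Remove genes with consistently low counts
#'
#' Keeps a gene iff its CPM is >= `cpm_threshold` in at least `min_samples`
#' samples; gene order is preserved.
#'
#' @param counts genes x samples matrix.
#' @param cpm_threshold CPM cutoff (>= 0).
#' @param min_samples minimum number of samples meeting the cutoff
#'   (defaults to the number of replicates of the smallest group if a
#'   `group` is given, else 1).
#' @param group optional sample grouping used only for the default
#'   `min_samples`.
#' @return filtered count matrix.
#' @export
filter_low <- function(counts, cpm_threshold = 1, min_samples = NULL,
                       group = NULL) {
  counts <- as_counts(counts)
  if (cpm_threshold < 0) stopf("cpm_threshold must be >= 0")
  if (is.null(min_samples))
    min_samples <- if (is.null(group)) 1L else min(table(group))
  keep <- rowSums(cpm(counts) >= cpm_threshold) >= min_samples
  counts[keep, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values computed on raw counts against a reference
#' sample (the one whose 75th-percentile CPM is closest to the mean of
#' those), using genes positive in both libraries, trimming the most
#' extreme M-values (default 30% each side) and A-values (default 5% each
#' side), with precision weights equal to the inverse asymptotic variance
#' of M. Because M-values are taken on raw counts, the factors absorb both
#' sequencing depth and composition bias: they are relative *effective
#' library sizes*, rescaled to geometric mean 1. Multiply by the geometric
#' mean of the library totals (see [effective_libsizes()]) to recover
#' absolute effective sizes.
#'
#' @param counts genes x samples matrix (>= 2 samples).
#' @param trim_M two-sided trim fraction on M-values.
#' @param trim_A two-sided trim fraction on A-values.
#' @return numeric vector of per-sample factors with geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  counts <- as_counts(counts)
  if (ncol(counts) < 2) stopf("TMM needs at least 2 samples")
  q75 <- apply(cpm(counts), 2, quantile, probs = 0.75)
  ref <- which.min(abs(q75 - mean(q75)))
  f <- vapply(seq_len(ncol(counts)), function(s)
    tmm_one(counts[, s], counts[, ref], colSums(counts)[s],
            colSums(counts)[ref], trim_M, trim_A), numeric(1))
  f / geomean(f)
}

tmm_one <- function(y, r, Ny, Nr, trim_M, trim_A) {
  pos <- y > 0 & r > 0
  y <- y[pos]; r <- r[pos]
  if (!length(y)) return(1)
  M <- log2(y) - log2(r)
  A <- (log2(y) + log2(r)) / 2
  w <- 1 / ((Ny - y) / (Ny * y) + (Nr - r) / (Nr * r))
  n <- length(M)
  loM <- floor(n * trim_M) + 1; hiM <- n - floor(n * trim_M)
  loA <- floor(n * trim_A) + 1; hiA <- n - floor(n * trim_A)
  rM <- rank(M, ties.method = "first")
  rA <- rank(A, ties.method = "first")
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (sum(keep) < 10) {
    warnf("fewer than 10 genes survive TMM trimming; using untrimmed mean")
    keep <- rep(TRUE, n)
  }
  2^(sum(w[keep] * M[keep]) / sum(w[keep]))
}

#' Absolute effective library sizes
#'
#' @param counts genes x samples matrix.
#' @param factors TMM factors from [tmm_factors()] (computed if missing).
#' @return numeric vector: geometric-mean library total x factor.
#' @export
effective_libsizes <- function(counts, factors = NULL) {
  counts <- as_counts(counts)
  if (is.null(factors)) factors <- tmm_factors(counts)
  geomean(colSums(counts)) * factors
}

#' Estimate NB dispersion by moments with moderation
#'
#' Gene-wise dispersions are method-of-moments estimates on
#' normalization-adjusted counts, pooling squared deviations from the
#' condition means across conditions: phi_g = (s^2 - mu) / mu^2, floored at
#' 0. The common dispersion is the median of the positive gene-wise
#' estimates, and each gene's working dispersion is the moderated value
#' w * phi_g + (1 - w) * phi_common with w = n_reps / (n_reps + 4).
#'
#' @param counts genes x samples matrix.
#' @param group condition label per sample.
#' @param factors TMM factors (computed if missing).
#' @param phi_fixed optional user dispersion used when no condition has
#'   replicates.
#' @return list: `phi` (moderated, per gene), `phi_raw`, `phi_common`,
#'   `weight`.
#' @export
estimate_dispersion <- function(counts, group, factors = NULL,
                                phi_fixed = NULL) {
  counts <- as_counts(counts)
  group <- as.character(group)
  if (is.null(factors)) factors <- tmm_factors(counts)
  reps <- table(group)
  if (all(reps < 2)) {
    if (is.null(phi_fixed))
      stopf(paste("no condition has replicates; supply phi_fixed to use a",
                  "common dispersion"))
    phi <- rep(phi_fixed, nrow(counts))
    return(list(phi = phi, phi_raw = phi, phi_common = phi_fixed,
                weight = 0))
  }
  z <- sweep(counts, 2, factors, "/")  # counts at a common scale
  conds <- names(reps)[reps >= 2]
  ss <- matrix(0, nrow(counts), 1)
  df <- 0
  for (cc in conds) {
    zc <- z[, group == cc, drop = FALSE]
    m <- rowMeans(zc)
    ss <- ss + rowSums((zc - m)^2)
    df <- df + ncol(zc) - 1L
  }
  mu <- rowMeans(z[, group %in% conds, drop = FALSE])
  s2 <- as.vector(ss) / df
  phi_raw <- ifelse(mu > 0, (s2 - mu) / mu^2, 0)
  phi_raw <- pmax(phi_raw, 0)
  pos <- phi_raw[phi_raw > 0]
  phi_common <- if (length(pos)) median(pos) else 0
  n_reps <- mean(reps[conds])
  w <- n_reps / (n_reps + 4)
  list(phi = w * phi_raw + (1 - w) * phi_common, phi_raw = phi_raw,
       phi_common = phi_common, weight = w)
}

# Double-tail NB exact p-value for group sums sa (na libs) vs sb (nb libs)
# at a common per-library scale: conditional on the total, sum the
# probabilities of all splits no more likely than the observed one.
# phi = 0 uses the Poisson limit. A relative tolerance guards float ties.
nb_exact_pvalue <- function(sa, sb, na, nb, phi, tol = 1e-8) {
  N <- sa + sb
  if (N == 0) return(1)
  m <- N / (na + nb)
  k <- 0:N
  if (phi == 0) {
    lp <- dpois(k, na * m, log = TRUE) + dpois(N - k, nb * m, log = TRUE)
  } else {
    lp <- dnbinom(k, mu = na * m, size = na / phi, log = TRUE) +
      dnbinom(N - k, mu = nb * m, size = nb / phi, log = TRUE)
  }
  p <- exp(lp - max(lp))
  obs <- p[sa + 1]
  min(1, sum(p[p <= obs * (1 + tol)]) / sum(p))
}

#' NB exact-test differential expression
#'
#' Counts are scaled to a common effective library size (the geometric mean
#' of the per-sample effective sizes, rounded) and summed within each
#' group; the p-value is the double-tail NB exact probability conditional
#' on the two-group total (see details in the vignette). log2 fold changes
#' (group_a over group_b) are computed from normalized group means with a
#' pseudo-count used for display only -- p-values never see it. BH
#' adjustment is applied across genes, and significance is
#' FDR < `alpha` & |log2FC| > `lfc`.
#'
#' @param counts genes x samples matrix.
#' @param group_a,group_b column indices (or names) of the two groups;
#'   `group_a` is the treatment in the reported fold change.
#' @param phi per-gene (or scalar) NB dispersion.
#' @param factors TMM factors (computed if missing).
#' @param alpha BH-FDR significance threshold.
#' @param lfc absolute log2FC significance threshold.
#' @param pseudo display pseudo-count at the common library scale.
#' @return data.frame of class `de_result`: `gene_id`, `log2fc`, `pvalue`,
#'   `fdr`, `significant`, `mean_cpm`.
#' @export
exact_test <- function(counts, group_a, group_b, phi, factors = NULL,
                       alpha = 0.05, lfc = 0.5, pseudo = 0.125) {
  counts <- as_counts(counts)
  if (is.character(group_a)) group_a <- match(group_a, colnames(counts))
  if (is.character(group_b)) group_b <- match(group_b, colnames(counts))
  if (!length(group_a) || !length(group_b))
    stopf("both groups must be non-empty")
  if (is.null(factors)) factors <- tmm_factors(counts)
  phi <- rep_len(phi, nrow(counts))

  eff <- effective_libsizes(counts, factors)
  used <- c(group_a, group_b)
  common <- geomean(eff[used])
  scaled <- round(sweep(counts[, used, drop = FALSE], 2,
                        common / eff[used], "*"))
  na <- length(group_a); nb <- length(group_b)
  sa <- rowSums(scaled[, seq_len(na), drop = FALSE])
  sb <- rowSums(scaled[, na + seq_len(nb), drop = FALSE])

  p <- vapply(seq_len(nrow(counts)), function(g)
    nb_exact_pvalue(sa[g], sb[g], na, nb, phi[g]), numeric(1))
  l2fc <- log2((sa / na + pseudo) / (sb / nb + pseudo))
  fdr <- p.adjust(p, method = "BH")
  res <- data.frame(
    gene_id = if (is.null(rownames(counts))) as.character(seq_len(nrow(counts)))
              else rownames(counts),
    log2fc = l2fc, pvalue = p, fdr = fdr,
    significant = fdr < alpha & abs(l2fc) > lfc,
    mean_cpm = rowMeans(cpm(counts)[, used, drop = FALSE]),
    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("de_result", "data.frame")
  attr(res, "alpha") <- alpha
  attr(res, "lfc") <- lfc
  res
}

#' One-call differential expression for a contrast
#'
#' Filters low-expression genes, computes TMM factors and moderated
#' dispersions on the contrast's samples, and runs the exact test
#' (treated vs control).
#'
#' @param cm a `count_matrix`.
#' @param treated,control condition labels.
#' @param cpm_threshold,min_samples low-count filter settings (see
#'   [filter_low()]; `min_samples` defaults to the smaller group size).
#' @param alpha,lfc significance thresholds.
#' @return a `de_result` (attributes carry factors and dispersions).
#' @export
run_de <- function(cm, treated, control, cpm_threshold = 1,
                   min_samples = NULL, alpha = 0.05, lfc = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  sel <- cm$samples$condition %in% c(treated, control)
  counts <- cm$counts[, sel, drop = FALSE]
  group <- cm$samples$condition[sel]
  counts <- filter_low(counts, cpm_threshold, min_samples, group = group)
  factors <- tmm_factors(counts)
  disp <- estimate_dispersion(counts, group, factors)
  res <- exact_test(counts, which(group == treated),
                    which(group == control), disp$phi, factors,
                    alpha = alpha, lfc = lfc)
  attr(res, "factors") <- factors
  attr(res, "dispersion") <- disp
  res
}
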