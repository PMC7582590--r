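# Independent oracles used against the package implementations. These are
# deliberately naive (lgamma arithmetic, explicit structure enumeration,
# regex-free scans) and share no code with the functions they check.

# log pmf of the sum of n iid NB(mean m, dispersion phi) counts:
# NB(mu = n*m, size = n/phi); phi = 0 is the Poisson limit.
oracle_group_lpmf <- function(k, m, n, phi) {
  mu <- n * m
  if (phi == 0) return(k * log(mu) - mu - lfactorial(k))
  r <- n / phi
  lgamma(k + r) - lgamma(r) - lfactorial(k) +
    r * log(r / (r + mu)) + k * log(mu / (r + mu))
}

# Double-tail exact p by full enumeration over all splits of the total.
oracle_exact_p <- function(sa, sb, na, nb, phi, tol = 1e-8) {
  N <- sa + sb
  if (N == 0) return(1)
  m <- N / (na + nb)
  k <- 0:N
  lp <- oracle_group_lpmf(k, m, na, phi) +
    oracle_group_lpmf(N - k, m, nb, phi)
  p <- exp(lp - max(lp))
  obs <- p[sa + 1]
  min(1, sum(p[p <= obs * (1 + tol)]) / sum(p))
}

# Brute-force minimum energy over all pseudoknot-free structures, by
# explicit recursive enumeration (leftmost-base decision), for short
# sequences only.
oracle_fold_min <- function(seq, e = c(GC = -3, AU = -2, GU = -1),
                            min_loop = 3) {
  b <- strsplit(chartr("Uu", "Tt", toupper(seq)), "")[[1]]
  pe <- function(x, y) {
    p <- paste0(x, y)
    if (p %in% c("GC", "CG")) return(e[["GC"]])
    if (p %in% c("AT", "TA")) return(e[["AU"]])
    if (p %in% c("GT", "TG")) return(e[["GU"]])
    NA_real_
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i + 1, j)               # i unpaired
    for (k in (i + min_loop + 1):j) {   # i paired with k
      en <- pe(b[i], b[k])
      if (!is.na(en) && en < 0) {
        v <- en + rec(i + 1, k - 1) + (if (k < j) rec(k + 1, j) else 0)
        if (v < best) best <- v
      }
    }
    best
  }
  rec(1, length(b))
}

# Naive seed-site scan: count every offset where the site matches.
oracle_site_scan <- function(site, utr) {
  w <- nchar(site)
  n <- nchar(utr)
  if (n < w) return(0L)
  sum(vapply(seq_len(n - w + 1),
             function(i) substr(utr, i, i + w - 1) == site, logical(1)))
}

# Two-sample KS statistic from the textbook definition.
oracle_ks_D <- function(x, y) {
  g <- sort(unique(c(x, y)))
  Fx <- vapply(g, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(g, function(t) mean(y <= t), numeric(1))
  max(abs(Fx - Fy))
}

# Kruskal-Wallis H with tie correction from the textbook formula.
oracle_kw_H <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (n + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}
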