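# NB log-linear fit with known dispersion by IRLS (Fisher scoring).
# X: design matrix, y: counts, offset: log effective library size.
# Returns coefficients, log-likelihood and a convergence flag.
nb_irls <- function(y, X, offset, phi, max_iter = 50L, tol = 1e-8) {
  eta <- log(pmax(y, 0.5)) - offset
  beta <- qr.solve(X, eta)
  eta <- as.vector(X %*% beta) + offset
  mu <- exp(eta)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + phi * mu)               # 1 / Var(working response)
    z <- (eta - offset) + (y - mu) / mu
    fit <- tryCatch(lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) return(NULL)
    beta <- fit$coefficients
    eta <- as.vector(X %*% beta) + offset
    eta <- pmin(eta, 30)                   # overflow guard
    mu <- exp(eta)
    ll <- nb_loglik(y, mu, phi)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(beta = beta, loglik = ll_old, converged = converged, mu = mu)
}

nb_loglik <- function(y, mu, phi) {
  if (phi == 0) sum(dpois(y, mu, log = TRUE))
  else sum(dnbinom(y, mu = mu, size = 1 / phi, log = TRUE))
}

#' Translational-efficiency interaction test
#'
#' Per gene, fits the NB log-linear model
#' `mean = exp(offset + b0 + b_assay * I(RPF) + b_cond * I(treated) +
#' b_int * I(RPF) * I(treated))` by IRLS with fixed dispersion, where the
#' offset is the log effective library size. The interaction coefficient is
#' the change in translational efficiency: `delta_log2_te = b_int / ln 2`.
#' The p-value is a likelihood-ratio test of `b_int = 0` (chi-squared,
#' 1 df), BH-adjusted across genes; non-converging genes get `NA` and are
#' excluded from the adjustment.
#'
#' @param mrna_counts,rpf_counts genes x samples matrices with matched
#'   rownames (gene universe is their intersection).
#' @param mrna_group,rpf_group condition label per column of the respective
#'   matrix.
#' @param treated,control the two condition labels to contrast.
#' @param phi per-gene dispersion (scalar recycled); estimated per assay
#'   and averaged if `NULL`.
#' @param mrna_factors,rpf_factors TMM factors per assay (computed if
#'   missing).
#' @param alpha,lfc significance thresholds on FDR and |delta log2 TE|.
#' @return data.frame of class `te_result`: `gene_id`, `delta_log2_te`,
#'   `pvalue`, `fdr`, `significant`, `converged`.
#' @export
te_test <- function(mrna_counts, rpf_counts, mrna_group, rpf_group,
                    treated, control, phi = NULL,
                    mrna_factors = NULL, rpf_factors = NULL,
                    alpha = 0.05, lfc = 0.5) {
  genes <- intersect(rownames(mrna_counts), rownames(rpf_counts))
  if (!length(genes)) stopf("no shared genes between the two assays")
  mrna_counts <- mrna_counts[genes, , drop = FALSE]
  rpf_counts <- rpf_counts[genes, , drop = FALSE]
  msel <- mrna_group %in% c(treated, control)
  rsel <- rpf_group %in% c(treated, control)
  mrna_counts <- mrna_counts[, msel, drop = FALSE]
  rpf_counts <- rpf_counts[, rsel, drop = FALSE]
  mg <- mrna_group[msel]; rg <- rpf_group[rsel]

  if (is.null(mrna_factors)) mrna_factors <- tmm_factors(mrna_counts)
  if (is.null(rpf_factors)) rpf_factors <- tmm_factors(rpf_counts)
  off <- log(c(effective_libsizes(mrna_counts, mrna_factors),
               effective_libsizes(rpf_counts, rpf_factors)))
  if (is.null(phi)) {
    dm <- estimate_dispersion(mrna_counts, mg, mrna_factors)$phi
    dr <- estimate_dispersion(rpf_counts, rg, rpf_factors)$phi
    phi <- (dm + dr) / 2
  }
  phi <- rep_len(phi, length(genes))

  is_rpf <- c(rep(0, ncol(mrna_counts)), rep(1, ncol(rpf_counts)))
  is_trt <- as.integer(c(mg, rg) == treated)
  X_full <- cbind(1, is_rpf, is_trt, is_rpf * is_trt)
  X_red <- X_full[, 1:3]

  n <- length(genes)
  est <- rep(NA_real_, n); p <- rep(NA_real_, n); conv <- logical(n)
  for (g in seq_len(n)) {
    y <- c(mrna_counts[g, ], rpf_counts[g, ])
    if (all(y == 0)) next
    f1 <- nb_irls(y, X_full, off, phi[g])
    f0 <- nb_irls(y, X_red, off, phi[g])
    if (is.null(f1) || is.null(f0) || !f1$converged || !f0$converged) next
    conv[g] <- TRUE
    est[g] <- f1$beta[4] / log(2)
    lr <- max(0, 2 * (f1$loglik - f0$loglik))
    p[g] <- pchisq(lr, df = 1, lower.tail = FALSE)
  }
  fdr <- rep(NA_real_, n)
  fdr[conv] <- p.adjust(p[conv], method = "BH")
  res <- data.frame(gene_id = genes, delta_log2_te = est, pvalue = p,
                    fdr = fdr,
                    significant = !is.na(fdr) & fdr < alpha & abs(est) > lfc,
                    converged = conv,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("te_result", "data.frame")
  res
}
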