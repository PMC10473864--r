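#' Sign concordance rate between discovery and replication effects
#'
#' Fraction of SNPs whose effect-size signs agree between a discovery and a
#' replication scan, with a one-sided binomial test (success probability
#' 0.5) for excess concordance. Pairs where either beta is zero or missing
#' are excluded from the trial count.
#'
#' @param beta_disc,beta_rep aligned effect-size vectors (typically the
#'   top-200 clumped SNPs of the discovery scan, pooled across traits).
#' @return list with `scr` (concordant fraction), `n_trials`, `k`
#'   (concordant count) and `p.value`.
#' @export
sign_concordance <- function(beta_disc, beta_rep) {
  stopifnot(length(beta_disc) == length(beta_rep))
  ok <- !is.na(beta_disc) & !is.na(beta_rep) &
    beta_disc != 0 & beta_rep != 0
  if (!any(ok)) stop("no usable (nonzero, non-missing) effect pairs")
  agree <- sign(beta_disc[ok]) == sign(beta_rep[ok])
  n <- sum(ok)
  k <- sum(agree)
  list(scr = k / n, n_trials = n, k = k,
       p.value = binom_tail(k, n, 0.5))
}

#' Pearson correlation of discovery and replication effect sizes
#'
#' Correlation between the beta coefficients of the two scans with its
#' two-sided P value from the t distribution on `n - 2` degrees of freedom.
#' The caller selects the SNP set, conventionally the top 200 SNPs from
#' clumping the discovery scan at `p1 = p2 = 1e-4` ranked by discovery P.
#'
#' @param beta_disc,beta_rep aligned effect-size vectors (>= 3 usable
#'   pairs).
#' @return list with `r`, `n`, `p.value` (`r = NA` when either vector has
#'   zero variance).
#' @export
beta_correlation <- function(beta_disc, beta_rep) {
  ok <- !is.na(beta_disc) & !is.na(beta_rep)
  x <- beta_disc[ok]; y <- beta_rep[ok]
  n <- length(x)
  if (n < 3) stop("fewer than 3 aligned effect pairs")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, n = n, p.value = NA_real_))
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, n = n, p.value = 2 * pt(-abs(tstat), n - 2))
}

#' QTL replication by Bonferroni-threshold binomial test
#'
#' Given the replication-scan P values of the discovery index SNPs, counts
#' how many fall below the Bonferroni threshold `alpha / n` and tests that
#' count against a Binomial(n, alpha / n) null (one-sided, greater).
#'
#' @param rep_pvalues replication P values of the `n` overlapping discovery
#'   index SNPs.
#' @param alpha family-wise level (default 0.05).
#' @return list with `n`, `threshold`, `k` (replicated count) and
#'   `p.value`.
#' @export
qtl_replication <- function(rep_pvalues, alpha = 0.05) {
  n <- length(rep_pvalues)
  if (n < 1) stop("need at least one replication P value")
  threshold <- alpha / n
  k <- sum(!is.na(rep_pvalues) & rep_pvalues < threshold)
  list(n = n, threshold = threshold, k = k,
       p.value = binom_tail(k, n, threshold))
}

#' Full replication summary between two scans
#'
#' Convenience wrapper computing the three replication indexes between a
#' discovery and a replication association scan: the sign concordance rate
#' on the top clumped SNPs, the Pearson correlation of their effect sizes,
#' and the Bonferroni binomial replication of the discovery QTLs.
#'
#' @param disc,rep `assoc_result` scans on the same SNP panel.
#' @param geno_disc discovery `geno_matrix` (for clumping LD).
#' @param top number of top clumped SNPs for SCR/correlation (default 200).
#' @param clump_p clumping threshold for the top-SNP set (default 1e-4).
#' @param qtl_p1 genome-wide threshold defining discovery QTLs
#'   (default 5e-8).
#' @return list of class `replication_summary` with elements `scr`,
#'   `beta_cor`, `qtl` (each as returned by the component functions) and
#'   `top_snps`.
#' @export
replication_summary <- function(disc, rep, geno_disc, top = 200,
                                clump_p = 1e-4, qtl_p1 = 5e-8) {
  cl <- clump(disc, geno_disc, p1 = clump_p, p2 = clump_p)
  top_snps <- head(cl$index_snp, top)
  i_d <- match(top_snps, disc$snp_id)
  i_r <- match(top_snps, rep$snp_id)
  scr <- sign_concordance(disc$beta[i_d], rep$beta[i_r])
  bc <- if (length(top_snps) >= 3)
    beta_correlation(disc$beta[i_d], rep$beta[i_r]) else NULL
  qtl_cl <- clump(disc, geno_disc, p1 = qtl_p1, p2 = qtl_p1)
  qtl <- if (nrow(qtl_cl)) {
    idx <- match(qtl_cl$index_snp, rep$snp_id)
    qtl_replication(rep$p[idx])
  } else NULL
  structure(list(scr = scr, beta_cor = bc, qtl = qtl, top_snps = top_snps),
            class = "replication_summary")
}

#' @export
print.replication_summary <- function(x, ...) {
  cat("Replication summary\n")
  cat(sprintf("  SCR: %.3f (k = %d / n = %d, binomial P = %.3g)\n",
              x$scr$scr, x$scr$k, x$scr$n_trials, x$scr$p.value))
  if (!is.null(x$beta_cor))
    cat(sprintf("  beta Pearson R: %.3f (n = %d, P = %.3g)\n",
                x$beta_cor$r, x$beta_cor$n, x$beta_cor$p.value))
  if (!is.null(x$qtl))
    cat(sprintf("  QTL replication: k = %d / n = %d at %.3g (P = %.3g)\n",
                x$qtl$k, x$qtl$n, x$qtl$threshold, x$qtl$p.value))
  invisible(x)
}
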