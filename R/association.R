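#' Genotype quality control
#'
#' Retains SNPs with minor allele frequency at least `maf_min`, a 1-df
#' chi-square Hardy-Weinberg equilibrium P value of at least `hwe_p_min`
#' (computed from genotype counts among non-missing subjects), and a
#' missing rate of at most `miss_max`. The operation is idempotent.
#'
#' @param geno a `geno_matrix`.
#' @param maf_min minimum MAF (default 0.01).
#' @param hwe_p_min minimum HWE P value (default 1e-6).
#' @param miss_max maximum per-SNP missing rate (default 0.05).
#' @return the filtered `geno_matrix` (a warning, not an error, if no SNP
#'   survives).
#' @export
qc_genotypes <- function(geno, maf_min = 0.01, hwe_p_min = 1e-6,
                         miss_max = 0.05) {
  stopifnot(inherits(geno, "geno_matrix"))
  D <- geno$dosages
  n <- nrow(D)
  n_obs <- colSums(!is.na(D))
  miss_rate <- 1 - n_obs / n
  af <- colSums(D, na.rm = TRUE) / (2 * n_obs)
  maf <- pmin(af, 1 - af)

  n_aa <- colSums(D == 0L, na.rm = TRUE)
  n_ab <- colSums(D == 1L, na.rm = TRUE)
  n_bb <- colSums(D == 2L, na.rm = TRUE)
  p <- (2 * n_bb + n_ab) / (2 * n_obs)
  e_aa <- n_obs * (1 - p)^2
  e_ab <- n_obs * 2 * p * (1 - p)
  e_bb <- n_obs * p^2
  chi <- ifelse(p == 0 | p == 1, 0,
                (n_aa - e_aa)^2 / pmax(e_aa, .Machine$double.eps) +
                (n_ab - e_ab)^2 / pmax(e_ab, .Machine$double.eps) +
                (n_bb - e_bb)^2 / pmax(e_bb, .Machine$double.eps))
  hwe_p <- pchisq(chi, df = 1, lower.tail = FALSE)

  keep <- !is.na(maf) & maf >= maf_min & hwe_p >= hwe_p_min &
    miss_rate <= miss_max
  if (!any(keep)) warning("no SNP passed genotype QC")
  geno$dosages <- D[, keep, drop = FALSE]
  geno$snp_info <- geno$snp_info[keep, , drop = FALSE]
  rownames(geno$snp_info) <- NULL
  geno
}

#' Residualize a phenotype on covariates
#'
#' Least-squares residuals of `y` on an intercept plus age, age^2,
#' age x sex, age^2 x sex, sex, and every `PC*` column of the covariate
#' table. Rows with missing `y` or covariates propagate as `NA`.
#'
#' @param y numeric phenotype vector, aligned to `covariates` rows.
#' @param covariates data frame with `age`, `sex` and optional `PC` columns.
#' @return residual vector of the same length as `y`.
#' @export
residualize <- function(y, covariates) {
  stopifnot(length(y) == nrow(covariates))
  age <- (covariates$age - mean(covariates$age, na.rm = TRUE)) /
    sd(covariates$age, na.rm = TRUE)
  sex <- covariates$sex
  X <- cbind(intercept = 1, age = age, age2 = age^2, sex = sex,
             agesex = age * sex, age2sex = age^2 * sex)
  pcs <- grep("^PC", names(covariates), value = TRUE)
  if (length(pcs)) X <- cbind(X, as.matrix(covariates[pcs]))
  keep_col <- apply(X, 2, function(v) length(unique(v[!is.na(v)])) > 1L)
  keep_col["intercept"] <- TRUE
  X <- X[, keep_col, drop = FALSE]
  ok <- !is.na(y) & complete.cases(X)
  qrX <- qr(X[ok, , drop = FALSE])
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  out <- rep(NA_real_, length(y))
  out[ok] <- qr.resid(qrX, y[ok])
  out
}

#' Per-SNP association scan
#'
#' Ordinary least-squares regression of a (typically residualized) phenotype
#' on each SNP's dosage: slope, standard error, and two-sided P from the t
#' distribution with `n - 2` degrees of freedom. Subjects missing either
#' value are excluded per SNP; monomorphic SNPs yield missing results. The
#' genomic inflation factor of the scan is attached.
#'
#' @param residuals numeric phenotype vector aligned to `geno` subjects.
#' @param geno a `geno_matrix`.
#' @return an `assoc_result` data frame: snp_id, chrom, pos, maf, n_used,
#'   beta, se, p; attribute `lambda_gc`.
#' @export
assoc_scan <- function(residuals, geno) {
  stopifnot(inherits(geno, "geno_matrix"),
            length(residuals) == nrow(geno$dosages))
  D <- geno$dosages
  y_ok <- !is.na(residuals)
  if (!anyNA(D) && all(y_ok)) {
    # complete-data fast path: all moments from column sums
    G <- D
    storage.mode(G) <- "double"
    y <- residuals
    n_j <- rep(nrow(G), ncol(G))
    Sg <- colSums(G)
    Sgg <- colSums(G * G)
    Sy <- rep(sum(y), ncol(G))
    Syy <- rep(sum(y^2), ncol(G))
    Sgy <- as.numeric(crossprod(G, y))
  } else {
    y <- ifelse(y_ok, residuals, 0)
    W <- (!is.na(D)) & y_ok         # subject x SNP usable mask
    G <- D
    G[is.na(G)] <- 0L
    G[!y_ok, ] <- 0L
    storage.mode(G) <- "double"
    Wn <- W * 1

    n_j <- colSums(Wn)
    Sg <- colSums(G * Wn)
    Sgg <- colSums(G * G * Wn)
    Sy <- as.numeric(crossprod(Wn, y))
    Syy <- as.numeric(crossprod(Wn, y^2))
    Sgy <- as.numeric(crossprod(G, y))
  }

  Sxx <- Sgg - Sg^2 / n_j
  Sxy <- Sgy - Sg * Sy / n_j
  Syy_c <- Syy - Sy^2 / n_j
  beta <- Sxy / Sxx
  rss <- pmax(Syy_c - beta * Sxy, 0)
  df <- n_j - 2
  se <- sqrt(rss / df / Sxx)
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df)
  mono <- !is.finite(Sxx) | Sxx <= 0 | df < 1
  beta[mono] <- NA_real_; se[mono] <- NA_real_; p[mono] <- NA_real_

  af <- Sg / (2 * n_j)
  res <- data.frame(
    snp_id = geno$snp_info$snp_id,
    chrom = geno$snp_info$chrom,
    pos = geno$snp_info$pos,
    maf = pmin(af, 1 - af),
    n_used = as.integer(n_j),
    beta = beta, se = se, p = p,
    stringsAsFactors = FALSE
  )
  attr(res, "lambda_gc") <- inflation_factor(p)
  class(res) <- c("assoc_result", "data.frame")
  res
}

#' Genomic inflation factor
#'
#' Median of the 1-df chi-square quantiles implied by the P values, divided
#' by the 1-df chi-square median (0.4549364). Values near 1 indicate
#' well-controlled confounding.
#'
#' @param pvalues numeric vector of P values (missing entries ignored).
#' @return the inflation factor lambda.
#' @export
inflation_factor <- function(pvalues) {
  p <- pvalues[!is.na(pvalues)]
  if (length(p) == 0L) stop("no non-missing P values")
  chi <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chi) / qchisq(0.5, df = 1)
}

#' Squared dosage correlation (composite LD) between two SNPs
#'
#' Squared Pearson correlation of the dosage vectors over subjects
#' non-missing at both SNPs; `NA` if either SNP is monomorphic among them.
#'
#' @param geno a `geno_matrix`.
#' @param snp_a,snp_b SNP identifiers.
#' @return r-squared in \[0, 1\] or `NA`.
#' @export
ld_r2 <- function(geno, snp_a, snp_b) {
  stopifnot(inherits(geno, "geno_matrix"))
  ia <- match(snp_a, geno$snp_info$snp_id)
  ib <- match(snp_b, geno$snp_info$snp_id)
  if (is.na(ia) || is.na(ib)) stop("unknown SNP id")
  ga <- geno$dosages[, ia]
  gb <- geno$dosages[, ib]
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]; gb <- gb[ok]
  if (length(unique(ga)) < 2L || length(unique(gb)) < 2L) return(NA_real_)
  cor(ga, gb)^2
}

#' Greedy LD clumping of an association scan into QTLs
#'
#' Among unassigned SNPs with `p < p1`, the smallest-P SNP becomes an index
#' SNP; every unassigned SNP with `p < p2`, within `kb` kilobases on the
#' same chromosome, and with dosage r^2 at least `r2` to the index is
#' assigned to its clump; the process repeats until no candidate remains.
#' Each clump is one QTL, represented by its index (lead) SNP. Ties at equal
#' P are broken by (chromosome, position) ascending.
#'
#' @param results an `assoc_result` from [assoc_scan()].
#' @param geno the matching `geno_matrix` (for LD).
#' @param p1 index-SNP significance threshold (default 5e-8).
#' @param p2 member significance threshold (default `p1`).
#' @param r2 LD threshold (default 0.5).
#' @param kb distance radius in kilobases, centre to centre (default 250).
#' @return data frame of class `clump_result`, ordered by index P:
#'   index_snp, chrom, pos, index_p, n_members, members (list column of
#'   member SNP ids, excluding the index).
#' @export
clump <- function(results, geno, p1 = 5e-8, p2 = p1, r2 = 0.5, kb = 250) {
  stopifnot(inherits(geno, "geno_matrix"),
            all(results$snp_id %in% geno$snp_info$snp_id))
  cand <- which(!is.na(results$p) & results$p < max(p1, p2))
  ord <- cand[order(results$p[cand], results$chrom[cand], results$pos[cand])]
  assigned <- rep(FALSE, nrow(results))
  out <- list()
  for (i in ord) {
    if (assigned[i] || results$p[i] >= p1) next
    assigned[i] <- TRUE
    near <- which(!assigned &
                  !is.na(results$p) & results$p < p2 &
                  results$chrom == results$chrom[i] &
                  abs(results$pos - results$pos[i]) <= kb * 1000)
    members <- character()
    for (j in near) {
      r2ij <- ld_r2(geno, results$snp_id[i], results$snp_id[j])
      if (!is.na(r2ij) && r2ij >= r2) {
        assigned[j] <- TRUE
        members <- c(members, results$snp_id[j])
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      index_snp = results$snp_id[i], chrom = results$chrom[i],
      pos = results$pos[i], index_p = results$p[i],
      n_members = length(members), stringsAsFactors = FALSE
    )
    out[[length(out)]]$members <- list(members)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(index_snp = character(), chrom = character(),
               pos = integer(), index_p = numeric(),
               n_members = integer(), members = I(list()),
               stringsAsFactors = FALSE)
  res <- res[order(res$index_p, res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("clump_result", "data.frame")
  res
}

#' Genetic relatedness matrix from standardized dosages
#'
#' `GRM = (1/M) * sum_j z_j z_j'` with `z_j = (d_j - 2 p_j) / sqrt(2 p_j
#' (1 - p_j))` over the `M` polymorphic SNPs; missing dosages are imputed at
#' the SNP mean (zero after standardization) for the cross-products.
#'
#' @param geno a `geno_matrix` with at least 2 subjects.
#' @return a `grm` object: list with `matrix` (subjects x subjects),
#'   `subject_ids`, `sparse = FALSE`.
#' @export
compute_grm <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"), nrow(geno$dosages) >= 2)
  D <- geno$dosages
  storage.mode(D) <- "double"
  n_obs <- colSums(!is.na(D))
  p <- colSums(D, na.rm = TRUE) / (2 * n_obs)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic SNPs")
  D <- D[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(D, 2, 2 * p, "-")
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  Z[is.na(Z)] <- 0
  K <- tcrossprod(Z) / ncol(Z)
  structure(list(matrix = K, subject_ids = geno$subject_ids,
                 sparse = FALSE), class = "grm")
}

#' Sparsify a GRM
#'
#' Zeroes off-diagonal relatedness entries below `cutoff` (the sparse-GRM
#' construction used before relatedness pruning).
#'
#' @param grm a `grm`.
#' @param cutoff relatedness threshold (default 0.05).
#' @return the sparsified `grm` (`sparse = TRUE`).
#' @export
sparsify_grm <- function(grm, cutoff = 0.05) {
  stopifnot(inherits(grm, "grm"))
  K <- grm$matrix
  off <- K
  diag(off) <- 0
  off[abs(off) < cutoff] <- 0
  diag(off) <- diag(K)
  grm$matrix <- off
  grm$sparse <- TRUE
  grm
}

#' Iterative relatedness pruning
#'
#' Repeatedly removes any subject with more than `max_relatives` nonzero
#' off-diagonal entries in the sparse GRM until none remain (subjects with
#' diffuse relatedness to many others, e.g. mixed genetic background).
#'
#' @param grm_sparse a sparsified `grm`.
#' @param max_relatives maximum allowed nonzero off-diagonal entries
#'   (default 100).
#' @return character vector of removed subject ids (possibly empty).
#' @export
prune_related <- function(grm_sparse, max_relatives = 100) {
  stopifnot(inherits(grm_sparse, "grm"))
  K <- grm_sparse$matrix
  ids <- grm_sparse$subject_ids
  removed <- character()
  repeat {
    deg <- rowSums(K != 0) - 1L   # excl. diagonal
    bad <- which(deg > max_relatives)
    if (!length(bad)) break
    worst <- bad[which.max(deg[bad])]
    removed <- c(removed, ids[worst])
    K <- K[-worst, -worst, drop = FALSE]
    ids <- ids[-worst]
  }
  removed
}
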