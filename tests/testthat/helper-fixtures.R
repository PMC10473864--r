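# Shared fixtures and independent brute-force oracles.

# hand-built genotype panel for LD / clumping tests
make_geno <- function(dosages, chrom = NULL, pos = NULL, snp_ids = NULL) {
  m <- ncol(dosages)
  if (is.null(snp_ids)) snp_ids <- sprintf("s%03d", seq_len(m))
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  dimnames(dosages) <- list(NULL, snp_ids)
  n_obs <- colSums(!is.na(dosages))
  af <- colSums(dosages, na.rm = TRUE) / (2 * n_obs)
  structure(
    list(dosages = dosages,
         snp_info = data.frame(snp_id = snp_ids, chrom = chrom,
                               pos = as.integer(pos), ref = "A", alt = "G",
                               maf = pmin(af, 1 - af),
                               stringsAsFactors = FALSE),
         subject_ids = sprintf("subj%04d", seq_len(nrow(dosages)))),
    class = "geno_matrix"
  )
}

# independent greedy-clumping oracle: re-scans every pair each round with
# set arithmetic, no shared code with clump()
oracle_clump <- function(results, geno, p1 = 5e-8, p2 = p1, r2 = 0.5,
                         kb = 250) {
  m <- nrow(results)
  r2mat <- matrix(NA_real_, m, m)
  for (i in seq_len(m)) for (j in seq_len(m))
    r2mat[i, j] <- suppressWarnings(
      ld_r2(geno, results$snp_id[i], results$snp_id[j]))
  remaining <- seq_len(m)
  indices <- integer()
  membership <- list()
  repeat {
    cand <- remaining[!is.na(results$p[remaining]) &
                        results$p[remaining] < p1]
    if (!length(cand)) break
    o <- order(results$p[cand], results$chrom[cand], results$pos[cand])
    idx <- cand[o[1]]
    remaining <- setdiff(remaining, idx)
    mem <- integer()
    for (j in remaining) {
      if (is.na(results$p[j]) || results$p[j] >= p2) next
      if (results$chrom[j] != results$chrom[idx]) next
      if (abs(results$pos[j] - results$pos[idx]) > kb * 1000) next
      if (is.na(r2mat[idx, j]) || r2mat[idx, j] < r2) next
      mem <- c(mem, j)
    }
    remaining <- setdiff(remaining, mem)
    indices <- c(indices, idx)
    membership[[length(membership) + 1]] <- results$snp_id[mem]
  }
  ord <- order(results$p[indices], results$chrom[indices],
               results$pos[indices])
  list(index_snp = results$snp_id[indices][ord],
       members = membership[ord])
}

# brute-force hypergeometric upper tail by enumeration over overlaps
oracle_hyper_tail <- function(k, n_universe, n_set, n_focal) {
  ks <- max(0, n_focal + n_set - n_universe):min(n_set, n_focal)
  pr <- choose(n_set, ks) * choose(n_universe - n_set, n_focal - ks) /
    choose(n_universe, n_focal)
  sum(pr[ks >= k])
}

# brute-force one-sided binomial tail by direct summation
oracle_binom_tail <- function(k, n, p) {
  ks <- 0:n
  sum(choose(n, ks) * p^ks * (1 - p)^(n - ks) * (ks >= k))
}

# brute-force signed-rank tail by enumerating all 2^n sign assignments
oracle_signed_rank_tail <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  v_all <- apply(signs, 1, function(s) sum(r[unlist(s)]))
  mean(v_all >= v_obs - 1e-9)
}
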