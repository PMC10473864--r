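test_that("genotype QC applies the MAF, HWE and missingness rules", {
  # dosages [0,1,2,2]: alt frequency 5/8, MAF 0.375
  g <- make_geno(cbind(c(0, 1, 2, 2)))
  q <- qc_genotypes(g, maf_min = 0.01, hwe_p_min = 0)
  expect_equal(q$snp_info$maf, 0.375)
  expect_equal(ncol(q$dosages), 1)

  # perfect HWE proportions: chi-square 0, P = 1
  d_hwe <- c(rep(0, 25), rep(1, 50), rep(2, 25))
  # chi-square 4: P = 0.0455, retained at 1e-6 but dropped at 0.05
  d_dev <- c(rep(0, 30), rep(1, 40), rep(2, 30))
  g2 <- make_geno(cbind(d_hwe, d_dev))
  expect_equal(ncol(qc_genotypes(g2)$dosages), 2)
  q2 <- qc_genotypes(g2, hwe_p_min = 0.05)
  expect_equal(q2$snp_info$snp_id, "s001")

  # missing rate filter
  d_miss <- c(rep(NA, 10), rep(c(0, 1, 2), length.out = 90))
  g3 <- make_geno(cbind(d_miss, rep(c(0, 1, 2), length.out = 100)))
  expect_equal(ncol(qc_genotypes(g3, miss_max = 0.05)$dosages), 1)

  # idempotence
  cfg <- sim_config(n_subjects = 400, n_snps = 200, maf_range = c(0.02, 0.5),
                    missing_rate = 0.03, seed = 77)
  gg <- sim_genotypes(cfg)
  once <- qc_genotypes(gg)
  twice <- qc_genotypes(once)
  expect_identical(once$dosages, twice$dosages)

  expect_warning(qc_genotypes(make_geno(cbind(rep(0, 50))), maf_min = 0.01),
                 "no SNP")
})

test_that("residualization produces least-squares residuals orthogonal to
           the design", {
  cov <- sim_covariates(500, seed = 3)
  # y equal to a covariate column -> residuals 0
  expect_lt(max(abs(residualize(cov$PC3, cov))), 1e-10)
  set.seed(4)
  y <- rnorm(500)
  r <- residualize(y, cov)
  expect_lt(abs(sum(r * cov$PC1)), 1e-8)
  expect_lt(abs(sum(r * cov$sex)), 1e-8)
  expect_lt(abs(sum(r)), 1e-8)
  # independent y at large n keeps its variance
  expect_lt(abs(var(r) / var(y) - 1), 0.1)
  # missing y propagates
  y[c(5, 10)] <- NA
  expect_true(all(is.na(residualize(y, cov)[c(5, 10)])))
  # collinear design is named
  cov2 <- cov
  cov2$PC2 <- cov2$PC1
  expect_error(residualize(y, cov2), "PC2")
})

test_that("association scan matches hand OLS and flags monomorphic SNPs", {
  g <- make_geno(cbind(a = c(0, 1, 2, 0, 1, 2), b = c(0, 1, 2, 1, 0, 1),
                       mono = rep(1, 6)))
  sc <- assoc_scan(c(0, 1, 2, 0, 1, 2), g)
  expect_equal(sc$beta[1], 1)
  expect_lt(sc$se[1], 1e-7)
  expect_true(is.na(sc$p[3]))

  g2 <- make_geno(cbind(c(0, 1, 2, 1)))
  sc2 <- assoc_scan(c(1, 2, 3, 1), g2)
  expect_equal(sc2$beta[1], 1.0)  # cov/var = 2/2

  # agrees with lm() under missing dosages
  cfg <- sim_config(n_subjects = 300, n_snps = 30, missing_rate = 0.05,
                    seed = 15)
  gm <- sim_genotypes(cfg)
  set.seed(16)
  y <- rnorm(300)
  scm <- assoc_scan(y, gm)
  for (j in c(1, 7, 20)) {
    fit <- summary(lm(y ~ gm$dosages[, j]))$coefficients
    expect_equal(scm$beta[j], fit[2, 1], tolerance = 1e-10)
    expect_equal(scm$se[j], fit[2, 2], tolerance = 1e-10)
    expect_equal(scm$p[j], fit[2, 4], tolerance = 1e-10)
  }
})

test_that("type-I error of the scan is calibrated on a null cohort", {
  cfg <- sim_config(n_subjects = 1000, n_snps = 10000, seed = 23)
  g <- sim_genotypes(cfg)
  set.seed(24)
  y <- rnorm(1000)
  sc <- assoc_scan(y, g)
  expect_lt(abs(mean(sc$p < 0.05) - 0.05), 0.01)
})

test_that("inflation factor is 1 at the null median and responds to
           enrichment", {
  expect_equal(inflation_factor(rep(0.5, 11)), 1.0)
  set.seed(2)
  p <- runif(1e5)
  expect_lt(abs(inflation_factor(p) - 1), 0.02)
  expect_gt(inflation_factor(p / 2), 1)
})

test_that("dosage r-squared matches the squared Pearson correlation", {
  g <- make_geno(cbind(a = c(0, 1, 2, 0), b = c(0, 1, 2, 0),
                       c = c(2, 1, 0, 2), d = c(1, 1, 1, 2)))
  expect_equal(ld_r2(g, "s001", "s002"), 1)
  expect_equal(ld_r2(g, "s001", "s003"), 1)  # g_c = 2 - g_a
  expect_equal(ld_r2(g, "s001", "s004"), 0.2727273, tolerance = 1e-6)
  g_mono <- make_geno(cbind(c(0, 1, 2), c(1, 1, 1)))
  expect_true(is.na(ld_r2(g_mono, "s001", "s002")))
})

test_that("greedy clumping follows the hand trace and the threshold rule", {
  # s1 strongest; s2 in LD and within radius -> member of s1;
  # s3 independent and far -> its own index
  set.seed(9)
  base <- rbinom(60, 2, 0.4)
  noise <- rbinom(60, 2, 0.4)
  g <- make_geno(cbind(s1 = base, s2 = base, s3 = noise),
                 pos = c(100L, 150000L, 400000L),
                 snp_ids = c("s1", "s2", "s3"))
  res <- data.frame(snp_id = c("s1", "s2", "s3"), chrom = "chr1",
                    pos = c(100L, 150000L, 400000L),
                    p = c(1e-10, 1e-9, 0.9e-8), stringsAsFactors = FALSE)
  cl <- clump(res, g)
  expect_equal(cl$index_snp, c("s1", "s3"))
  expect_equal(cl$members[[1]], "s2")
  expect_equal(cl$n_members, c(1, 0))

  res$p <- c(0.5, 0.5, 0.5)
  expect_equal(nrow(clump(res, g)), 0)
})

test_that("clumping equals the brute-force oracle on random instances", {
  set.seed(100)
  for (rep_i in 1:25) {
    m <- sample(5:50, 1)
    cfg <- sim_config(n_subjects = 120, n_snps = m,
                      ld_block_size = sample(c(1, 3, 5), 1),
                      ld_decay = runif(1, 0.5, 0.95),
                      seed = 1000 + rep_i)
    g <- sim_genotypes(cfg)
    res <- data.frame(snp_id = g$snp_info$snp_id, chrom = g$snp_info$chrom,
                      pos = g$snp_info$pos,
                      p = 10^runif(m, -12, -2), stringsAsFactors = FALSE)
    got <- clump(res, g, p1 = 1e-4, p2 = 1e-3, r2 = 0.5, kb = 250)
    want <- oracle_clump(res, g, p1 = 1e-4, p2 = 1e-3, r2 = 0.5, kb = 250)
    expect_equal(got$index_snp, want$index_snp)
    expect_equal(unname(got$members), unname(want$members))
  }
})

test_that("GRM standardization, sparsification and pruning follow the
           rules", {
  g <- make_geno(cbind(c(0, 2)))
  K <- compute_grm(g)$matrix
  expect_equal(K, matrix(c(2, -2, -2, 2), 2), ignore_attr = TRUE)

  # duplicated subjects look nearly self-related
  cfg <- sim_config(n_subjects = 40, n_snps = 2000, ld_block_size = 1,
                    seed = 55)
  gg <- sim_genotypes(cfg)
  gg$dosages[2, ] <- gg$dosages[1, ]
  grm <- compute_grm(gg)
  expect_lt(abs(grm$matrix[1, 2] - grm$matrix[1, 1]), 0.05)

  # pruning removes the hub subject
  K2 <- diag(150)
  K2[1, 2:120] <- K2[2:120, 1] <- 0.1   # subject 1 has 119 relatives
  grm2 <- structure(list(matrix = K2,
                         subject_ids = sprintf("id%03d", 1:150),
                         sparse = TRUE), class = "grm")
  expect_equal(prune_related(grm2, max_relatives = 100), "id001")
  expect_equal(prune_related(grm2, max_relatives = 150), character())

  sp <- sparsify_grm(grm, cutoff = 0.05)
  off <- sp$matrix; diag(off) <- 0
  expect_true(all(off[off != 0] >= 0.05 | off[off != 0] <= -0.05))
  expect_equal(diag(sp$matrix), diag(grm$matrix))
})
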