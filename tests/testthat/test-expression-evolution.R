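# hand-built long expression table: one species/stage, explicit organ means
tensor_row <- function(species, organ, gene, values, stage = "s13") {
  data.frame(species = species, organ = organ, stage = stage, gene = gene,
             replicate = seq_along(values), value = values,
             stringsAsFactors = FALSE)
}

test_that("BSI equals the log2 brain-over-others ratio on anchor cases", {
  t1 <- rbind(tensor_row("human", "brain", "g1", 8),
              tensor_row("human", "heart", "g1", 2),
              tensor_row("human", "liver", "g1", 2))
  expect_equal(compute_bsi(t1, "g1", "human", "s13")$bsi, 2)

  t2 <- rbind(tensor_row("human", "brain", "g1", 2),
              tensor_row("human", "heart", "g1", 2),
              tensor_row("human", "liver", "g1", 2))
  expect_equal(compute_bsi(t2, "g1", "human", "s13")$bsi, 0)

  t3 <- rbind(tensor_row("human", "brain", "g1", 5),
              tensor_row("human", "heart", "g1", 1.5),
              tensor_row("human", "liver", "g1", 3),
              tensor_row("human", "testis", "g1", 4))
  r3 <- compute_bsi(t3, "g1", "human", "s13")
  expect_equal(r3$bsi, 0.8194278, tolerance = 1e-6)
  expect_setequal(r3$organs_used, c("brain", "heart", "liver", "testis"))

  # replicate averaging precedes the ratio
  t4 <- rbind(tensor_row("human", "brain", "g1", c(6, 10)),
              tensor_row("human", "heart", "g1", c(1, 3)))
  expect_equal(compute_bsi(t4, "g1", "human", "s13")$bsi, 2)

  # organs below the expression floor are excluded from the denominator
  r5 <- compute_bsi(rbind(t3, tensor_row("human", "kidney", "g1", 0.5)),
                    "g1", "human", "s13", rpkm_min = 1)
  expect_equal(r5$bsi, r3$bsi)
  # missing brain cell yields a missing record with a reason
  t6 <- tensor_row("human", "heart", "g1", 2)
  expect_true(is.na(compute_bsi(t6, "g1", "human", "s13")$bsi))
})

test_that("BSI is shift-equivariant in brain and invariant to global
           scaling", {
  set.seed(17)
  tens <- sim_species_expression(species = "human", n_genes = 40, seed = 17)
  g <- "g000007"
  b0 <- compute_bsi(tens, g, "human", "stage13", rpkm_min = 0)$bsi
  tens2 <- tens
  tens2$value[tens2$organ == "brain"] <- 2 * tens2$value[tens2$organ == "brain"]
  expect_equal(compute_bsi(tens2, g, "human", "stage13", rpkm_min = 0)$bsi,
               b0 + 1, tolerance = 1e-12)
  tens3 <- tens
  tens3$value <- tens3$value * 3.14
  expect_equal(compute_bsi(tens3, g, "human", "stage13", rpkm_min = 0)$bsi,
               b0, tolerance = 1e-12)
  # dropping a non-brain organ equal to the mean of the others is neutral
  tm <- rbind(tensor_row("human", "brain", "g1", 5),
              tensor_row("human", "heart", "g1", 2),
              tensor_row("human", "liver", "g1", 4),
              tensor_row("human", "testis", "g1", 3))  # mean(2,4) = 3
  with_t <- compute_bsi(tm, "g1", "human", "s13", rpkm_min = 0)$bsi
  without_t <- compute_bsi(tm[tm$organ != "testis", ], "g1", "human", "s13",
                           rpkm_min = 0)$bsi
  expect_equal(with_t, without_t, tolerance = 1e-10)
})

test_that("signed-rank test gives exact tie-aware tails and the stated
           conventions", {
  # 10 identical positive differences: P = 2^-10 despite full ties
  expect_equal(wilcoxon_signed_rank(rep(1, 10))$p.value, 2^-10)
  # all differences zero: no evidence, P = 1
  expect_equal(wilcoxon_signed_rank(rep(0, 5))$p.value, 1)
  # matches stats::wilcox.test exact P when there are no ties
  set.seed(23)
  for (i in 1:10) {
    d <- round(rnorm(12), 6)
    got <- wilcoxon_signed_rank(d)$p.value
    want <- wilcox.test(d, alternative = "greater", exact = TRUE)$p.value
    expect_equal(got, want, tolerance = 1e-12)
  }
  # matches brute-force sign enumeration with ties present
  for (i in 1:5) {
    d <- sample(c(-2, -1, 1, 1, 2, 3), 8, replace = TRUE)
    d <- d[d != 0]
    expect_equal(wilcoxon_signed_rank(d)$p.value,
                 oracle_signed_rank_tail(d), tolerance = 1e-12)
  }
  # large-sample approximation stays close to exact at the boundary size
  set.seed(29)
  d <- rnorm(60, 0.2)
  exact <- wilcoxon_signed_rank(d, exact_max_n = 200)$p.value
  approx <- wilcoxon_signed_rank(d, exact_max_n = 10)$p.value
  expect_lt(abs(log(exact) - log(approx)), 0.2)
})

test_that("cross-species BSI test pairs common qualifying organs", {
  mk <- function(sp, brain, heart, liver) {
    rbind(tensor_row(sp, "brain", "g1", brain),
          tensor_row(sp, "heart", "g1", heart),
          tensor_row(sp, "liver", "g1", liver))
  }
  # ten genes with a BSI difference of exactly +1
  rows <- list()
  for (i in 1:10) {
    g <- paste0("g", i)
    rows[[i]] <- rbind(
      within(mk("human", 8, 2, 2), gene <- g),
      within(mk("mouse", 4, 2, 2), gene <- g))
  }
  tens <- do.call(rbind, rows)
  r <- cross_species_bsi_test(tens, paste0("g", 1:10), "human", "mouse",
                              "s13")
  expect_equal(unname(r$diffs), rep(1, 10))
  expect_equal(r$p.value, 2^-10)
  expect_equal(r$n_genes_used, 10)
  # organ qualifying in only one species is excluded in both
  tens2 <- rbind(mk("human", 8, 2, 2),
                 mk("mouse", 4, 0.5, 2))  # mouse heart below floor
  r2 <- cross_species_bsi_test(tens2, "g1", "human", "mouse", "s13",
                               rpkm_min = 1)
  expect_equal(unname(r2$diffs["g1"]), log2(8 / 2) - log2(4 / 2))
  # identical species: all zero differences -> P = 1
  tens3 <- rbind(mk("human", 8, 2, 2), mk("mouse", 8, 2, 2))
  expect_equal(cross_species_bsi_test(tens3, "g1", "human", "mouse",
                                      "s13")$p.value, 1)
})

test_that("threshold sweep runs per threshold and species", {
  tens <- sim_species_expression(n_genes = 120, focal_genes = 120,
                                 human_brain_shift = 1, seed = 33)
  sw <- bsi_threshold_sweep(tens, unique(tens$gene), "stage13")
  expect_equal(nrow(sw), 3 * 5)
  expect_true(all(sw$p.value >= 0 & sw$p.value <= 1))
  expect_equal(nrow(bsi_threshold_sweep(tens, unique(tens$gene), "stage13",
                                        thresholds = numeric())), 0)
})

test_that("hypergeometric DEG enrichment matches enumeration and
           Bonferroni-corrects", {
  universe <- sprintf("u%02d", 1:10)
  sets <- data.frame(tissue = "cortex", direction = "up",
                     gene = universe[1:5], stringsAsFactors = FALSE)
  r <- deg_enrichment(universe[1:2], sets, universe)
  expect_equal(r$p.value, 10 / 45)  # C(5,2)/C(10,2)
  expect_equal(r$p.bonferroni, r$p.value)  # single set
  # zero overlap -> P = 1; focal = set -> minimal P
  r0 <- deg_enrichment(universe[6:7], sets, universe)
  expect_equal(r0$p.value, 1)
  rmin <- deg_enrichment(universe[1:5], sets, universe)
  expect_equal(rmin$p.value, 1 / choose(10, 5))
  # brute-force agreement on random instances with universe <= 20
  set.seed(37)
  for (i in 1:20) {
    N <- sample(8:20, 1)
    uni <- sprintf("x%02d", 1:N)
    K <- sample(2:(N - 1), 1)
    nf <- sample(2:(N - 1), 1)
    st <- data.frame(tissue = "t", direction = "up",
                     gene = sample(uni, K), stringsAsFactors = FALSE)
    focal <- sample(uni, nf)
    k <- length(intersect(focal, st$gene))
    expect_equal(deg_enrichment(focal, st, uni)$p.value,
                 oracle_hyper_tail(k, N, K, nf), tolerance = 1e-12)
  }
  expect_error(deg_enrichment("a", sets, character()), "empty universe")
})

test_that("brain up/down classification applies the Bonferroni t-test
           rule", {
  tm <- rbind(
    up = c(b1 = 5, b2 = 6, b3 = 7, n1 = 1, n2 = 2, n3 = 3),
    flat = c(b1 = 2, b2 = 3, b3 = 4, n1 = 2, n2 = 3, n3 = 4),
    down = c(b1 = 1, b2 = 1.1, b3 = 0.9, n1 = 9, n2 = 9.1, n3 = 8.9)
  )
  r <- classify_brain_regulation(tm, c("b1", "b2", "b3"), alpha = 0.15)
  expect_equal(r$t[1], 4.898979, tolerance = 1e-6)
  expect_equal(r$p.value[1], 0.0080499, tolerance = 1e-5)
  # threshold is alpha / n_genes = 0.05: gene 1 passes, gene 2 is ns
  expect_equal(r$class, c("up", "ns", "down"))
  # degenerate variance -> ns with warning
  tm2 <- rbind(c(b1 = 1, b2 = 1, n1 = 1, n2 = 1),
               c(b1 = 5, b2 = 6, n1 = 1, n2 = 2))
  expect_warning(r2 <- classify_brain_regulation(tm2, c("b1", "b2")),
                 "zero pooled variance")
  expect_equal(r2$class[1], "ns")
})
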