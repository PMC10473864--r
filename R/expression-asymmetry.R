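# Hemispheric expression asymmetry-level (AL) analysis.
#
# AL = |L - R| / sqrt(2 (L^2 + R^2)) on replicate-mean expression of the
# left and right hemisphere of a brain region: the absolute sine of the
# angular asymmetry index, i.e. the plan-II statistic without the arcsine.

#' Expression asymmetry level of a left/right value pair
#'
#' `|L - R| / sqrt(2 (L^2 + R^2))`; the pair (0, 0) is undefined and gives
#' `NA`. Over nonnegative values the statistic is bounded by `1/sqrt(2)`;
#' over arbitrary real pairs its supremum is 1, attained at `L = -R`.
#'
#' @param left,right numeric vectors.
#' @return numeric vector of asymmetry levels.
#' @export
asym_level <- function(left, right) {
  stopifnot(length(left) == length(right))
  denom <- sqrt(2 * (left^2 + right^2))
  out <- abs(left - right) / denom
  out[!is.na(denom) & denom == 0] <- NA_real_
  out
}

#' Asymmetry level of one gene in one region from hemisphere replicates
#'
#' Replicates are averaged per hemisphere after dropping missing values;
#' values at or below `floor` (on whatever relative scale the caller has
#' normalized to, see [donor_al()]) are treated as missing. If either
#' hemisphere mean is missing — or both are zero — the AL is missing.
#'
#' @param left_reps,right_reps replicate expression values per hemisphere.
#' @param floor low-expression mask threshold (default 1e-7).
#' @return a single asymmetry level or `NA`.
#' @export
region_al <- function(left_reps, right_reps, floor = 1e-7) {
  m <- function(v) {
    v <- v[!is.na(v)]
    v <- v[v >= floor]
    if (!length(v)) NA_real_ else mean(v)
  }
  L <- m(left_reps)
  R <- m(right_reps)
  if (is.na(L) || is.na(R)) return(NA_real_)
  asym_level(L, R)
}

#' Per-gene, per-region asymmetry levels for one donor
#'
#' Normalizes expression to relative abundance (each sample's values
#' divided by the sample total over genes, where a sample is one
#' donor x region x hemisphere x replicate), masks relative values below
#' `floor` as missing, averages replicates per hemisphere, and computes the
#' AL per gene and region.
#'
#' @param donor_table data frame (donor, region, hemisphere, gene,
#'   replicate, value) for one donor (multiple donors allowed; kept apart).
#' @param floor relative-abundance mask threshold (default 1e-7).
#' @return data frame (donor, region, gene, al).
#' @export
donor_al <- function(donor_table, floor = 1e-7) {
  d <- donor_table
  stopifnot(all(c("donor", "region", "hemisphere", "gene", "replicate",
                  "value") %in% names(d)))
  sample_id <- paste(d$donor, d$region, d$hemisphere, d$replicate)
  totals <- tapply(d$value, sample_id, sum, na.rm = TRUE)
  rel <- d$value / as.numeric(totals[sample_id])
  rel[!is.na(rel) & rel < floor] <- NA_real_

  key <- paste(d$donor, d$region, d$gene)
  left_mean <- tapply(ifelse(d$hemisphere == "left", rel, NA), key,
                      mean, na.rm = TRUE)
  right_mean <- tapply(ifelse(d$hemisphere == "right", rel, NA), key,
                       mean, na.rm = TRUE)
  keys <- do.call(rbind, strsplit(names(left_mean), " "))
  L <- as.numeric(left_mean)
  R <- as.numeric(right_mean[names(left_mean)])
  L[is.nan(L)] <- NA; R[is.nan(R)] <- NA
  data.frame(donor = keys[, 1], region = keys[, 2], gene = keys[, 3],
             al = asym_level(L, R), stringsAsFactors = FALSE)
}

#' Group test of asymmetry level: focal genes versus the rest
#'
#' One-sided rank-sum test of whether the focal genes' ALs are larger than
#' the other genes'. With `scope = "overall"` all (gene, region) ALs are
#' pooled into one test; with `scope = "per_region"` one test per region is
#' run and Benjamini-Hochberg adjusted across regions.
#'
#' @param al_table data frame (region, gene, al) as from [donor_al()].
#' @param focal focal gene ids.
#' @param scope `"overall"` or `"per_region"`.
#' @return for `"overall"`, a single P value; for `"per_region"`, a data
#'   frame (region, p.value, p.bh).
#' @export
al_group_test <- function(al_table, focal, scope = c("overall",
                                                     "per_region")) {
  scope <- match.arg(scope)
  is_focal <- al_table$gene %in% focal
  if (scope == "overall") {
    return(rank_sum_greater(al_table$al[is_focal], al_table$al[!is_focal]))
  }
  regions <- unique(al_table$region)
  pv <- vapply(regions, function(rg) {
    sel <- al_table$region == rg
    rank_sum_greater(al_table$al[sel & is_focal],
                     al_table$al[sel & !is_focal])
  }, numeric(1))
  data.frame(region = regions, p.value = pv,
             p.bh = p.adjust(pv, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Average asymmetry levels across two donors
#'
#' Restricts both donors to their shared regions, reports the Pearson
#' correlation between donors over the stacked (gene, region) AL pairs with
#' both values present, and returns per-gene ALs averaged over shared
#' regions within each donor and then across donors (falling back to the
#' present donor when one side is missing, unless `strict_both`).
#'
#' @param al_donor1,al_donor2 data frames (region, gene, al).
#' @param strict_both if `TRUE`, a gene's average is missing unless both
#'   donors contribute (default `FALSE`).
#' @return list with `shared_regions`, `correlation`, `cor_p` (two-sided),
#'   `n_pairs`, and `averaged` (data frame gene, al).
#' @export
donor_average <- function(al_donor1, al_donor2, strict_both = FALSE) {
  shared <- intersect(unique(al_donor1$region), unique(al_donor2$region))
  if (!length(shared)) stop("donors share no region")
  d1 <- al_donor1[al_donor1$region %in% shared, ]
  d2 <- al_donor2[al_donor2$region %in% shared, ]
  key1 <- paste(d1$region, d1$gene)
  key2 <- paste(d2$region, d2$gene)
  common <- intersect(key1, key2)
  x <- d1$al[match(common, key1)]
  y <- d2$al[match(common, key2)]
  ok <- !is.na(x) & !is.na(y)
  r <- if (sum(ok) >= 3) cor(x[ok], y[ok]) else NA_real_
  cor_p <- if (!is.na(r) && abs(r) < 1) {
    n <- sum(ok)
    2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
  } else NA_real_

  per_gene <- function(d) tapply(d$al, d$gene, mean, na.rm = TRUE)
  g1 <- per_gene(d1)
  g2 <- per_gene(d2)
  genes <- union(names(g1), names(g2))
  a1 <- as.numeric(g1[genes]); a2 <- as.numeric(g2[genes])
  a1[is.nan(a1)] <- NA; a2[is.nan(a2)] <- NA
  avg <- rowMeans(cbind(a1, a2), na.rm = !strict_both)
  avg[is.nan(avg)] <- NA
  list(shared_regions = shared, correlation = r, cor_p = cor_p,
       n_pairs = sum(ok),
       averaged = data.frame(gene = genes, al = avg,
                             stringsAsFactors = FALSE))
}
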