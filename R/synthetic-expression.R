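#' Simulate a cross-species organ x stage expression tensor
#'
#' Log-normal expression with shared gene- and organ-level effects: on the
#' log2 scale each replicate value is
#' `gene effect + organ effect + cell noise + replicate noise`, identically
#' distributed across species, except that focal genes have their human
#' brain expression multiplied by `2^human_brain_shift`. Missing
#' species x organ x stage cells can be declared explicitly (emulating
#' unprofiled stages) or drawn at a given rate.
#'
#' @param species,organs,stages axis labels; `"brain"` must be among
#'   `organs` and `"human"` among `species` when `human_brain_shift != 0`.
#' @param n_genes number of genes (`g000001`...).
#' @param focal_genes gene ids receiving the human-brain shift (defaults to
#'   none); may be a subset of the gene ids or an integer count, in which
#'   case the first `focal_genes` genes are focal.
#' @param human_brain_shift log2-scale upregulation of focal genes in the
#'   human brain.
#' @param replicates biological replicates per cell.
#' @param missing_cells optional data frame (species, organ, stage) of cells
#'   to drop, or a single numeric rate of randomly missing cells.
#' @param base_log2 mean log2 expression (default 3, i.e. ~8 RPKM).
#' @param gene_sd,organ_sd,cell_sd,rep_sd SDs of the log2-scale effects.
#' @param seed integer seed.
#' @return long-format data frame of class `expr_tensor` with columns
#'   species, organ, stage, gene, replicate, value; attribute
#'   `focal_genes` records the planted set.
#' @export
sim_species_expression <- function(species = c("human", "macaque", "mouse",
                                               "rat", "rabbit", "opossum"),
                                   organs = c("brain", "heart", "liver",
                                              "testis"),
                                   stages = "stage13",
                                   n_genes = 500, focal_genes = n_genes,
                                   human_brain_shift = 0, replicates = 2,
                                   missing_cells = NULL,
                                   base_log2 = 3, gene_sd = 1,
                                   organ_sd = 0.5, cell_sd = 0.3,
                                   rep_sd = 0.25, seed = 1) {
  stopifnot(is.finite(human_brain_shift), "brain" %in% organs)
  set.seed(seed)
  genes <- sprintf("g%06d", seq_len(n_genes))
  if (is.numeric(focal_genes) && length(focal_genes) == 1L)
    focal_genes <- genes[seq_len(min(focal_genes, n_genes))]
  g_eff <- setNames(rnorm(n_genes, base_log2, gene_sd), genes)
  o_eff <- setNames(rnorm(length(organs), 0, organ_sd), organs)

  grid <- expand.grid(species = species, organ = organs, stage = stages,
                      stringsAsFactors = FALSE)
  if (is.numeric(missing_cells) && length(missing_cells) == 1L) {
    drop <- runif(nrow(grid)) < missing_cells
    grid <- grid[!drop, , drop = FALSE]
  } else if (is.data.frame(missing_cells) && nrow(missing_cells)) {
    key <- function(d) paste(d$species, d$organ, d$stage)
    grid <- grid[!key(grid) %in% key(missing_cells), , drop = FALSE]
  }

  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ce <- rnorm(n_genes, 0, cell_sd)           # cell-level gene noise
    mu <- g_eff + o_eff[grid$organ[i]] + ce
    if (grid$species[i] == "human" && grid$organ[i] == "brain")
      mu[genes %in% focal_genes] <- mu[genes %in% focal_genes] +
        human_brain_shift
    vals <- matrix(rnorm(n_genes * replicates, rep(mu, replicates), rep_sd),
                   nrow = n_genes)
    out[[i]] <- data.frame(
      species = grid$species[i], organ = grid$organ[i],
      stage = grid$stage[i],
      gene = rep(genes, replicates),
      replicate = rep(seq_len(replicates), each = n_genes),
      value = 2^as.numeric(vals),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  attr(res, "focal_genes") <- focal_genes
  class(res) <- c("expr_tensor", "data.frame")
  res
}

#' Simulate donor region x hemisphere expression tables
#'
#' Paired left/right expression per gene and brain region, with replicates.
#' Non-focal genes have symmetric expression up to replicate noise; focal
#' genes receive an additional multiplicative left-right perturbation: a
#' per-gene-per-region log2 offset drawn from `N(0, asym_shift^2)` applied
#' with opposite sign to the two hemispheres.
#'
#' @param donors donor labels.
#' @param regions region labels.
#' @param n_genes number of genes.
#' @param focal_genes focal ids or an integer count (first genes).
#' @param asym_shift SD (log2 scale) of the planted hemispheric perturbation
#'   for focal genes; 0 plants nothing.
#' @param replicates replicates per hemisphere sample.
#' @param base_log2,gene_sd,region_sd,rep_sd log2-scale effect SDs.
#' @param seed integer seed.
#' @return data frame (donor, region, hemisphere, gene, replicate, value)
#'   with attribute `focal_genes`.
#' @export
sim_region_expression <- function(donors = c("donor1", "donor2"),
                                  regions = paste0("region", 1:10),
                                  n_genes = 400, focal_genes = 50,
                                  asym_shift = 0, replicates = 2,
                                  base_log2 = 3, gene_sd = 1,
                                  region_sd = 0.4, rep_sd = 0.3, seed = 1) {
  stopifnot(asym_shift >= 0)
  set.seed(seed)
  genes <- sprintf("g%06d", seq_len(n_genes))
  if (is.numeric(focal_genes) && length(focal_genes) == 1L)
    focal_genes <- genes[seq_len(min(focal_genes, n_genes))]
  g_eff <- setNames(rnorm(n_genes, base_log2, gene_sd), genes)
  out <- list()
  k <- 0L
  for (d in donors) {
    for (rg in regions) {
      r_eff <- rnorm(1, 0, region_sd)
      delta <- numeric(n_genes)
      if (asym_shift > 0)
        delta[genes %in% focal_genes] <-
          rnorm(sum(genes %in% focal_genes), 0, asym_shift)
      for (h in c("left", "right")) {
        sgn <- if (h == "left") 0.5 else -0.5
        mu <- g_eff + r_eff + sgn * delta
        vals <- matrix(rnorm(n_genes * replicates,
                             rep(mu, replicates), rep_sd),
                       nrow = n_genes)
        k <- k + 1L
        out[[k]] <- data.frame(
          donor = d, region = rg, hemisphere = h,
          gene = rep(genes, replicates),
          replicate = rep(seq_len(replicates), each = n_genes),
          value = 2^as.numeric(vals),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- do.call(rbind, out)
  attr(res, "focal_genes") <- focal_genes
  class(res) <- c("expr_tensor", "data.frame")
  res
}
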