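# Cross-species Brain Specificity Index analysis.
#
# BSI = log2( brain expression / mean over other organs ), computed from
# replicate means of an RPKM-like expression table; organs enter the
# denominator only if present and above an expression floor.

# replicate means for one (species, stage): named vector organ -> mean
organ_means <- function(tensor, gene, species, stage) {
  d <- tensor[tensor$gene == gene & tensor$species == species &
                tensor$stage == stage, , drop = FALSE]
  if (!nrow(d)) return(setNames(numeric(), character()))
  tapply(d$value, d$organ, mean, na.rm = TRUE)
}

# organ x gene matrix of replicate means for one (species, stage);
# organs absent from the table are simply absent rows (missing cells)
species_mean_matrix <- function(tensor, species, stage, genes) {
  d <- tensor[tensor$species == species & tensor$stage == stage &
                tensor$gene %in% genes, , drop = FALSE]
  if (!nrow(d))
    return(matrix(numeric(), 0, length(genes),
                  dimnames = list(character(), genes)))
  tapply(d$value, list(factor(d$organ), factor(d$gene, levels = genes)),
         mean, na.rm = TRUE)
}

#' Brain Specificity Index of one gene
#'
#' `BSI = log2(mean brain expression / mean over the included non-brain
#' organs of their replicate means)`. A non-brain organ is included only if
#' it is profiled (non-missing) and its replicate mean exceeds `rpkm_min`;
#' the record is missing when the brain cell is absent or no non-brain
#' organ qualifies.
#'
#' @param tensor an expression table (species, organ, stage, gene,
#'   replicate, value), e.g. from [sim_species_expression()].
#' @param gene,species,stage which cell to evaluate.
#' @param rpkm_min expression floor for including a non-brain organ
#'   (default 1).
#' @param organs optional restriction of the organs considered.
#' @return list of class `bsi_record`: gene, species, stage, organs_used,
#'   bsi (`NA` with a `reason` when not computable).
#' @export
compute_bsi <- function(tensor, gene, species, stage, rpkm_min = 1,
                        organs = NULL) {
  m <- organ_means(tensor, gene, species, stage)
  if (!is.null(organs)) m <- m[names(m) %in% organs]
  rec <- list(gene = gene, species = species, stage = stage,
              organs_used = character(), bsi = NA_real_, reason = NULL)
  class(rec) <- "bsi_record"
  if (!"brain" %in% names(m) || is.na(m[["brain"]])) {
    rec$reason <- "brain cell missing"
    return(rec)
  }
  others <- m[setdiff(names(m), "brain")]
  others <- others[!is.na(others) & others > rpkm_min]
  if (!length(others)) {
    rec$reason <- "no non-brain organ above threshold"
    return(rec)
  }
  rec$organs_used <- c("brain", names(others))
  rec$bsi <- log2(m[["brain"]] / mean(others))
  rec
}

#' @export
print.bsi_record <- function(x, ...) {
  if (is.na(x$bsi)) {
    cat("BSI(", x$gene, ", ", x$species, ", ", x$stage, "): missing (",
        x$reason, ")\n", sep = "")
  } else {
    cat("BSI(", x$gene, ", ", x$species, ", ", x$stage, ") = ",
        round(x$bsi, 4), " over ", paste(x$organs_used, collapse = "/"),
        "\n", sep = "")
  }
  invisible(x)
}

#' Cross-species paired BSI comparison
#'
#' For every gene, the BSI is computed in both species over the organs
#' common to both at the given stage — an organ qualifies only if it is
#' profiled and its replicate mean exceeds `rpkm_min` in *both* species —
#' and the per-gene BSI differences are tested with a one-sided paired
#' Wilcoxon signed-rank test of `species_a` BSI being larger.
#'
#' @param tensor an expression table.
#' @param genes gene ids to use.
#' @param species_a,species_b the species pair (default human vs `species_b`).
#' @param stage developmental stage label.
#' @param rpkm_min expression floor (default 1).
#' @return list with `p.value`, `n_genes_used`, and `diffs` (named per-gene
#'   BSI differences a - b).
#' @export
cross_species_bsi_test <- function(tensor, genes, species_a = "human",
                                   species_b, stage, rpkm_min = 1) {
  Ma <- species_mean_matrix(tensor, species_a, stage, genes)
  Mb <- species_mean_matrix(tensor, species_b, stage, genes)
  common <- intersect(rownames(Ma), rownames(Mb))
  diffs <- rep(NA_real_, length(genes))
  names(diffs) <- genes
  if ("brain" %in% common) {
    Ma <- Ma[common, , drop = FALSE]
    Mb <- Mb[common, , drop = FALSE]
    oth <- setdiff(common, "brain")
    if (length(oth)) {
      ba <- Ma["brain", ]; bb <- Mb["brain", ]
      Oa <- Ma[oth, , drop = FALSE]
      Ob <- Mb[oth, , drop = FALSE]
      ok <- !is.na(Oa) & !is.na(Ob) & Oa > rpkm_min & Ob > rpkm_min
      n_ok <- colSums(ok)
      den_a <- colSums(ifelse(ok, Oa, 0)) / n_ok
      den_b <- colSums(ifelse(ok, Ob, 0)) / n_ok
      d <- log2(ba / den_a) - log2(bb / den_b)
      d[n_ok == 0 | is.na(ba) | is.na(bb)] <- NA_real_
      diffs[colnames(Ma)] <- d
    }
  }
  used <- diffs[!is.na(diffs)]
  if (!length(used)) stop("no usable gene for the species pair")
  w <- wilcoxon_signed_rank(used)
  list(p.value = w$p.value, n_genes_used = length(used), diffs = diffs)
}

#' BSI robustness sweep over expression thresholds
#'
#' Repeats [cross_species_bsi_test()] for each threshold and each non-focal
#' species against `species_a`.
#'
#' @param tensor an expression table.
#' @param genes gene ids.
#' @param stage stage label.
#' @param species_a reference species (default `"human"`).
#' @param species_b species to compare against; defaults to all others in
#'   the tensor.
#' @param thresholds expression floors to sweep (default 0.5, 1, 1.5).
#' @return data frame (threshold, species, p.value, n_genes_used); zero
#'   rows when `thresholds` is empty.
#' @export
bsi_threshold_sweep <- function(tensor, genes, stage, species_a = "human",
                                species_b = NULL,
                                thresholds = c(0.5, 1, 1.5)) {
  if (is.null(species_b))
    species_b <- setdiff(unique(tensor$species), species_a)
  out <- list()
  for (th in thresholds) {
    for (sp in species_b) {
      r <- cross_species_bsi_test(tensor, genes, species_a, sp, stage,
                                  rpkm_min = th)
      out[[length(out) + 1L]] <- data.frame(
        threshold = th, species = sp, p.value = r$p.value,
        n_genes_used = r$n_genes_used, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(threshold = numeric(), species = character(),
               p.value = numeric(), n_genes_used = integer(),
               stringsAsFactors = FALSE)
}

#' Hypergeometric enrichment of a focal set in DEG sets
#'
#' Upper-tail hypergeometric P of the overlap between the focal set and
#' each per-tissue up/down differentially-expressed gene set, with
#' Bonferroni correction across all sets tested.
#'
#' @param focal focal gene ids (subset of `universe`).
#' @param deg_sets data frame (tissue, direction, gene).
#' @param universe character vector of all genes.
#' @return data frame (tissue, direction, set_size, overlap, p.value,
#'   p.bonferroni).
#' @export
deg_enrichment <- function(focal, deg_sets, universe) {
  if (!length(universe)) stop("empty universe")
  stopifnot(all(focal %in% universe), all(deg_sets$gene %in% universe))
  focal <- unique(focal)
  keys <- unique(deg_sets[c("tissue", "direction")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    set <- unique(deg_sets$gene[deg_sets$tissue == keys$tissue[i] &
                                  deg_sets$direction == keys$direction[i]])
    k <- length(intersect(focal, set))
    out[[i]] <- data.frame(
      tissue = keys$tissue[i], direction = keys$direction[i],
      set_size = length(set), overlap = k,
      p.value = hyper_tail(k, length(universe), length(set), length(focal)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$p.bonferroni <- pmin(res$p.value * nrow(res), 1)
  res
}

#' Classify genes as brain up-, down-regulated, or not significant
#'
#' Per gene, a two-sided equal-variance two-sample t-test of its mean
#' expression in brain tissues versus nonbrain tissues; the class is `up`
#' or `down` by the sign of the mean difference when the P value passes the
#' Bonferroni threshold `0.05 / n_genes`, otherwise `ns`. Genes with zero
#' pooled variance are `ns` with a warning.
#'
#' @param tissue_means numeric matrix or data frame, genes x tissues.
#' @param brain_tissues column names counted as brain (>= 2 required, as
#'   are >= 2 nonbrain columns).
#' @param alpha family-wise level before Bonferroni division (default
#'   0.05).
#' @return data frame (gene, t, p.value, class).
#' @export
classify_brain_regulation <- function(tissue_means, brain_tissues,
                                      alpha = 0.05) {
  tissue_means <- as.matrix(tissue_means)
  stopifnot(all(brain_tissues %in% colnames(tissue_means)))
  nb <- setdiff(colnames(tissue_means), brain_tissues)
  if (length(brain_tissues) < 2 || length(nb) < 2)
    stop("need >= 2 brain and >= 2 nonbrain tissues")
  n_genes <- nrow(tissue_means)
  thr <- alpha / n_genes
  out <- data.frame(gene = rownames(tissue_means) %||%
                      as.character(seq_len(n_genes)),
                    t = NA_real_, p.value = NA_real_, class = "ns",
                    stringsAsFactors = FALSE)
  degenerate <- FALSE
  for (i in seq_len(n_genes)) {
    b <- tissue_means[i, brain_tissues]
    o <- tissue_means[i, nb]
    if (var(b) == 0 && var(o) == 0) { degenerate <- TRUE; next }
    tt <- t.test(b, o, var.equal = TRUE)
    out$t[i] <- unname(tt$statistic)
    out$p.value[i] <- tt$p.value
    if (tt$p.value < thr)
      out$class[i] <- if (mean(b) > mean(o)) "up" else "down"
  }
  if (degenerate)
    warning("gene(s) with zero pooled variance classified as ns")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
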