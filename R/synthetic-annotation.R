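#' Simulate gene models around a genotype panel
#'
#' Places gene intervals (0-based half-open, BED convention) so that chosen
#' SNPs fall inside exactly one gene, inside two overlapping genes, or in no
#' gene at all — the three cases the SNP-to-gene assignment policy must
#' distinguish.
#'
#' @param geno a `geno_matrix`.
#' @param n_single,n_double,n_intergenic how many SNPs to place in each
#'   containment class (drawn without replacement from the panel).
#' @param gene_halfwidth half-width of each gene interval in bp.
#' @param seed integer seed.
#' @return list with `genes` (data frame of class `gene_models`: gene_id,
#'   chrom, start, end, strand) and `snp_classes` (snp_id, class).
#' @export
sim_gene_models <- function(geno, n_single = 20, n_double = 5,
                            n_intergenic = 5, gene_halfwidth = 200L,
                            seed = 1) {
  stopifnot(inherits(geno, "geno_matrix"))
  info <- geno$snp_info
  need <- n_single + n_double + n_intergenic
  if (need > nrow(info)) stop("not enough SNPs for the requested classes")
  set.seed(seed)
  pick <- sample(nrow(info), need)
  cls <- rep(c("single", "double", "intergenic"),
             c(n_single, n_double, n_intergenic))
  genes <- list()
  gid <- 0L
  for (i in seq_along(pick)) {
    s <- info[pick[i], ]
    if (cls[i] == "intergenic") next
    n_g <- if (cls[i] == "single") 1L else 2L
    for (g in seq_len(n_g)) {
      gid <- gid + 1L
      # 0-based half-open interval containing the (1-based) SNP position
      genes[[gid]] <- data.frame(
        gene_id = sprintf("gene%04d", gid),
        chrom = s$chrom,
        start = max(0L, s$pos - 1L - gene_halfwidth + (g - 1L) * 37L),
        end = s$pos + gene_halfwidth + (g - 1L) * 37L,
        strand = if (gid %% 2L) "+" else "-",
        stringsAsFactors = FALSE
      )
    }
  }
  genes <- do.call(rbind, genes)
  class(genes) <- c("gene_models", "data.frame")
  list(genes = genes,
       snp_classes = data.frame(snp_id = info$snp_id[pick], class = cls,
                                stringsAsFactors = FALSE))
}

#' Write gene models to a BED file
#'
#' Standard 6-column BED (0-based half-open) via rtracklayer when available,
#' otherwise a plain tab-delimited writer with the same columns.
#'
#' @param genes a `gene_models` data frame.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_gene_bed <- function(genes, file) {
  stopifnot(is.data.frame(genes))
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- GenomicRanges::GRanges(
      seqnames = genes$chrom,
      ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
      strand = genes$strand, name = genes$gene_id, score = 0L
    )
    rtracklayer::export(gr, file, format = "BED")
  } else {
    bed <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id,
                      0L, genes$strand)
    write.table(bed, file, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(file)
}

#' Read gene models from a BED file
#'
#' @param file a BED path (0-based half-open intervals).
#' @return a `gene_models` data frame.
#' @export
read_gene_bed <- function(file) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(file, format = "BED")
    genes <- data.frame(
      gene_id = gr$name,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    )
  } else {
    bed <- read.table(file, sep = "\t", stringsAsFactors = FALSE)
    genes <- data.frame(gene_id = bed[[4]], chrom = bed[[1]],
                        start = bed[[2]], end = bed[[3]],
                        strand = if (ncol(bed) >= 6) bed[[6]] else "*",
                        stringsAsFactors = FALSE)
  }
  class(genes) <- c("gene_models", "data.frame")
  genes
}

#' Simulate a gene-age (clade-of-origin) map with planted enrichment
#'
#' Background genes are assigned to the ordered clades in the stated
#' proportions; a focal gene set is then drawn from the background with the
#' enriched clade's probability multiplied by `fold` and the other clades
#' rescaled proportionally, so the focal set is `fold`-fold enriched in the
#' chosen clade in expectation.
#'
#' @param clades ordered clade labels, most ancient first.
#' @param background_sizes per-clade background gene counts (same length).
#' @param focal_size number of focal genes to draw.
#' @param enriched_clade label(s) of the enriched clade(s).
#' @param fold enrichment multiplier(s), recycled over `enriched_clade`;
#'   the adjusted enriched probabilities must sum to <= 1.
#' @param seed integer seed.
#' @return list with `map` (a [clade_map()]) and `focal` (character vector
#'   of focal gene ids, a subset of the background).
#' @export
sim_clade_map <- function(clades, background_sizes, focal_size,
                          enriched_clade = clades[1], fold = 1, seed = 1) {
  stopifnot(length(clades) == length(background_sizes),
            all(enriched_clade %in% clades))
  fold <- rep_len(fold, length(enriched_clade))
  p_bg <- background_sizes / sum(background_sizes)
  names(p_bg) <- clades
  p_adj <- p_bg
  p_adj[enriched_clade] <- fold * p_bg[enriched_clade]
  if (sum(p_adj[enriched_clade]) > 1)
    stop("fold * background proportion of the enriched clade(s) exceeds 1")
  rest <- setdiff(clades, enriched_clade)
  if (length(rest))
    p_adj[rest] <- p_bg[rest] * (1 - sum(p_adj[enriched_clade])) /
      sum(p_bg[rest])

  set.seed(seed)
  assignment <- rep(clades, background_sizes)
  genes <- sprintf("g%06d", seq_along(assignment))
  names(assignment) <- genes
  by_clade <- split(genes, factor(assignment, levels = clades))
  k <- as.integer(rmultinom(1, focal_size, p_adj))
  if (any(k > lengths(by_clade)))
    stop("focal draw exceeds a clade's background size; enlarge background")
  focal <- unlist(mapply(function(g, ki) sample(g, ki), by_clade, k,
                         SIMPLIFY = FALSE), use.names = FALSE)
  list(map = clade_map(clades, assignment), focal = focal)
}

#' Simulate per-tissue differentially-expressed gene sets
#'
#' Emits one up- and one down-regulated gene set per tissue, drawn from the
#' universe; sets of the `enrich_tissue`/`enrich_direction` combination
#' up-weight the focal genes by `fold`.
#'
#' @param universe character vector of gene ids.
#' @param tissues tissue labels.
#' @param focal focal gene set (subset of `universe`).
#' @param enrich_tissue,enrich_direction which set is enriched for `focal`.
#' @param fold weight multiplier for focal genes in the enriched set.
#' @param set_size genes per set.
#' @param seed integer seed.
#' @return data frame (tissue, direction, gene).
#' @export
sim_deg_sets <- function(universe, tissues, focal = character(),
                         enrich_tissue = tissues[1],
                         enrich_direction = "up", fold = 1,
                         set_size = 100, seed = 1) {
  set.seed(seed)
  out <- list()
  for (ti in tissues) {
    for (dir in c("up", "down")) {
      w <- rep(1, length(universe))
      if (ti == enrich_tissue && dir == enrich_direction && length(focal))
        w[universe %in% focal] <- fold
      g <- sample(universe, min(set_size, length(universe)), prob = w)
      out[[paste(ti, dir)]] <- data.frame(tissue = ti, direction = dir,
                                          gene = g, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
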