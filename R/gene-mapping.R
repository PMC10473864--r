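#' Assign SNPs to genes by interval containment
#'
#' A SNP inside exactly one gene interval is assigned to that gene; a SNP
#' inside two or more genes is dropped (multi-gene ambiguity), as is an
#' intergenic SNP. An optional flank widens every gene interval for
#' sensitivity analyses (default 0: containment only).
#'
#' @param snps data frame with `snp_id`, `chrom`, `pos` (1-based).
#' @param genes a `gene_models` data frame (0-based half-open intervals).
#' @param flank symmetric extension of each gene interval in bp (default 0).
#' @return data frame (snp_id, gene_id) with `NA` gene_id for dropped SNPs;
#'   SNPs on chromosomes absent from the gene set map to `NA` with a
#'   warning.
#' @export
map_snp_to_gene <- function(snps, genes, flank = 0L) {
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snps)),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  missing_chr <- setdiff(unique(snps$chrom), unique(genes$chrom))
  if (length(missing_chr))
    warning("chromosome(s) absent from gene set: ",
            paste(missing_chr, collapse = ", "))
  all_chr <- union(unique(snps$chrom), unique(genes$chrom))
  snp_gr <- GenomicRanges::GRanges(
    seqnames = factor(snps$chrom, levels = all_chr),
    ranges = IRanges::IRanges(start = snps$pos, width = 1)
  )
  gene_gr <- GenomicRanges::GRanges(
    seqnames = factor(genes$chrom, levels = all_chr),
    ranges = IRanges::IRanges(start = genes$start + 1L - flank,
                              end = genes$end + flank)
  )
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  n_hits <- tabulate(qh, nbins = nrow(snps))
  gene_id <- rep(NA_character_, nrow(snps))
  uni <- n_hits == 1L
  gene_id[qh[qh %in% which(uni)]] <- genes$gene_id[sh[qh %in% which(uni)]]
  data.frame(snp_id = snps$snp_id, gene_id = gene_id,
             stringsAsFactors = FALSE)
}

#' Merge two gene-annotation sets
#'
#' Deduplicated union, stably sorted by identifier — the rule used to
#' combine two independent annotation sources with high overlap.
#'
#' @param set_a,set_b character vectors of gene identifiers.
#' @return sorted character vector of the union.
#' @export
merge_annotations <- function(set_a, set_b) {
  sort(unique(c(as.character(set_a), as.character(set_b))))
}
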