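#' Simulation configuration for the synthetic cohort
#'
#' Bundles every knob of the genotype/phenotype generator. Identical
#' configurations (including `seed`) produce byte-identical outputs.
#'
#' The defaults describe the desk-scale study conditions used throughout the
#' package's own analyses: 4,000 discovery subjects, 10,000 biallelic SNPs in
#' LD blocks of 10 SNPs with haplotype-copying probability 0.9, minor allele
#' frequencies uniform on (0.05, 0.5), and unit residual noise on each
#' hemisphere. The replication phases mirror the discovery/replication layout
#' of a two-ancestry, two-time-period cohort: phase 2 is a smaller panel of
#' different ancestry (per-SNP allele-frequency shift on the logit scale),
#' phase 3 a smaller same-ancestry panel measured at a second time period.
#'
#' @param n_subjects discovery-phase subjects.
#' @param n_snps number of biallelic SNPs.
#' @param maf_range interval in (0, 0.5] from which per-block minor allele
#'   frequencies are drawn.
#' @param ld_block_size SNPs per LD block (1 = independent SNPs).
#' @param ld_decay haplotype-copying probability in \[0, 1\]; adjacent-SNP
#'   correlation within a block is approximately `ld_decay`, so r^2 decays
#'   roughly as `ld_decay^(2*distance)`.
#' @param noise_sd residual SD of each hemisphere measurement.
#' @param base_level mean level of the left and right measurements.
#' @param common_sd SD of the subject-level component shared by both sides.
#' @param missing_rate fraction of dosages set missing (VCF `./.`).
#' @param phase_spec named list of phases, each `list(n = <subjects>,
#'   freq_shift_sd = <logit-scale allele-frequency shift SD>)`.
#' @param seed integer seed controlling every random draw.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 4000, n_snps = 10000,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 10, ld_decay = 0.9,
                       noise_sd = 1, base_level = 10, common_sd = 1,
                       missing_rate = 0,
                       phase_spec = list(
                         phase1 = list(n = n_subjects, freq_shift_sd = 0),
                         phase2 = list(n = 1200, freq_shift_sd = 0.3),
                         phase3 = list(n = 1000, freq_shift_sd = 0)
                       ),
                       seed = 1) {
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (n_subjects < 1 || n_snps < 1)
    stop("n_subjects and n_snps must be positive")
  if (ld_decay < 0 || ld_decay > 1) stop("ld_decay must be in [0,1]")
  structure(
    list(n_subjects = n_subjects, n_snps = n_snps, maf_range = maf_range,
         ld_block_size = ld_block_size, ld_decay = ld_decay,
         noise_sd = noise_sd, base_level = base_level, common_sd = common_sd,
         missing_rate = missing_rate, phase_spec = phase_spec,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# SNP panel layout shared by all phases: per-block MAF, chromosome and
# position. Blocks are 1 kb-spaced SNPs separated by 500 kb gaps, split over
# up to 22 chromosomes.
snp_panel <- function(config) {
  m <- config$n_snps
  bs <- config$ld_block_size
  block <- (seq_len(m) - 1L) %/% bs          # 0-based block index
  within <- (seq_len(m) - 1L) %% bs          # 0-based index inside block
  n_block <- max(block) + 1L
  n_chr <- min(22L, n_block)
  blocks_per_chr <- ceiling(n_block / n_chr)
  chrom <- block %/% blocks_per_chr + 1L
  block_in_chr <- block %% blocks_per_chr
  pos <- 1L + block_in_chr * 510000L + within * 1000L
  set.seed(config$seed)
  maf_block <- runif(n_block, config$maf_range[1], config$maf_range[2])
  data.frame(
    snp_id = sprintf("snp%05d", seq_len(m)),
    chrom = paste0("chr", chrom),
    pos = pos,
    ref = "A", alt = "G",
    block = block,
    maf = maf_block[block + 1L],
    stringsAsFactors = FALSE
  )
}

#' Simulate a genotype panel
#'
#' Dosages in \{0, 1, 2\} for `n_subjects` x `n_snps` biallelic SNPs. Within
#' each LD block haplotypes are generated by a copying chain: the first SNP
#' of a block is Bernoulli(MAF) per haplotype, and each subsequent SNP copies
#' the previous SNP's allele with probability `ld_decay`, otherwise draws
#' fresh. The per-block MAF is constant, so marginal allele frequencies are
#' exact and adjacent-SNP correlation decays geometrically with distance.
#'
#' @param config a [sim_config()].
#' @param phase which phase panel to generate (`"phase1"`, `"phase2"`, ...);
#'   phases share the SNP panel but draw independent subjects, and a phase
#'   with nonzero `freq_shift_sd` perturbs each block's allele frequency on
#'   the logit scale (a different-ancestry replication panel).
#' @return an object of class `geno_matrix`: list with `dosages`
#'   (subjects x SNPs integer matrix, `NA` for missing), `snp_info`
#'   (snp_id, chrom, pos, ref, alt, maf) and `subject_ids`.
#' @export
sim_genotypes <- function(config, phase = "phase1") {
  stopifnot(inherits(config, "sim_config"))
  if (!phase %in% names(config$phase_spec))
    stop("unknown phase: ", phase)
  panel <- snp_panel(config)
  ph <- config$phase_spec[[phase]]
  phase_idx <- match(phase, names(config$phase_spec))
  n <- ph$n
  m <- config$n_snps

  set.seed(config$seed + 97L * phase_idx)
  maf <- panel$maf
  if (!is.null(ph$freq_shift_sd) && ph$freq_shift_sd > 0) {
    # ancestry shift: per-block logit-scale perturbation
    n_block <- max(panel$block) + 1L
    shift <- rnorm(n_block, 0, ph$freq_shift_sd)
    lo <- log(maf / (1 - maf)) + shift[panel$block + 1L]
    maf <- 1 / (1 + exp(-lo))
  }

  # both haplotypes as rows of a 2n x block matrix, one LD block at a
  # time (MAF is constant within a block); within-block columns copy the
  # previous column's allele with probability ld_decay
  nh <- 2L * n
  rho <- config$ld_decay
  D <- matrix(0L, n, m)
  for (b in unique(panel$block)) {
    cols <- which(panel$block == b)
    bs <- length(cols)
    H <- matrix(runif(nh * bs) < maf[cols[1L]], nh, bs)
    if (rho > 0 && bs > 1L) {
      for (k in 2:bs) {
        cp <- runif(nh) < rho
        H[cp, k] <- H[cp, k - 1L]
      }
    }
    D[, cols] <- H[1:n, , drop = FALSE] + H[(n + 1L):nh, , drop = FALSE]
  }
  if (config$missing_rate > 0) {
    miss <- matrix(rbinom(n * m, 1L, config$missing_rate) == 1L, n, m)
    D[miss] <- NA_integer_
  }
  dimnames(D) <- list(NULL, panel$snp_id)
  structure(
    list(dosages = D,
         snp_info = panel[c("snp_id", "chrom", "pos", "ref", "alt", "maf")],
         subject_ids = sprintf("%s_s%05d", phase, seq_len(n))),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("Genotype panel:", length(x$subject_ids), "subjects x",
      nrow(x$snp_info), "SNPs on",
      length(unique(x$snp_info$chrom)), "chromosomes\n")
  invisible(x)
}

#' Write a genotype panel to VCF
#'
#' Hard-call dosages are encoded as `0/0`, `0/1`, `1/1` genotypes and
#' missing dosages as `./.`. The file is written through the vcfR
#' representation (output is bgzip-compressed `.vcf.gz` unless `file` ends
#' in `.vcf`, in which case a plain-text VCF is written).
#'
#' @param geno a `geno_matrix`.
#' @param file output path.
#' @return the path, invisibly.
#' @importClassesFrom vcfR vcfR
#' @export
write_geno_vcf <- function(geno, file) {
  stopifnot(inherits(geno, "geno_matrix"))
  gt_code <- c("0/0", "0/1", "1/1")
  D <- geno$dosages
  gt <- matrix("./.", nrow = ncol(D), ncol = nrow(D))
  ok <- !is.na(t(D))
  gt[ok] <- gt_code[t(D)[ok] + 1L]
  colnames(gt) <- geno$subject_ids
  info <- geno$snp_info
  fix <- cbind(
    CHROM = sub("^chr", "", info$chrom), POS = as.character(info$pos),
    ID = info$snp_id, REF = info$ref, ALT = info$alt,
    QUAL = ".", FILTER = "PASS", INFO = "."
  )
  meta <- c("##fileformat=VCFv4.2",
            "##source=asymlat",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  v <- new("vcfR", meta = meta, fix = fix,
           gt = cbind(FORMAT = "GT", gt))
  if (grepl("\\.vcf$", file)) {
    tmp <- paste0(file, ".gz")
    vcfR::write.vcf(v, tmp)
    con <- gzfile(tmp, "rt")
    writeLines(readLines(con), file)
    close(con)
    unlink(tmp)
  } else {
    vcfR::write.vcf(v, file)
  }
  invisible(file)
}

#' Read a genotype panel from VCF
#'
#' Inverse of [write_geno_vcf()]: parses hard-call GT fields into dosages
#' in \{0, 1, 2\} with `./.` as missing.
#'
#' @param file a VCF path (plain or gzipped).
#' @return a `geno_matrix`.
#' @export
read_geno_vcf <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_count <- function(g) {
    ifelse(is.na(g) | g %in% c("./.", "."), NA_integer_,
           vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), 1L))
  }
  D <- t(apply(gt, 2, alt_count))
  D <- matrix(as.integer(D), nrow = ncol(gt), ncol = nrow(gt),
              dimnames = list(NULL, rownames(gt)))
  fix <- vcfR::getFIX(v)
  info <- data.frame(
    snp_id = fix[, "ID"], chrom = paste0("chr", fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]), ref = fix[, "REF"], alt = fix[, "ALT"],
    stringsAsFactors = FALSE
  )
  maf_obs <- colMeans(D, na.rm = TRUE) / 2
  info$maf <- pmin(maf_obs, 1 - maf_obs)
  structure(
    list(dosages = D, snp_info = info, subject_ids = colnames(gt)),
    class = "geno_matrix"
  )
}
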