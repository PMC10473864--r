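#' Ground-truth description of the simulated cohort
#'
#' Names the causal SNPs acting on the signed asymmetry component, the
#' fraction of asymmetry variance each explains, and the covariate effects
#' on each hemisphere. Per-allele effect sizes are derived from
#' `variance_explained` at generation time, once the allele frequencies of
#' the genotype panel are known.
#'
#' @param causal_snp_ids SNP identifiers with an effect on asymmetry.
#' @param variance_explained per-SNP fraction of the left-minus-right
#'   difference variance, each in \[0, 1) and summing to < 1.
#' @param covariate_effects list with elements `L` and `R`, each a named
#'   numeric vector of coefficients over `age`, `sex`, `age2`, `agesex`,
#'   `age2sex` (age terms are applied to age centred at 55 and scaled by 10
#'   so the terms are O(1)).
#' @return a list of class `cohort_truth`.
#' @export
cohort_truth <- function(causal_snp_ids = character(),
                         variance_explained = numeric(),
                         covariate_effects = list(
                           L = c(age = 0.05, sex = 0.3, age2 = 0,
                                 agesex = 0, age2sex = 0),
                           R = c(age = 0.04, sex = 0.3, age2 = 0,
                                 agesex = 0, age2sex = 0)
                         )) {
  stopifnot(length(causal_snp_ids) == length(variance_explained))
  if (length(variance_explained) &&
      (any(variance_explained < 0) || any(variance_explained >= 1) ||
       sum(variance_explained) >= 1))
    stop("variance_explained entries must be in [0,1) and sum to < 1")
  structure(
    list(causal_snp_ids = as.character(causal_snp_ids),
         variance_explained = variance_explained,
         causal_effects = NULL,   # filled by sim_phenotypes
         covariate_effects = covariate_effects),
    class = "cohort_truth"
  )
}

#' Simulate subject covariates
#'
#' Age uniform on \[40, 69\], sex Bernoulli(0.5), and 20 principal-component
#' style standard-normal columns.
#'
#' @param n number of subjects.
#' @param subject_ids optional identifiers.
#' @param seed integer seed.
#' @return data frame with `subject_id`, `age`, `sex`, `PC1`..`PC20`.
#' @export
sim_covariates <- function(n, subject_ids = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(subject_ids)) subject_ids <- sprintf("s%05d", seq_len(n))
  cov <- data.frame(
    subject_id = subject_ids,
    age = runif(n, 40, 69),
    sex = rbinom(n, 1, 0.5),
    stringsAsFactors = FALSE
  )
  pcs <- matrix(rnorm(n * 20), n, 20,
                dimnames = list(NULL, paste0("PC", 1:20)))
  cbind(cov, as.data.frame(pcs))
}

#' Simulate paired left/right phenotypes with known asymmetry QTLs
#'
#' Each subject's pair is built as
#' `L = base + common + A/2 + noise_L` and
#' `R = base + common - A/2 + noise_R`, where the signed asymmetry component
#' `A = sum(beta_i * dosage_i) + covariate asymmetry` carries the genetic
#' signal. Per-allele effects `beta_i` are scaled so that SNP `i` explains
#' `variance_explained[i]` of the variance of `L - R`. Because the angular
#' asymmetry trait is locally linear in `L - R` around the diagonal, those
#' fractions carry through (to first order) to the derived trait.
#'
#' @param geno a `geno_matrix` from [sim_genotypes()].
#' @param truth a [cohort_truth()]; all causal SNPs must exist in `geno`.
#' @param config the [sim_config()] used to generate `geno`.
#' @param n_pairs number of left/right trait pairs to emit (causal SNPs act
#'   on every pair; measurement noise is independent across pairs).
#' @param instances time-period labels; each instance redraws the
#'   measurement noise but keeps the genetic and covariate parts.
#' @return list with `traits` (subject_id, pair_id, instance, left, right),
#'   `covariates` (see [sim_covariates()]) and `truth` with
#'   `causal_effects` filled in (per-allele effect on `L - R`).
#' @export
sim_phenotypes <- function(geno, truth, config, n_pairs = 1,
                           instances = "instance1") {
  stopifnot(inherits(geno, "geno_matrix"), inherits(truth, "cohort_truth"),
            inherits(config, "sim_config"))
  miss <- setdiff(truth$causal_snp_ids, geno$snp_info$snp_id)
  if (length(miss))
    stop("causal SNP(s) absent from genotype panel: ",
         paste(miss, collapse = ", "))
  n <- length(geno$subject_ids)
  # phase-specific offset so different phases draw independent noise
  tag <- sum(utf8ToInt(sub("_.*$", "", geno$subject_ids[1]))) %% 1000L
  set.seed(config$seed + 7919L + tag)
  cov <- sim_covariates(n, geno$subject_ids,
                        seed = config$seed + 104729L + tag)

  # per-allele effects from variance-explained targets
  v_noise <- 2 * config$noise_sd^2
  ve <- truth$variance_explained
  v_total <- if (length(ve)) v_noise / (1 - sum(ve)) else v_noise
  beta <- numeric(length(ve))
  A_gen <- numeric(n)
  if (length(ve)) {
    idx <- match(truth$causal_snp_ids, geno$snp_info$snp_id)
    p <- geno$snp_info$maf[idx]
    beta <- sqrt(ve * v_total / (2 * p * (1 - p)))
    G <- geno$dosages[, idx, drop = FALSE]
    G[is.na(G)] <- 0L
    A_gen <- as.numeric(G %*% beta)
  }
  truth$causal_effects <- setNames(beta, truth$causal_snp_ids)

  age_s <- (cov$age - 55) / 10
  X <- cbind(age = age_s, sex = cov$sex, age2 = age_s^2,
             agesex = age_s * cov$sex, age2sex = age_s^2 * cov$sex)
  ce <- truth$covariate_effects
  cov_L <- as.numeric(X %*% ce$L[colnames(X)])
  cov_R <- as.numeric(X %*% ce$R[colnames(X)])

  out <- vector("list", n_pairs * length(instances))
  k <- 0L
  for (pr in seq_len(n_pairs)) {
    common <- config$base_level + rnorm(n, 0, config$common_sd)
    for (ins in instances) {
      k <- k + 1L
      eL <- rnorm(n, 0, config$noise_sd)
      eR <- rnorm(n, 0, config$noise_sd)
      out[[k]] <- data.frame(
        subject_id = geno$subject_ids,
        pair_id = sprintf("pair%03d", pr),
        instance = ins,
        left = common + cov_L + A_gen / 2 + eL,
        right = common + cov_R - A_gen / 2 + eR,
        stringsAsFactors = FALSE
      )
    }
  }
  list(traits = do.call(rbind, out), covariates = cov, truth = truth)
}
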