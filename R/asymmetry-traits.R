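#' Angular left-right asymmetry index
#'
#' The signed angular asymmetry of a left/right pair, defined as
#' \code{asin((L - R) / sqrt(2 * (L^2 + R^2)))}: the angular deviation of the
#' point (L, R) from the diagonal L = R. For strictly positive L and R it is
#' a monotone transform of the traditional index \code{(L - R)/(L + R)}, but
#' it remains defined and bounded when values span zero.
#'
#' @param left,right numeric vectors of paired left/right measurements.
#' @return numeric vector of angles in radians, in \code{[-pi/2, pi/2]};
#'   pairs with \code{L = R = 0} (direction undefined at the origin) and
#'   pairs with missing values return \code{NA}.
#' @seealso [compute_asymmetry()] for the four trait plans,
#'   [traditional_index()], [asym_level()] for the sine (non-arcsine) form.
#' @export
#' @examples
#' asymmetry_angle(1, 0)   # pi/4
#' asymmetry_angle(3, 1)   # asin(2/sqrt(20))
asymmetry_angle <- function(left, right) {
  stopifnot(length(left) == length(right))
  denom <- sqrt(2 * (left^2 + right^2))
  out <- asin((left - right) / denom)
  out[!is.na(denom) & denom == 0] <- NA_real_
  out
}

#' Traditional left-right asymmetry index
#'
#' \code{(L - R) / (L + R)}. Pairs with \code{L + R = 0} are undefined and
#' return \code{NA}.
#'
#' @inheritParams asymmetry_angle
#' @return numeric vector.
#' @export
traditional_index <- function(left, right) {
  stopifnot(length(left) == length(right))
  denom <- left + right
  out <- (left - right) / denom
  out[!is.na(denom) & denom == 0] <- NA_real_
  out
}

#' Derive one asymmetry trait from a left/right trait pair
#'
#' Four plans are supported:
#' \describe{
#'   \item{I}{signed angle on raw values.}
#'   \item{II}{absolute value of plan I.}
#'   \item{III}{signed angle on z-standardized values (each side centred and
#'     scaled over its non-missing subjects).}
#'   \item{IV}{absolute value of plan III.}
#' }
#'
#' @param pair a `trait_pair` (see [trait_pair()]) or a data frame with
#'   columns `subject_id`, `left`, `right`.
#' @param plan one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @return an object of class `asymmetry_trait`: a list with `plan`,
#'   `subject_id`, `values` (radians), `qc_status` (initially `"kept"`),
#'   and `normalized` (initially `NULL`).
#' @export
compute_asymmetry <- function(pair, plan = c("I", "II", "III", "IV")) {
  plan <- match.arg(plan)
  pair <- as_trait_pair(pair)
  if (nrow(pair) == 0L) stop("empty trait pair")
  L <- pair$left
  R <- pair$right
  if (plan %in% c("III", "IV")) {
    for (v in list(L, R)) {
      if (length(unique(v[!is.na(v)])) < 2L)
        stop("degenerate standardization: fewer than 2 distinct values on one side")
    }
    L <- (L - mean(L, na.rm = TRUE)) / sd(L, na.rm = TRUE)
    R <- (R - mean(R, na.rm = TRUE)) / sd(R, na.rm = TRUE)
  }
  values <- asymmetry_angle(L, R)
  if (plan %in% c("II", "IV")) values <- abs(values)
  structure(
    list(plan = plan, subject_id = pair$subject_id, values = values,
         qc_status = "kept", normalized = NULL),
    class = "asymmetry_trait"
  )
}

#' @export
print.asymmetry_trait <- function(x, ...) {
  n_ok <- sum(!is.na(x$values))
  cat("Asymmetry trait (plan ", x$plan, "): ", length(x$values),
      " subjects, ", n_ok, " non-missing; QC: ", x$qc_status, "\n", sep = "")
  invisible(x)
}

#' Construct a left/right trait pair table
#'
#' @param subject_id subject identifiers.
#' @param left,right paired measurements.
#' @param instance optional time-period label.
#' @return a data frame of class `trait_pair`.
#' @export
trait_pair <- function(subject_id, left, right, instance = "1") {
  stopifnot(length(left) == length(right), length(subject_id) == length(left))
  structure(
    data.frame(subject_id = as.character(subject_id), left = left,
               right = right, instance = instance,
               stringsAsFactors = FALSE),
    class = c("trait_pair", "data.frame")
  )
}

as_trait_pair <- function(x) {
  if (inherits(x, "trait_pair")) return(x)
  stopifnot(is.data.frame(x), all(c("left", "right") %in% names(x)))
  if (is.null(x$subject_id)) x$subject_id <- as.character(seq_len(nrow(x)))
  if (is.null(x$instance)) x$instance <- "1"
  class(x) <- c("trait_pair", "data.frame")
  x
}

#' Expand left/right trait pairs into the full set of asymmetry traits
#'
#' Every pair yields one trait per plan, so `n` pairs expand to `4 * n`
#' asymmetry traits.
#'
#' @param pairs a list of trait pairs, or a single data frame with a
#'   `pair_id` column identifying the pairs.
#' @param plans character vector of plans to derive (default all four).
#' @return a list of `asymmetry_trait` objects, named `<pair>_plan<plan>`.
#' @export
derive_asymmetry_traits <- function(pairs, plans = c("I", "II", "III", "IV")) {
  if (is.data.frame(pairs)) {
    stopifnot("pair_id" %in% names(pairs))
    pairs <- split(pairs[setdiff(names(pairs), "pair_id")], pairs$pair_id)
  }
  if (is.null(names(pairs))) names(pairs) <- paste0("pair", seq_along(pairs))
  out <- list()
  for (pid in names(pairs)) {
    for (pl in plans) {
      out[[paste0(pid, "_plan", pl)]] <- compute_asymmetry(pairs[[pid]], pl)
    }
  }
  out
}

#' Trait-level quality control
#'
#' A trait is dropped when it has fewer than `min_n` non-missing values
#' (`dropped(small_sample)`) or when more than `max_identical_frac` of its
#' non-missing values are identical (`dropped(degenerate)`); otherwise kept.
#'
#' @param trait an `asymmetry_trait`.
#' @param min_n minimum non-missing sample size (default 1000).
#' @param max_identical_frac maximal allowed modal-value frequency among
#'   non-missing values (default 0.5).
#' @return the trait with `qc_status` set.
#' @export
qc_trait <- function(trait, min_n = 1000, max_identical_frac = 0.5) {
  stopifnot(inherits(trait, "asymmetry_trait"))
  v <- trait$values[!is.na(trait$values)]
  if (length(v) < min_n) {
    trait$qc_status <- "dropped(small_sample)"
  } else if (max(table(v)) / length(v) > max_identical_frac) {
    trait$qc_status <- "dropped(degenerate)"
  } else {
    trait$qc_status <- "kept"
  }
  trait
}

#' Normalize a trait vector
#'
#' `rank_int` is the rank-based inverse-normal transform
#' `qnorm((rank - 0.5) / n)` with average ranks for ties, computed over
#' non-missing entries; `zscale` is the ordinary z-score. `auto` applies
#' `rank_int` unless more than 25\% of the values are tied at a single value
#' (heavy ties make the rank transform a poor fit), in which case it falls
#' back to `zscale`.
#'
#' @param values numeric vector; missing entries propagate.
#' @param method `"rank_int"`, `"zscale"`, or `"auto"`.
#' @return numeric vector of the same length.
#' @export
normalize_trait <- function(values, method = c("rank_int", "zscale", "auto")) {
  method <- match.arg(method)
  ok <- !is.na(values)
  v <- values[ok]
  if (length(unique(v)) < 2L) stop("degenerate normalization: all values identical")
  if (method == "auto") {
    method <- if (max(table(v)) / length(v) > 0.25) "zscale" else "rank_int"
  }
  out <- rep(NA_real_, length(values))
  if (method == "rank_int") {
    r <- rank(v, ties.method = "average")
    out[ok] <- qnorm((r - 0.5) / length(v))
  } else {
    out[ok] <- (v - mean(v)) / sd(v)
  }
  out
}
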