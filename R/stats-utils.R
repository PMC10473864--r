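# Shared small statistical primitives.
#
# The one-sided binomial and hypergeometric tails wrap the base
# distribution functions; the paired signed-rank test is implemented
# directly because the tie-aware exact null (needed when many paired
# differences share a magnitude, as log-ratio indices often do) is not
# available from stats::wilcox.test.

#' One-sided binomial tail probability P(X >= k | n, p)
#'
#' @param k observed success count.
#' @param n number of trials.
#' @param p success probability under the null.
#' @return upper-tail probability including `k`.
#' @export
binom_tail <- function(k, n, p) {
  stopifnot(k >= 0, k <= n, p >= 0, p <= 1)
  pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' One-sided hypergeometric tail probability of an overlap at least as large
#'
#' P(X >= k) where X is the overlap between a draw of size `n_focal` and a
#' marked set of size `n_set` in a universe of size `n_universe`.
#'
#' @param k observed overlap.
#' @param n_universe universe size.
#' @param n_set marked-set size.
#' @param n_focal draw size.
#' @return upper-tail probability including `k`.
#' @export
hyper_tail <- function(k, n_universe, n_set, n_focal) {
  stopifnot(n_universe >= n_set, n_universe >= n_focal, k >= 0)
  phyper(k - 1, n_set, n_universe - n_set, n_focal, lower.tail = FALSE)
}

#' One-sided paired Wilcoxon signed-rank test
#'
#' Tests whether paired differences `x - y` are shifted in the positive
#' direction. Zero differences are dropped (Wilcoxon convention); when no
#' nonzero differences remain the test carries no evidence and P = 1 is
#' returned. For small samples the exact null distribution of the
#' signed-rank sum is used; with tied magnitudes the exact distribution is
#' computed over the realized (average) ranks by dynamic programming, so
#' e.g. n identical positive differences give P = 2^-n exactly. Larger
#' samples use the normal approximation with tie correction.
#'
#' @param x,y paired numeric vectors, or `y = NULL` to test differences in
#'   `x` directly.
#' @param exact_max_n use the exact null up to this many nonzero pairs.
#' @return list with `statistic` (rank sum of positive differences),
#'   `n` (nonzero pairs used) and `p.value` (one-sided, greater).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max_n = 200) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, n = 0L, p.value = 1))
  }
  r <- rank(abs(d), ties.method = "average")
  v <- sum(r[d > 0])
  if (n <= exact_max_n) {
    p <- signed_rank_tail_exact(r, v)
  } else {
    mu <- sum(r) / 2
    sigma2 <- sum(r^2) / 4  # tie-corrected: uses realized average ranks
    z <- (v - mu - 0.5) / sqrt(sigma2)  # continuity correction
    p <- pnorm(z, lower.tail = FALSE)
  }
  list(statistic = v, n = n, p.value = p)
}

# Exact P(V >= v) where V = sum over a uniform random sign assignment of the
# given rank values (average ranks allowed: everything is doubled so the
# DP runs over integers).
signed_rank_tail_exact <- function(ranks, v) {
  w <- as.integer(round(2 * ranks))
  total <- sum(w)
  # f[s+1] = number of sign assignments with doubled rank-sum s
  f <- numeric(total + 1)
  f[1] <- 1
  for (wi in w) {
    g <- f
    g[(wi + 1):(total + 1)] <- g[(wi + 1):(total + 1)] + f[1:(total + 1 - wi)]
    f <- g
  }
  thr <- ceiling(round(2 * v, 6))  # doubled observed statistic
  sum(f[(thr + 1):(total + 1)]) / 2^length(w)
}

#' One-sided rank-sum (Mann-Whitney) test of focal > others
#'
#' Thin wrapper over [stats::wilcox.test()] with `alternative = "greater"`,
#' returning only the P value (NA when either group is empty or all values
#' are missing).
#'
#' @param focal,others numeric vectors.
#' @return one-sided P value.
#' @export
rank_sum_greater <- function(focal, others) {
  focal <- focal[!is.na(focal)]
  others <- others[!is.na(others)]
  if (length(focal) == 0L || length(others) == 0L) return(NA_real_)
  suppressWarnings(
    wilcox.test(focal, others, alternative = "greater")$p.value
  )
}
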