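#' Gene-age map: ordered clades with gene-to-clade assignments
#'
#' @param clades ordered clade labels, most ancient first.
#' @param assignment named character vector mapping every background gene to
#'   exactly one clade in `clades`.
#' @return a list of class `clade_map` with `clades` and `assignment`.
#' @export
clade_map <- function(clades, assignment) {
  clades <- as.character(clades)
  assignment <- setNames(as.character(assignment), names(assignment))
  if (is.null(names(assignment)) || any(!nzchar(names(assignment))))
    stop("assignment must be a named vector (gene -> clade)")
  if (!all(assignment %in% clades))
    stop("assignment contains clades not in the clade order")
  structure(list(clades = clades, assignment = assignment),
            class = "clade_map")
}

#' @export
print.clade_map <- function(x, ...) {
  tab <- table(factor(x$assignment, levels = x$clades))
  cat("Gene-age map:", length(x$assignment), "genes over",
      length(x$clades), "clades (ancient -> recent)\n")
  print(tab)
  invisible(x)
}

#' Read a gene-to-clade TSV
#'
#' @param file TSV with columns `gene_id` and `clade`.
#' @param clades ordered clade labels (ancient first); defaults to order of
#'   first appearance in the file.
#' @return a `clade_map`.
#' @export
read_clade_map <- function(file, clades = NULL) {
  d <- read.table(file, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  if (is.null(clades)) clades <- unique(d$clade)
  clade_map(clades, setNames(d$clade, d$gene_id))
}

# Focal genes restricted to the background, with a warning for the rest.
restrict_focal <- function(focal, map) {
  known <- focal %in% names(map$assignment)
  if (any(!known))
    warning(sum(!known), " focal gene(s) absent from the background map ",
            "were excluded")
  unique(focal[known])
}

#' Binomial enrichment of a focal gene set in one clade
#'
#' One-sided tail P(X >= k | n = focal size, p = background proportion of
#' the clade), where k is the number of focal genes originating in the
#' clade. Focal genes absent from the background map are excluded with a
#' warning.
#'
#' @param focal character vector of focal gene ids.
#' @param map a `clade_map`.
#' @param clade clade label.
#' @return one-sided binomial P value.
#' @export
clade_binomial <- function(focal, map, clade) {
  stopifnot(inherits(map, "clade_map"), clade %in% map$clades)
  focal <- restrict_focal(focal, map)
  n <- length(focal)
  if (n == 0L) stop("no focal genes overlap the background map")
  p_bg <- mean(map$assignment == clade)
  k <- sum(map$assignment[focal] == clade)
  binom_tail(k, n, p_bg)
}

#' Per-clade enrichment table
#'
#' [clade_binomial()] applied to every clade, with a significance flag at
#' unadjusted P < `alpha`.
#'
#' @param focal focal gene ids.
#' @param map a `clade_map`.
#' @param alpha per-clade significance level (default 0.05).
#' @return data frame (clade, k, n, p_background, p.value, significant),
#'   one row per clade in ancient-to-recent order.
#' @export
enrich_all_clades <- function(focal, map, alpha = 0.05) {
  stopifnot(inherits(map, "clade_map"))
  focal <- restrict_focal(focal, map)
  n <- length(focal)
  if (n == 0L) stop("no focal genes overlap the background map")
  tab_bg <- table(factor(map$assignment, levels = map$clades))
  p_bg <- as.numeric(tab_bg) / length(map$assignment)
  k <- as.integer(table(factor(map$assignment[focal], levels = map$clades)))
  pv <- mapply(binom_tail, k, MoreArgs = list(n = n), p = p_bg)
  data.frame(clade = map$clades, k = k, n = n, p_background = p_bg,
             p.value = pv, significant = pv < alpha,
             stringsAsFactors = FALSE)
}

#' Merge clades more ancient than a boundary into one "ancient" clade
#'
#' All clades strictly preceding `boundary` in the ancient-to-recent order
#' are collapsed into a single clade labelled `"ancient"`; gene assignments
#' are remapped and the remaining order is preserved. Used to compare trees
#' whose ancient clades have different resolution.
#'
#' @param map a `clade_map`.
#' @param boundary clade label marking the first clade kept as-is
#'   (default `"Tetrapoda"`).
#' @return a new `clade_map`.
#' @export
degenerate_tree <- function(map, boundary = "Tetrapoda") {
  stopifnot(inherits(map, "clade_map"))
  i <- match(boundary, map$clades)
  if (is.na(i)) stop("boundary clade not in the map: ", boundary)
  if (i == 1L) return(map)
  old <- map$clades[seq_len(i - 1L)]
  new_clades <- c("ancient", map$clades[i:length(map$clades)])
  assignment <- map$assignment
  assignment[assignment %in% old] <- "ancient"
  clade_map(new_clades, assignment)
}

#' Stepwise binomial clade enrichment
#'
#' Iteratively: test every clade, and if the minimum P value is below
#' `alpha`, record that clade, remove all of its genes from both the focal
#' set and the background, renormalize background proportions over the
#' remaining clades, and repeat. Stops when no clade reaches `alpha` (or
#' the focal set is exhausted). Addresses the non-independence of the
#' per-clade tests. Ties in the minimum P are broken toward the more
#' ancient clade.
#'
#' @param focal focal gene ids.
#' @param map a `clade_map`.
#' @param alpha stopping level (default 0.05).
#' @return data frame (clade, p.value) of selected clades in selection
#'   order (zero rows when nothing is significant).
#' @export
stepwise_enrichment <- function(focal, map, alpha = 0.05) {
  stopifnot(inherits(map, "clade_map"))
  focal <- restrict_focal(focal, map)
  sel <- list()
  cur_map <- map
  cur_focal <- focal
  while (length(cur_map$clades) > 0L && length(cur_focal) > 0L) {
    tab <- enrich_all_clades(cur_focal, cur_map, alpha = alpha)
    best <- which(tab$p.value == min(tab$p.value))[1L]  # ancient-first ties
    if (tab$p.value[best] >= alpha) break
    sel[[length(sel) + 1L]] <- data.frame(clade = tab$clade[best],
                                          p.value = tab$p.value[best],
                                          stringsAsFactors = FALSE)
    keep_clades <- setdiff(cur_map$clades, tab$clade[best])
    if (!length(keep_clades)) break
    keep_genes <- cur_map$assignment != tab$clade[best]
    cur_map <- clade_map(keep_clades, cur_map$assignment[keep_genes])
    cur_focal <- cur_focal[cur_focal %in% names(cur_map$assignment)]
    if (!length(cur_focal)) break
  }
  if (length(sel)) do.call(rbind, sel) else
    data.frame(clade = character(), p.value = numeric(),
               stringsAsFactors = FALSE)
}
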