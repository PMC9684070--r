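#' DEG-calling thresholds
#'
#' A gene is called differentially expressed when its BH-adjusted p-value is
#' below `alpha_adj` and the absolute natural-log fold change exceeds
#' `min_abs_lfc` (strict inequalities on both).
#'
#' @param alpha_adj adjusted-p cutoff (default 0.05).
#' @param min_abs_lfc natural-log fold-change cutoff (default 0.1).
#' @return A `DegThresholds` list.
#' @export
deg_thresholds <- function(alpha_adj = 0.05, min_abs_lfc = 0.1) {
  stopifnot(alpha_adj > 0, alpha_adj < 1, min_abs_lfc >= 0)
  structure(list(alpha_adj = alpha_adj, min_abs_lfc = min_abs_lfc),
            class = "DegThresholds")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Midranks are used for ties. For small tie-free samples
#' (`n1 + n2 <= exact_limit`) the p-value comes from the exact null
#' distribution of the Mann-Whitney statistic; otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used — the same convention as classical implementations, but vectorizable
#' across thousands of genes.
#'
#' @param x,y numeric vectors, each non-empty.
#' @param exact_limit largest `n1 + n2` for which the exact path is taken
#'   when no ties are present (default 12).
#' @return List with `statistic` (Mann-Whitney U for `x`) and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 12L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty", call. = FALSE)
  z <- c(x, y)
  r <- rank(z)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  nties <- tabulate(match(z, unique(z)))
  has_ties <- any(nties > 1L)
  N <- n1 + n2
  if (!has_ties && N <= exact_limit) {
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE))
    p <- min(1, p)
  } else {
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 *
      ((N + 1) - sum(nties^3 - nties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      d <- U - mu
      d <- d - sign(d) * 0.5
      p <- min(1, 2 * stats::pnorm(-abs(d) / sqrt(sigma2)))
    }
  }
  list(statistic = U, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; the adjusted value for a p is the minimum over
#' larger-or-equal order statistics of `m * p_(j) / j`, clipped at 1, in the
#' original input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Natural-log fold change between two cell groups
#'
#' De-logs the normalized values, averages within each group, and returns
#' `ln(mean1 + pseudocount) - ln(mean2 + pseudocount)`. With the default
#' pseudocount of 1 this is the convention of the standard single-cell
#' toolchain on the natural-log scale; `pseudocount = 0` gives the plain log
#' ratio of group means (used for parameter-recovery checks, where it is
#' unbiased for the planted effect).
#'
#' @param nd a `NormalizedDataset`.
#' @param cells1,cells2 index vectors of the two groups (non-empty).
#' @param genes genes to evaluate (default all).
#' @param pseudocount added to each de-logged group mean before logging.
#' @return Named numeric vector of log fold changes.
#' @export
log_fold_change <- function(nd, cells1, cells2, genes = nd$gene_ids,
                            pseudocount = 1) {
  if (length(cells1) == 0 || length(cells2) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  gi <- match(genes, nd$gene_ids)
  if (anyNA(gi)) {
    stop("gene(s) absent from dataset: ",
         paste(utils::head(genes[is.na(gi)], 5L), collapse = ", "),
         call. = FALSE)
  }
  m1 <- delogged_group_means(nd, cells1, gi)
  m2 <- delogged_group_means(nd, cells2, gi)
  out <- log(m1 + pseudocount) - log(m2 + pseudocount)
  names(out) <- genes
  out
}

# Mean of expm1(values) per gene over a cell subset, computed sparsely.
delogged_group_means <- function(nd, cells, gene_idx) {
  v <- nd$values[cells, gene_idx, drop = FALSE]
  v@x <- expm1(v@x)
  Matrix::colMeans(v)
}

#' Per-gene differential expression between two cell groups
#'
#' Tests every gene detected (nonzero) in at least one cell of either group
#' with the Wilcoxon rank-sum test, adjusts p-values by Benjamini-Hochberg
#' across exactly that tested set, computes natural-log fold changes and
#' detection fractions, and flags significance at the supplied thresholds.
#' Optional `min_pct` / `logfc_prefilter` gates restrict the tested set the
#' way some toolchains do by default; both default to off.
#'
#' @param nd a `NormalizedDataset`.
#' @param cells1,cells2 disjoint non-empty cell index vectors
#'   (group 1 vs group 2; positive lfc means higher in group 1).
#' @param thresholds a [deg_thresholds()] object.
#' @param contrast optional named list describing the contrast (organ,
#'   subtype, diets, timepoint); stored as an attribute and echoed in output.
#' @param min_pct minimum detection fraction in either group (default 0, off).
#' @param logfc_prefilter minimum |lfc| required before testing (default 0,
#'   off).
#' @param exact_limit passed to [wilcoxon_rank_sum()].
#' @return A `DeTable` data.frame: `gene`, `lfc`, `p`, `adj_p`, `pct1`,
#'   `pct2`, `n1`, `n2`, `significant`.
#' @export
find_degs <- function(nd, cells1, cells2, thresholds = deg_thresholds(),
                      contrast = NULL, min_pct = 0, logfc_prefilter = 0,
                      exact_limit = 12L) {
  if (is.character(cells1)) cells1 <- match(cells1, nd$cell_ids)
  if (is.character(cells2)) cells2 <- match(cells2, nd$cell_ids)
  if (length(cells1) == 0 || length(cells2) == 0) {
    stop("degenerate contrast: empty cell group", call. = FALSE)
  }
  if (length(intersect(cells1, cells2))) {
    stop("degenerate contrast: groups overlap", call. = FALSE)
  }
  n1 <- length(cells1); n2 <- length(cells2)
  X1 <- as.matrix(nd$values[cells1, , drop = FALSE])
  X2 <- as.matrix(nd$values[cells2, , drop = FALSE])
  pct1 <- colMeans(X1 > 0)
  pct2 <- colMeans(X2 > 0)
  tested <- pct1 > 0 | pct2 > 0
  if (min_pct > 0) tested <- tested & (pct1 >= min_pct | pct2 >= min_pct)
  m1 <- colMeans(expm1(X1))
  m2 <- colMeans(expm1(X2))
  lfc <- log(m1 + 1) - log(m2 + 1)
  if (logfc_prefilter > 0) tested <- tested & abs(lfc) > logfc_prefilter
  idx <- which(tested)
  p <- stat <- numeric(length(idx))
  for (k in seq_along(idx)) {
    res <- wilcoxon_rank_sum(X1[, idx[k]], X2[, idx[k]],
                             exact_limit = exact_limit)
    p[k] <- res$p
    stat[k] <- res$statistic
  }
  adj_p <- bh_adjust(p)
  out <- data.frame(
    gene = nd$gene_ids[idx], lfc = lfc[idx], statistic = stat, p = p,
    adj_p = adj_p, pct1 = pct1[idx], pct2 = pct2[idx], n1 = n1, n2 = n2,
    significant = adj_p < thresholds$alpha_adj &
      abs(lfc[idx]) > thresholds$min_abs_lfc,
    row.names = NULL
  )
  attr(out, "contrast") <- contrast
  attr(out, "thresholds") <- thresholds
  class(out) <- c("DeTable", "data.frame")
  out
}

#' @exportS3Method base::print
print.DeTable <- function(x, ...) {
  ct <- attr(x, "contrast")
  if (!is.null(ct)) {
    cat("Contrast:", paste(names(ct), unlist(ct), sep = "=", collapse = " "),
        "\n")
  }
  cat("DeTable:", nrow(x), "tested genes,", sum(x$significant),
      "significant\n")
  n_show <- min(nrow(x), 10L)
  if (n_show > 0) {
    print.data.frame(utils::head(x, n_show), digits = 3)
    if (nrow(x) > n_show) cat("... and", nrow(x) - n_show, "more genes\n")
  }
  invisible(x)
}

#' Downsampling-equalized DEG counting
#'
#' Cluster size drives statistical power, so raw DEG counts are not
#' comparable across clusters of different sizes. Each contrast's two groups
#' are subsampled without replacement to a common `n_cells` (by default the
#' smallest group size across all contrasts, mirroring the atlas's
#' downsampling to its smallest cluster) before counting significant genes.
#' With `n_draws > 1` the per-contrast count is the median across draws.
#'
#' @param nd a `NormalizedDataset`.
#' @param contrasts list of contrasts, each a list with `cells1`, `cells2`
#'   and optionally `label`.
#' @param n_cells common group size, or `"auto"` for the minimum group size.
#' @param n_draws number of independent subsample draws (default 1).
#' @param seed integer seed governing all draws.
#' @param thresholds a [deg_thresholds()] object.
#' @param ... passed to [find_degs()].
#' @return data.frame `contrast`, `n_cells`, `n_draws`, `deg_count`, with the
#'   per-draw count matrix in attribute `"draws"`.
#' @export
count_degs_downsampled <- function(nd, contrasts, n_cells = "auto",
                                   n_draws = 1L, seed = 1L,
                                   thresholds = deg_thresholds(), ...) {
  sizes <- unlist(lapply(contrasts, function(ct) {
    c(length(ct$cells1), length(ct$cells2))
  }))
  if (identical(n_cells, "auto")) n_cells <- min(sizes)
  n_cells <- as.integer(n_cells)
  if (n_cells > min(sizes)) {
    stop("n_cells (", n_cells, ") exceeds the smallest group size (",
         min(sizes), ")", call. = FALSE)
  }
  labels <- vapply(seq_along(contrasts), function(i) {
    lb <- contrasts[[i]]$label
    if (is.null(lb)) paste0("contrast_", i) else lb
  }, character(1))
  draws <- matrix(NA_integer_, nrow = length(contrasts), ncol = n_draws,
                  dimnames = list(labels, NULL))
  for (d in seq_len(n_draws)) {
    set.seed(seed + d - 1L)
    for (i in seq_along(contrasts)) {
      ct <- contrasts[[i]]
      s1 <- sample(ct$cells1, n_cells)
      s2 <- sample(ct$cells2, n_cells)
      de <- find_degs(nd, s1, s2, thresholds = thresholds, ...)
      draws[i, d] <- sum(de$significant)
    }
  }
  out <- data.frame(contrast = labels, n_cells = n_cells, n_draws = n_draws,
                    deg_count = apply(draws, 1L, stats::median),
                    row.names = NULL)
  attr(out, "draws") <- draws
  attr(out, "seed") <- seed
  out
}
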