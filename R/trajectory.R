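#' Chow-standardized fold changes at one timepoint
#'
#' For each non-chow diet present at the given timepoint (within an optional
#' organ/cluster selection), computes the per-gene natural-log fold change
#' of that diet's cells against the timepoint-matched chow controls, the
#' standardization used throughout the reversion analysis. A gene is marked
#' `detected` for a diet when it is nonzero in at least one cell of that
#' diet's group or of the chow group.
#'
#' @param nd a `NormalizedDataset`.
#' @param timepoint timepoint in months.
#' @param organ,cluster optional selection.
#' @param diets diets to standardize (default all non-chow diets present).
#' @param pseudocount passed to [log_fold_change()]; the default 1 matches
#'   the DE convention, 0 gives plain mean ratios.
#' @return Named list (one element per diet) of data.frames with columns
#'   `gene`, `lfc`, `detected`.
#' @export
standardize_to_chow <- function(nd, timepoint, organ = NULL, cluster = NULL,
                                diets = NULL, pseudocount = 1) {
  chow <- cells_where(nd, organ = organ, cluster = cluster, diet = "chow",
                      timepoint = timepoint)
  if (length(chow) == 0) {
    stop("no chow cells at timepoint ", timepoint,
         " for the requested selection", call. = FALSE)
  }
  present <- unique(nd$meta$diet[cells_where(nd, organ = organ,
                                             cluster = cluster,
                                             timepoint = timepoint)])
  if (is.null(diets)) diets <- setdiff(DIETS, "chow")
  diets <- intersect(diets, setdiff(present, "chow"))
  chow_pct <- Matrix::colMeans(nd$values[chow, , drop = FALSE] > 0)
  out <- list()
  for (d in diets) {
    grp <- cells_where(nd, organ = organ, cluster = cluster, diet = d,
                       timepoint = timepoint)
    lfc <- log_fold_change(nd, grp, chow, pseudocount = pseudocount)
    grp_pct <- Matrix::colMeans(nd$values[grp, , drop = FALSE] > 0)
    out[[d]] <- data.frame(gene = nd$gene_ids, lfc = unname(lfc),
                           detected = grp_pct > 0 | chow_pct > 0,
                           row.names = NULL)
  }
  out
}

#' Classify reversion-diet restoration of obesity DEGs
#'
#' A Western-diet DEG is `restored` when the reversion arm's
#' chow-standardized fold change is closer to chow (zero) than to the
#' sustained-WD fold change: `|lfc_rev| < |lfc_rev - lfc_wd|`. Both inputs
#' must be standardized against the chow control at the matching timepoint.
#' Equality within `tie_tol` is flagged and conservatively classified as
#' not restored. Genes without a reversion measurement are excluded and
#' counted in the `n_excluded` attribute.
#'
#' @param deg_wd a `DeTable` for the WD-vs-chow contrast; only rows flagged
#'   `significant` enter the classification.
#' @param lfc_rev reversion-vs-chow fold changes: a named numeric vector or
#'   a data.frame with columns `gene`, `lfc` and optionally `detected`
#'   (as returned by [standardize_to_chow()]).
#' @param tie_tol equality tolerance for the tie flag (default 1e-12).
#' @return A `RestorationTable` data.frame: `gene`, `direction`, `lfc_wd`,
#'   `lfc_rev`, `restored`, `tie`.
#' @export
classify_restoration <- function(deg_wd, lfc_rev, tie_tol = 1e-12) {
  sig <- deg_wd[deg_wd$significant, , drop = FALSE]
  if (is.data.frame(lfc_rev)) {
    detected <- if ("detected" %in% names(lfc_rev)) lfc_rev$detected else TRUE
    lfc_rev <- stats::setNames(lfc_rev$lfc, lfc_rev$gene)[detected]
  }
  have_rev <- sig$gene %in% names(lfc_rev)
  n_excluded <- sum(!have_rev)
  sig <- sig[have_rev, , drop = FALSE]
  rev <- unname(lfc_rev[sig$gene])
  d_chow <- abs(rev)
  d_wd <- abs(rev - sig$lfc)
  tie <- abs(d_chow - d_wd) <= tie_tol
  out <- data.frame(
    gene = sig$gene,
    direction = ifelse(sig$lfc > 0, "up", "down"),
    lfc_wd = sig$lfc, lfc_rev = rev,
    restored = d_chow < d_wd & !tie,
    tie = tie, row.names = NULL
  )
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("RestorationTable", "data.frame")
  out
}

#' @exportS3Method base::print
print.RestorationTable <- function(x, ...) {
  cat("RestorationTable:", nrow(x), "DEGs;",
      sum(x$restored), "restored,", sum(!x$restored), "persistent (",
      attr(x, "n_excluded") %||% 0, "excluded without rev measurement )\n")
  n_show <- min(nrow(x), 10L)
  if (n_show > 0) {
    print.data.frame(utils::head(x, n_show), digits = 3)
    if (nrow(x) > n_show) cat("... and", nrow(x) - n_show, "more genes\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Restored proportions by direction
#'
#' Fractions of up- and downregulated obesity DEGs classified as restored.
#' A direction with zero genes is reported as `NA` (undefined), not 0.
#'
#' @param rt a `RestorationTable`.
#' @return List: `up`, `down` (fractions restored or `NA`), `n_up`, `n_down`.
#' @export
restored_proportions <- function(rt) {
  if (nrow(rt) == 0) {
    stop("restoration table is empty in both directions", call. = FALSE)
  }
  frac <- function(dir) {
    sub <- rt[rt$direction == dir, , drop = FALSE]
    if (nrow(sub) == 0) NA_real_ else mean(sub$restored)
  }
  list(up = frac("up"), down = frac("down"),
       n_up = sum(rt$direction == "up"), n_down = sum(rt$direction == "down"))
}

#' Genes most consistently changing across organs
#'
#' Intersects the genes with a computable fold change in every organ's
#' table, ranks them by mean natural-log fold change across organs, and
#' keeps genes whose mean |lfc| strictly exceeds the threshold, split into
#' up- and downregulated lists.
#'
#' @param lfc_by_organ named list (>= 2 organs) of `DeTable`s, or of
#'   data.frames with columns `gene` and `lfc`, for one EC population.
#' @param min_mean_abs_lfc inclusion threshold on |mean lfc|
#'   (default 0.2, strict).
#' @return A `ConsistencyMatrix` list: `lfc` (genes x organs matrix over the
#'   common gene set), `mean_lfc`, `included` (ranked included genes),
#'   `up`, `down`, `threshold`.
#' @export
consistency_ranking <- function(lfc_by_organ, min_mean_abs_lfc = 0.2) {
  stopifnot(length(lfc_by_organ) >= 2)
  if (is.null(names(lfc_by_organ))) {
    names(lfc_by_organ) <- paste0("organ_", seq_along(lfc_by_organ))
  }
  common <- Reduce(intersect, lapply(lfc_by_organ, function(t) t$gene))
  if (length(common) == 0) {
    stop("no gene has a computable fold change in every organ", call. = FALSE)
  }
  common <- sort(common)
  mat <- vapply(lfc_by_organ, function(t) t$lfc[match(common, t$gene)],
                numeric(length(common)))
  mat <- matrix(mat, nrow = length(common),
                dimnames = list(common, names(lfc_by_organ)))
  mean_lfc <- rowMeans(mat)
  keep <- abs(mean_lfc) > min_mean_abs_lfc
  ranked <- names(sort(mean_lfc[keep], decreasing = TRUE))
  structure(
    list(lfc = mat, mean_lfc = mean_lfc, included = ranked,
         up = ranked[mean_lfc[ranked] > 0],
         down = rev(ranked[mean_lfc[ranked] < 0]),
         threshold = min_mean_abs_lfc),
    class = "ConsistencyMatrix"
  )
}

#' @exportS3Method base::print
print.ConsistencyMatrix <- function(x, ...) {
  cat("ConsistencyMatrix:", nrow(x$lfc), "genes x", ncol(x$lfc), "organs;",
      length(x$up), "up and", length(x$down), "down at mean |lfc| >",
      x$threshold, "\n")
  invisible(x)
}
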