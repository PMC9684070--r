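#' Cluster population shifts between two conditions
#'
#' Computes each cluster's fraction of cells within the condition and the
#' control arm, and the log2 ratio of those fractions. Clusters present in
#' only one arm are reported with an undefined (`NA`) ratio and a
#' zero-fraction flag, never dropped. Shifts with |log2 ratio| above the
#' threshold are highlighted, matching the per-figure convention
#' (0.5 for most organs, 0.3 where stated).
#'
#' @param meta per-cell metadata data.frame (or a dataset whose `$meta` is
#'   used) with a `cluster` column.
#' @param condition,control values of `condition_col` defining the two arms
#'   (e.g. `"wd"` vs `"chow"`).
#' @param threshold highlight threshold on |log2 ratio| (default 0.5).
#' @param condition_col metadata column holding the condition (default
#'   `"diet"`).
#' @param cluster_col metadata column holding cluster labels.
#' @return data.frame per cluster: `cluster`, `n_cond`, `n_ctrl`,
#'   `frac_cond`, `frac_ctrl`, `log2_ratio`, `zero_fraction`, `highlight`.
#' @export
population_shifts <- function(meta, condition = "wd", control = "chow",
                              threshold = 0.5, condition_col = "diet",
                              cluster_col = "cluster") {
  if (inherits(meta, c("CellDataset", "NormalizedDataset"))) meta <- meta$meta
  in_cond <- meta[[condition_col]] == condition
  in_ctrl <- meta[[condition_col]] == control
  if (!any(in_cond)) stop("condition '", condition, "' has no cells",
                          call. = FALSE)
  if (!any(in_ctrl)) stop("control '", control, "' has no cells",
                          call. = FALSE)
  clusters <- sort(unique(meta[[cluster_col]][in_cond | in_ctrl]))
  n_cond <- vapply(clusters, function(cl) {
    sum(in_cond & meta[[cluster_col]] == cl)
  }, integer(1))
  n_ctrl <- vapply(clusters, function(cl) {
    sum(in_ctrl & meta[[cluster_col]] == cl)
  }, integer(1))
  frac_cond <- n_cond / sum(n_cond)
  frac_ctrl <- n_ctrl / sum(n_ctrl)
  defined <- frac_cond > 0 & frac_ctrl > 0
  log2_ratio <- ifelse(defined, log2(frac_cond / frac_ctrl), NA_real_)
  data.frame(cluster = clusters, n_cond = n_cond, n_ctrl = n_ctrl,
             frac_cond = frac_cond, frac_ctrl = frac_ctrl,
             log2_ratio = log2_ratio, zero_fraction = !defined,
             highlight = !is.na(log2_ratio) & abs(log2_ratio) > threshold,
             row.names = NULL)
}

#' Pairwise fold-change concordance across organs
#'
#' Collates the union of genes with |lfc| above the gate in any table, then
#' correlates (Pearson) each pair of tables over the universe genes that
#' have a computable fold change in both members of the pair. Pairs sharing
#' fewer than 3 genes get an undefined (`NA`) coefficient.
#'
#' @param tables named list (>= 2) of `DeTable`s, or data.frames with
#'   columns `gene` and `lfc`, all for the same EC population.
#' @param lfc_gate gate on |lfc| used to build the gene universe
#'   (default 0.1).
#' @return List with `r` (correlation matrix), `n` (per-pair gene counts)
#'   and `universe` (the collated gene set).
#' @export
deg_concordance <- function(tables, lfc_gate = 0.1) {
  stopifnot(length(tables) >= 2)
  if (is.null(names(tables))) {
    names(tables) <- paste0("table_", seq_along(tables))
  }
  universe <- sort(unique(unlist(lapply(tables, function(t) {
    t$gene[abs(t$lfc) > lfc_gate]
  }))))
  k <- length(tables)
  lfc <- lapply(tables, function(t) {
    stats::setNames(t$lfc, t$gene)[universe]
  })
  r <- matrix(NA_real_, k, k, dimnames = list(names(tables), names(tables)))
  n <- matrix(0L, k, k, dimnames = dimnames(r))
  for (i in seq_len(k)) {
    for (j in seq_len(i)) {
      both <- !is.na(lfc[[i]]) & !is.na(lfc[[j]])
      n[i, j] <- n[j, i] <- sum(both)
      if (sum(both) >= 3) {
        r[i, j] <- r[j, i] <- stats::cor(lfc[[i]][both], lfc[[j]][both])
      }
    }
  }
  list(r = r, n = n, universe = universe)
}

#' Platelet-positive EC quantification
#'
#' A cell is platelet-positive when any single one of the platelet-specific
#' genes exceeds `min_count` raw UMIs (default 1, i.e. at least 2 counts of
#' Pf4, Ppbp or Nrgn; counts are not summed across the three genes).
#' Genes absent from the dataset are treated as all-zero and reported.
#'
#' @param ds a `CellDataset`.
#' @param genes platelet gene symbols.
#' @param min_count strict per-gene count threshold (default 1).
#' @return List: `fraction`, `flags` (named logical per cell),
#'   `missing_genes`.
#' @export
platelet_positive_fraction <- function(ds,
                                       genes = c("Pf4", "Ppbp", "Nrgn"),
                                       min_count = 1L) {
  if (length(ds$cell_ids) == 0) stop("empty dataset", call. = FALSE)
  present <- intersect(genes, ds$gene_ids)
  if (length(present) == 0) {
    stop("none of the platelet genes (", paste(genes, collapse = ", "),
         ") is present in the dataset", call. = FALSE)
  }
  sub <- ds$counts[, present, drop = FALSE]
  flags <- Matrix::rowSums(sub > min_count) > 0
  names(flags) <- ds$cell_ids
  list(fraction = mean(flags), flags = flags,
       missing_genes = setdiff(genes, present))
}

#' Per-cluster expression z-scores
#'
#' Averages normalized expression per cluster and z-scores each gene's
#' vector of cluster means across clusters (mean 0, sd 1), the
#' transformation used for cluster-level heat maps. The population standard
#' deviation (denominator = number of clusters) is the default; genes
#' constant across clusters get an all-zero row and are flagged.
#'
#' @param nd a `NormalizedDataset`.
#' @param clusters per-cell cluster labels (default the metadata `cluster`
#'   column); at least 2 distinct clusters required.
#' @param sd_type `"population"` (default) or `"sample"` denominator.
#' @return genes x clusters z-score matrix with logical attribute
#'   `"constant"` marking flagged rows.
#' @export
cluster_zscores <- function(nd, clusters = nd$meta$cluster,
                            sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(length(clusters) == length(nd$cell_ids))
  levels <- sort(unique(clusters))
  if (length(levels) < 2) stop("need at least 2 clusters", call. = FALSE)
  means <- vapply(levels, function(cl) {
    Matrix::colMeans(nd$values[clusters == cl, , drop = FALSE])
  }, numeric(length(nd$gene_ids)))
  means <- matrix(means, nrow = length(nd$gene_ids),
                  dimnames = list(nd$gene_ids, levels))
  mu <- rowMeans(means)
  centered <- means - mu
  denom <- if (sd_type == "population") ncol(means) else ncol(means) - 1L
  sd <- sqrt(rowSums(centered^2) / denom)
  constant <- sd == 0
  z <- centered / ifelse(constant, 1, sd)
  z[constant, ] <- 0
  attr(z, "constant") <- constant
  z
}
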