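#' Quality-control parameters
#'
#' Cell-level filters follow the strict inequalities used when curating the
#' EC atlas: cells are removed when they have fewer than `min_genes` or more
#' than `max_genes` uniquely detected genes, more than `max_umi` total UMIs,
#' or a mitochondrial fraction above `max_mito_frac`. Boundary cells (exactly
#' 500 genes, exactly 25,000 UMIs, exactly 20% mitochondrial) are retained.
#' Mitochondrial genes are recognized by the case-sensitive mouse prefix
#' `"mt-"` (e.g. mt-Atp6) by default.
#'
#' @param min_genes minimum detected genes per cell (default 500).
#' @param max_genes maximum detected genes per cell (default 6000).
#' @param max_umi maximum UMI total per cell (default 25000).
#' @param max_mito_frac maximum mitochondrial UMI fraction (default 0.20).
#' @param mito_prefix gene-symbol prefix marking mitochondrial genes.
#' @return A `QcParams` list.
#' @export
qc_params <- function(min_genes = 500L, max_genes = 6000L, max_umi = 25000L,
                      max_mito_frac = 0.20, mito_prefix = "mt-") {
  stopifnot(min_genes < max_genes, max_mito_frac > 0, max_mito_frac <= 1,
            max_umi > 0)
  structure(list(min_genes = as.integer(min_genes),
                 max_genes = as.integer(max_genes),
                 max_umi = as.integer(max_umi),
                 max_mito_frac = max_mito_frac,
                 mito_prefix = mito_prefix),
            class = "QcParams")
}

#' Filter low-quality cells and undetected genes
#'
#' Removes genes with zero total count and cells violating any of the
#' [qc_params()] rules. All cell-level criteria are evaluated on the
#' pre-filter matrix; the gene rule is applied over the retained cells so
#' that removing low-quality cells cannot leave silent all-zero genes
#' behind — applying the filter twice therefore removes nothing on the
#' second pass. The report counts removals per rule; a cell violating
#' several rules is counted under each.
#'
#' @param ds a `CellDataset`.
#' @param params a `QcParams` object.
#' @return List with elements `dataset` (the filtered `CellDataset`) and
#'   `report` (data.frame of rule, n_removed).
#' @export
qc_filter <- function(ds, params = qc_params()) {
  counts <- ds$counts
  n_detected <- Matrix::rowSums(counts > 0)
  umi <- Matrix::rowSums(counts)
  mito_genes <- startsWith(ds$gene_ids, params$mito_prefix)
  mito_umi <- if (any(mito_genes)) {
    Matrix::rowSums(counts[, mito_genes, drop = FALSE])
  } else {
    rep(0, nrow(counts))
  }
  mito_frac <- ifelse(umi > 0, mito_umi / umi, 0)

  low_genes <- n_detected < params$min_genes
  high_genes <- n_detected > params$max_genes
  high_umi <- umi > params$max_umi
  high_mito <- mito_frac > params$max_mito_frac
  drop_cell <- low_genes | high_genes | high_umi | high_mito
  gene_zero <- Matrix::colSums(counts[!drop_cell, , drop = FALSE]) == 0

  report <- data.frame(
    rule = c("gene_zero_count", "cell_low_genes", "cell_high_genes",
             "cell_high_umi", "cell_high_mito", "cells_removed_total"),
    n_removed = c(sum(gene_zero), sum(low_genes), sum(high_genes),
                  sum(high_umi), sum(high_mito), sum(drop_cell))
  )
  if (all(drop_cell)) {
    stop("empty after QC: all ", nrow(counts), " cells removed", call. = FALSE)
  }
  out <- subset_cells(ds, cells = which(!drop_cell), genes = which(!gene_zero))
  list(dataset = out, report = report)
}

#' Library-size log-normalization
#'
#' Computes `value[c, g] = ln(1 + count[c, g] / libsize[c] * scale_factor)`
#' with the per-cell UMI total as library size. With the default scale
#' factor of 10,000 this is the standard log-normalization of UMI data on
#' the natural-log scale; the zero pattern of the counts is preserved
#' exactly.
#'
#' @param ds a `CellDataset` that has passed QC (no zero-library cells).
#' @param scale_factor positive scaling constant (default 1e4).
#' @return A `NormalizedDataset` with fields `values` (sparse cells x genes),
#'   `scale_factor`, `gene_ids`, `cell_ids`, `meta`, `provenance`.
#' @export
normalize_dataset <- function(ds, scale_factor = 1e4) {
  stopifnot(scale_factor > 0)
  libsize <- Matrix::rowSums(ds$counts)
  if (any(libsize == 0)) {
    stop(sum(libsize == 0), " cell(s) with zero library size; ",
         "run qc_filter() first", call. = FALSE)
  }
  values <- Matrix::Diagonal(x = scale_factor / libsize) %*% ds$counts
  values <- methods::as(values, "CsparseMatrix")
  values@x <- log1p(values@x)
  dimnames(values) <- list(ds$cell_ids, ds$gene_ids)
  structure(
    list(values = values, scale_factor = scale_factor,
         gene_ids = ds$gene_ids, cell_ids = ds$cell_ids, meta = ds$meta,
         provenance = list(n_cells = nrow(ds$counts),
                           n_genes = ncol(ds$counts),
                           total_umi = sum(libsize))),
    class = "NormalizedDataset"
  )
}

#' @exportS3Method base::print
print.NormalizedDataset <- function(x, ...) {
  cat("NormalizedDataset:", length(x$cell_ids), "cells x",
      length(x$gene_ids), "genes; ln(1 + count/libsize *",
      format(x$scale_factor), ")\n")
  invisible(x)
}

#' Default EC marker panels
#'
#' Subtype marker panels for arterial-arteriolar (art), capillary (cap) and
#' venous-venular (ven) endothelial cells, plus the pan-EC gate and the
#' platelet-contamination triple. Organ-specific extensions can be supplied
#' by appending genes to the returned lists.
#'
#' @return Named list of character vectors.
#' @export
default_marker_panels <- function() {
  list(art = c("Fbln5", "Gkn3", "Hey1", "Mgp"),
       cap = c("Car4", "Rgcc"),
       ven = c("Vcam1", "Vwf"))
}

#' Pan-EC gate and platelet marker genes
#' @return Named list with `ec` and `platelet` gene vectors.
#' @export
auxiliary_marker_genes <- function() {
  list(ec = c("Pecam1", "Cdh5", "Flt1"),
       platelet = c("Pf4", "Ppbp", "Nrgn"))
}

#' Assign EC subtypes from marker panels
#'
#' Scores each cell against each panel as the mean normalized expression of
#' the panel's genes present in the dataset and labels the cell with the
#' highest-scoring panel. Ties are broken by panel order and flagged. When
#' cluster labels are supplied, each cluster is instead labelled by the
#' majority vote of its cells' per-cell calls (ties again by panel order).
#'
#' @param nd a `NormalizedDataset`.
#' @param panels named list of marker gene vectors
#'   (default [default_marker_panels()]).
#' @param clusters optional per-cell cluster labels for majority voting.
#' @return data.frame with columns `cell_id`, `subtype`, `tie`, and one
#'   score column per panel.
#' @export
annotate_subtypes <- function(nd, panels = default_marker_panels(),
                              clusters = NULL) {
  stopifnot(length(panels) >= 1, !is.null(names(panels)))
  for (nm in names(panels)) {
    if (anyDuplicated(panels[[nm]]))
      stop("duplicate gene in panel '", nm, "'", call. = FALSE)
  }
  present <- lapply(panels, intersect, nd$gene_ids)
  if (all(lengths(present) == 0)) {
    stop("no marker-panel gene present in the dataset", call. = FALSE)
  }
  scores <- vapply(present, function(g) {
    if (length(g) == 0) return(rep(-Inf, length(nd$cell_ids)))
    Matrix::rowMeans(nd$values[, g, drop = FALSE])
  }, numeric(length(nd$cell_ids)))
  scores <- matrix(scores, nrow = length(nd$cell_ids),
                   dimnames = list(nd$cell_ids, names(panels)))
  best <- apply(scores, 1L, max)
  tie <- rowSums(scores == best) > 1L
  label <- names(panels)[apply(scores == best, 1L, which.max)]
  if (!is.null(clusters)) {
    stopifnot(length(clusters) == length(label))
    for (cl in unique(clusters)) {
      idx <- clusters == cl
      tab <- table(factor(label[idx], levels = names(panels)))
      label[idx] <- names(panels)[which.max(tab)]
      tie[idx] <- sum(tab == max(tab)) > 1L
    }
  }
  out <- data.frame(cell_id = nd$cell_ids, subtype = label, tie = tie,
                    row.names = NULL)
  cbind(out, as.data.frame(scores, row.names = NULL))
}
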