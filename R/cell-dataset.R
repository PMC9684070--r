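#' Single-cell count dataset with study metadata
#'
#' A `CellDataset` binds a sparse non-negative integer count matrix
#' (cells x genes) to per-cell metadata describing the study design:
#' organ of origin, cluster/subtype label, diet arm (`chow`, `wd`, `rev`),
#' timepoint in months, and animal of origin. The reversion arm exists only
#' at the 4- and 6-month timepoints, mirroring a design in which animals are
#' switched from a Western diet back to chow after 3 months.
#'
#' @param counts sparse or dense non-negative integer matrix, cells x genes.
#' @param gene_ids character vector of unique gene symbols (columns).
#' @param cell_ids character vector of unique cell barcodes (rows).
#' @param meta data.frame with one row per cell and columns `barcode`,
#'   `organ`, `cluster`, `diet`, `timepoint_months`, `animal`.
#' @return An object of class `CellDataset`.
#' @export
cell_dataset <- function(counts, gene_ids, cell_ids, meta) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  ds <- structure(
    list(counts = counts, gene_ids = as.character(gene_ids),
         cell_ids = as.character(cell_ids), meta = as.data.frame(meta)),
    class = "CellDataset"
  )
  validate_cell_dataset(ds)
  dimnames(ds$counts) <- list(ds$cell_ids, ds$gene_ids)
  ds
}

DIETS <- c("chow", "wd", "rev")
TIMEPOINTS <- c(3L, 4L, 6L)
REV_TIMEPOINTS <- c(4L, 6L)

META_COLS <- c("barcode", "organ", "cluster", "diet", "timepoint_months",
               "animal")

validate_cell_dataset <- function(ds) {
  counts <- ds$counts
  if (nrow(counts) != length(ds$cell_ids) ||
      ncol(counts) != length(ds$gene_ids)) {
    stop("counts dimensions (", nrow(counts), " x ", ncol(counts),
         ") do not match cell_ids/gene_ids lengths (",
         length(ds$cell_ids), " x ", length(ds$gene_ids), ")", call. = FALSE)
  }
  if (anyDuplicated(ds$gene_ids)) stop("gene_ids must be unique", call. = FALSE)
  if (anyDuplicated(ds$cell_ids)) stop("cell_ids must be unique", call. = FALSE)
  check_count_values(counts)
  meta <- ds$meta
  missing_cols <- setdiff(META_COLS, names(meta))
  if (length(missing_cols)) {
    stop("metadata lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(ds$cell_ids, meta$barcode)
  if (length(absent)) {
    stop("barcode(s) in matrix absent from metadata: ",
         paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(meta$barcode)) {
    stop("duplicated barcode(s) in metadata", call. = FALSE)
  }
  bad_diet <- setdiff(unique(meta$diet), DIETS)
  if (length(bad_diet)) {
    stop("unknown diet label(s): ", paste(bad_diet, collapse = ", "),
         " (expected ", paste(DIETS, collapse = "/"), ")", call. = FALSE)
  }
  tp <- meta$timepoint_months
  if (!all(tp %in% TIMEPOINTS)) {
    stop("timepoint_months must be one of ",
         paste(TIMEPOINTS, collapse = ", "), call. = FALSE)
  }
  bad_rev <- meta$diet == "rev" & !(tp %in% REV_TIMEPOINTS)
  if (any(bad_rev)) {
    stop("reversion cells at disallowed timepoint(s): ",
         paste(unique(tp[bad_rev]), collapse = ", "),
         " (rev exists only at ", paste(REV_TIMEPOINTS, collapse = ", "),
         " months)", call. = FALSE)
  }
  invisible(ds)
}

# Reject non-integer or negative entries, naming the first offending
# coordinate in cells x genes orientation.
check_count_values <- function(counts) {
  tm <- methods::as(counts, "TsparseMatrix")
  bad <- which(tm@x < 0 | tm@x != round(tm@x))
  if (length(bad)) {
    b <- bad[[1L]]
    stop("count matrix entry at (cell ", tm@i[b] + 1L, ", gene ",
         tm@j[b] + 1L, ") is ", tm@x[b],
         ": entries must be non-negative integers", call. = FALSE)
  }
  invisible(TRUE)
}

#' @exportS3Method base::print
print.CellDataset <- function(x, ...) {
  cat("CellDataset:", length(x$cell_ids), "cells x", length(x$gene_ids),
      "genes\n")
  cat("  organs:    ", paste(sort(unique(x$meta$organ)), collapse = ", "),
      "\n")
  cat("  clusters:  ", paste(sort(unique(x$meta$cluster)), collapse = ", "),
      "\n")
  arms <- unique(x$meta[, c("diet", "timepoint_months")])
  arms <- arms[order(arms$diet, arms$timepoint_months), ]
  cat("  diet arms: ",
      paste(sprintf("%s@%dmo", arms$diet, arms$timepoint_months),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.CellDataset <- function(x) dim(x$counts)

#' Subset a CellDataset by cell and/or gene indices
#'
#' @param ds a `CellDataset`.
#' @param cells,genes integer, logical or character indices; `NULL` keeps all.
#' @return A `CellDataset` restricted to the selection.
#' @export
subset_cells <- function(ds, cells = NULL, genes = NULL) {
  if (is.null(cells)) cells <- seq_along(ds$cell_ids)
  if (is.null(genes)) genes <- seq_along(ds$gene_ids)
  if (is.character(cells)) cells <- match(cells, ds$cell_ids)
  if (is.character(genes)) genes <- match(genes, ds$gene_ids)
  meta <- ds$meta[match(ds$cell_ids[cells], ds$meta$barcode), , drop = FALSE]
  rownames(meta) <- NULL
  cell_dataset(ds$counts[cells, genes, drop = FALSE],
               ds$gene_ids[genes], ds$cell_ids[cells], meta)
}

#' Select cell indices by design variables
#'
#' @param meta a per-cell metadata data.frame (or a `CellDataset` /
#'   `NormalizedDataset`, whose `$meta` is used).
#' @param organ,cluster,diet,timepoint optional filters; `NULL` means no
#'   restriction.
#' @return Integer vector of matching cell (row) indices.
#' @export
cells_where <- function(meta, organ = NULL, cluster = NULL, diet = NULL,
                        timepoint = NULL) {
  if (inherits(meta, c("CellDataset", "NormalizedDataset"))) meta <- meta$meta
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(organ)) keep <- keep & meta$organ %in% organ
  if (!is.null(cluster)) keep <- keep & meta$cluster %in% cluster
  if (!is.null(diet)) keep <- keep & meta$diet %in% diet
  if (!is.null(timepoint)) keep <- keep & meta$timepoint_months %in% timepoint
  which(keep)
}

#' Read a 10x-style triplet dataset plus cell metadata
#'
#' Expects a Matrix Market coordinate matrix, one-symbol-per-line gene and
#' barcode files, and a tab-separated metadata table keyed by barcode. The
#' on-disk matrix may be oriented either features x cells (the CellRanger
#' convention) or cells x genes; orientation is detected from the gene and
#' barcode counts and normalized to cells x genes in memory.
#'
#' @param matrix_path path to `matrix.mtx`.
#' @param genes_path path to `features.tsv` (one gene symbol per line).
#' @param barcodes_path path to `barcodes.tsv` (one barcode per line).
#' @param meta_path path to `cell_metadata.tsv` (header with columns
#'   `barcode`, `organ`, `cluster`, `diet`, `timepoint_months`, `animal`).
#' @return A validated `CellDataset`.
#' @export
read_dataset <- function(matrix_path, genes_path, barcodes_path, meta_path) {
  for (p in c(matrix_path, genes_path, barcodes_path, meta_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  m <- Matrix::readMM(matrix_path)
  genes <- readLines(genes_path)
  barcodes <- readLines(barcodes_path)
  genes <- genes[nzchar(genes)]
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(m) == length(genes) && ncol(m) == length(barcodes)) {
    m <- Matrix::t(m)              # features x cells on disk -> transpose
  } else if (!(nrow(m) == length(barcodes) && ncol(m) == length(genes))) {
    stop("matrix dimensions (", nrow(m), " x ", ncol(m),
         ") match neither genes x barcodes (", length(genes), " x ",
         length(barcodes), ") nor barcodes x genes", call. = FALSE)
  }
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  absent <- setdiff(barcodes, meta$barcode)
  if (length(absent)) {
    stop("barcode(s) in matrix absent from metadata: ",
         paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
  }
  meta <- meta[match(barcodes, meta$barcode), , drop = FALSE]
  rownames(meta) <- NULL
  cell_dataset(m, genes, barcodes, meta)
}

#' Write a CellDataset as a 10x-style triplet plus metadata
#'
#' Emits `matrix.mtx` (coordinate integer, features x cells as CellRanger
#' writes), `features.tsv`, `barcodes.tsv` and `cell_metadata.tsv` such that
#' [read_dataset()] reproduces the dataset exactly.
#'
#' @param ds a `CellDataset`.
#' @param out_dir output directory, created if absent.
#' @return Named character vector of the four paths written, invisibly.
#' @export
write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir,
                                 call. = FALSE)
  paths <- c(matrix = file.path(out_dir, "matrix.mtx"),
             genes = file.path(out_dir, "features.tsv"),
             barcodes = file.path(out_dir, "barcodes.tsv"),
             meta = file.path(out_dir, "cell_metadata.tsv"))
  write_mtx_integer(Matrix::t(ds$counts), paths[["matrix"]])
  writeLines(ds$gene_ids, paths[["genes"]])
  writeLines(ds$cell_ids, paths[["barcodes"]])
  utils::write.table(ds$meta, paths[["meta"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

# Matrix Market coordinate *integer* dialect (as CellRanger emits);
# Matrix::writeMM would declare the values real.
write_mtx_integer <- function(m, path) {
  tm <- methods::as(m, "TsparseMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               paste(nrow(m), ncol(m), length(tm@x))), con)
  if (length(tm@x)) {
    ord <- order(tm@j, tm@i)
    writeLines(paste(tm@i[ord] + 1L, tm@j[ord] + 1L,
                     format(tm@x[ord], scientific = FALSE, trim = TRUE)),
               con)
  }
  invisible(path)
}
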