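#' Read and filter a GWAS-catalog-style export
#'
#' Reads a tab-separated catalog with SNP id, mapped gene(s), association
#' p-value and trait columns, keeps records with `p <= p_max` (default
#' 1e-5, the conventional suggestive-association cutoff), expands rows
#' listing several genes (separated by `;` or `,`) to one record per gene,
#' and drops rows whose p-value does not parse, counting them. Catalog
#' exports differ on which gene field to use, so the gene column name is
#' configurable and defaults to the mapped-gene column.
#'
#' @param path TSV path with a header.
#' @param p_max retention threshold on the association p-value.
#' @param gene_col name of the gene column (default `"mapped_gene"`).
#' @param snp_col,p_col,trait_col remaining column names.
#' @return A `GwasCatalog` data.frame (`snp_id`, `gene`, `p_value`,
#'   `trait`), with attributes `n_dropped_unparseable` and `p_max`.
#' @export
read_gwas_catalog <- function(path, p_max = 1e-5, gene_col = "mapped_gene",
                              snp_col = "snp_id", p_col = "p_value",
                              trait_col = "trait") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c(snp_col, gene_col, p_col, trait_col)
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("GWAS catalog lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  p <- suppressWarnings(as.numeric(raw[[p_col]]))
  unparseable <- is.na(p)
  keep <- !unparseable & p <= p_max
  raw <- raw[keep, , drop = FALSE]
  p <- p[keep]
  gene_lists <- strsplit(raw[[gene_col]], "[;,]")
  n_per_row <- lengths(gene_lists)
  out <- data.frame(
    snp_id = rep(raw[[snp_col]], n_per_row),
    gene = trimws(unlist(gene_lists)),
    p_value = rep(p, n_per_row),
    trait = rep(raw[[trait_col]], n_per_row),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[nzchar(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_unparseable") <- sum(unparseable)
  attr(out, "p_max") <- p_max
  class(out) <- c("GwasCatalog", "data.frame")
  out
}

#' Map human gene symbols to mouse symbols
#'
#' Uses an explicit ortholog table (`human_symbol`, `mouse_symbol`) when one
#' is provided; symbols without a table entry fall back to the
#' capitalization heuristic (APOE -> Apoe). When a `target_genes` universe
#' is supplied (typically the DE table's genes), a heuristic mapping that
#' does not occur in the universe is treated as unmapped; table entries are
#' accepted as-is. Unmapped symbols are listed, never silently dropped.
#'
#' @param human_symbols character vector of human gene symbols.
#' @param ortholog_table optional data.frame with columns `human_symbol`,
#'   `mouse_symbol`; duplicate conflicting entries are an error.
#' @param target_genes optional mouse gene universe for validating
#'   heuristic mappings.
#' @return List: `mapping` (named character, human -> mouse) and `unmapped`.
#' @export
map_orthologs <- function(human_symbols, ortholog_table = NULL,
                          target_genes = NULL) {
  human_symbols <- unique(human_symbols)
  table_map <- character(0)
  if (!is.null(ortholog_table)) {
    stopifnot(all(c("human_symbol", "mouse_symbol") %in%
                    names(ortholog_table)))
    dup <- unique(ortholog_table$human_symbol[
      duplicated(ortholog_table$human_symbol)])
    conflicting <- dup[vapply(dup, function(h) {
      length(unique(ortholog_table$mouse_symbol[
        ortholog_table$human_symbol == h])) > 1
    }, logical(1))]
    if (length(conflicting)) {
      stop("conflicting ortholog entries for: ",
           paste(conflicting, collapse = ", "), call. = FALSE)
    }
    table_map <- stats::setNames(ortholog_table$mouse_symbol,
                                 ortholog_table$human_symbol)
  }
  heuristic <- function(s) {
    paste0(toupper(substr(s, 1, 1)), tolower(substr(s, 2, nchar(s))))
  }
  mapping <- character(0)
  unmapped <- character(0)
  for (h in human_symbols) {
    if (h %in% names(table_map)) {
      mapping[h] <- table_map[[h]]
    } else {
      m <- heuristic(h)
      if (is.null(target_genes) || m %in% target_genes) {
        mapping[h] <- m
      } else {
        unmapped <- c(unmapped, h)
      }
    }
  }
  list(mapping = mapping, unmapped = unmapped)
}

#' Join obesity DEGs with GWAS-catalog risk genes
#'
#' For one trait, aggregates each catalog gene's qualifying SNPs to the
#' minimum association p-value (the strongest association, one point per
#' gene), maps human symbols to mouse, joins on the DE table's genes, and
#' highlights genes with |lfc| above the threshold — the risk-gene
#' dot-plot table (x = -log10 p, y = log fold change in obesity).
#'
#' @param catalog a [read_gwas_catalog()] result (already filtered at
#'   `p <= p_max`).
#' @param de a `DeTable` for one contrast (conventionally WD vs chow at the
#'   6-month timepoint).
#' @param trait trait label; must match catalog records exactly (child
#'   traits are excluded upstream by supplying the exact parent-trait
#'   label).
#' @param lfc_highlight highlight threshold on |lfc| (default 0.1, strict).
#' @param ortholog_table optional ortholog table for [map_orthologs()].
#' @return A `RiskGeneTable` data.frame: `human_symbol`, `mouse_symbol`,
#'   `trait`, `min_p`, `neg_log10_p`, `lfc`, `highlighted`; attributes
#'   `n_not_in_de` and `unmapped` record the genes that did not join.
#' @export
link_degs_to_gwas <- function(catalog, de, trait, lfc_highlight = 0.1,
                              ortholog_table = NULL) {
  rows <- catalog[catalog$trait == trait, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop("trait absent from catalog: ", trait, call. = FALSE)
  }
  min_p <- tapply(rows$p_value, rows$gene, min)
  human <- names(min_p)
  orth <- map_orthologs(human, ortholog_table = ortholog_table,
                        target_genes = de$gene)
  mapped_h <- names(orth$mapping)
  mouse <- unname(orth$mapping)
  in_de <- mouse %in% de$gene
  out <- data.frame(
    human_symbol = mapped_h[in_de],
    mouse_symbol = mouse[in_de],
    trait = trait,
    min_p = unname(min_p[mapped_h[in_de]]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$neg_log10_p <- -log10(out$min_p)
  out$lfc <- de$lfc[match(out$mouse_symbol, de$gene)]
  out$highlighted <- abs(out$lfc) > lfc_highlight
  out <- out[order(out$min_p, out$mouse_symbol), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_not_in_de") <- sum(!in_de)
  attr(out, "unmapped") <- orth$unmapped
  class(out) <- c("RiskGeneTable", "data.frame")
  out
}
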