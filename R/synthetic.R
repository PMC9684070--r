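#' Configuration for the synthetic EC atlas generator
#'
#' Describes a multi-organ, multi-subtype, multi-diet single-cell experiment
#' with planted, recoverable effect structure. Counts are negative-binomial
#' with log-normal per-gene base means and log-normal library-size factors;
#' a configurable fraction of genes per organ x subtype carries a planted
#' diet effect (half up, half down), of which a configurable fraction
#' reverts under the reversion diet. Marker genes are fold-enriched in their
#' own subtype and a fixed fraction of cells receives a platelet-gene spike.
#'
#' The diet arms follow the study design: chow and Western diet (wd) at
#' every requested timepoint, reversion (rev) only at 4 and 6 months.
#'
#' @param organs organ labels (default three organs; the full design used
#'   seven).
#' @param subtypes EC subtype labels (default art/cap/ven).
#' @param timepoints timepoints in months, subset of {3, 4, 6}.
#' @param cells_per_group cells per organ x subtype x diet x timepoint
#'   group: a single integer or a named vector keyed by organ.
#' @param n_genes total genes, including marker and platelet genes.
#' @param baseline_log_mean numeric `(location, scale)` of the log-normal
#'   over per-gene base mean counts.
#' @param dispersion negative-binomial shape parameter theta
#'   (variance = m + m^2/theta).
#' @param libsize_log_sd sd of log library-size factors.
#' @param frac_de fraction of genes with a planted diet effect per
#'   organ x subtype.
#' @param effect_size_lfc `(low, high)` range of planted |natural-log|
#'   effects.
#' @param frac_restored fraction of planted DE genes whose effect reverts
#'   under the reversion diet.
#' @param restored_gamma residual effect fraction for restored genes under
#'   rev (0 = full reversion; values in (0, 1) plant partial restoration).
#' @param marker_panels named list of subtype marker genes.
#' @param marker_base_mean base mean count of marker genes outside their own
#'   subtype (fixed, not drawn: canonical markers are reliably expressed).
#' @param marker_fold fold-enrichment of marker genes in their own subtype.
#' @param platelet_spike list with `genes` (triple), `fraction` of cells
#'   spiked (assigned by exact count, not Bernoulli), and `level` (UMI count
#'   assigned, >= 2 so spiked cells satisfy the ">1 count" criterion).
#' @param animals_per_group animals cycled through each group's cells.
#' @param planted_effects optional explicit effect table with columns
#'   `organ`, `subtype`, `gene`, `planted_lfc`, `is_restored`, overriding
#'   random planting for the organ x subtype combinations it covers.
#' @param seed integer seed; generation is bit-reproducible given the
#'   configuration.
#' @return A `SynthConfig` list.
#' @export
synth_config <- function(organs = c("liver", "heart", "kidney"),
                         subtypes = c("art", "cap", "ven"),
                         timepoints = c(3L, 4L, 6L),
                         cells_per_group = 150L,
                         n_genes = 1000L,
                         baseline_log_mean = c(location = log(0.2), scale = 1),
                         dispersion = 2,
                         libsize_log_sd = 0.3,
                         frac_de = 0.1,
                         effect_size_lfc = c(0.5, 1),
                         frac_restored = 0.7,
                         restored_gamma = 0,
                         marker_panels = default_marker_panels(),
                         marker_base_mean = 1,
                         marker_fold = 10,
                         platelet_spike = list(genes = c("Pf4", "Ppbp", "Nrgn"),
                                               fraction = 0.05, level = 3L),
                         animals_per_group = 3L,
                         planted_effects = NULL,
                         seed = 1L) {
  stopifnot(length(organs) >= 1, length(subtypes) >= 1,
            all(timepoints %in% TIMEPOINTS),
            frac_de >= 0, frac_de <= 1,
            frac_restored >= 0, frac_restored <= 1,
            restored_gamma >= 0, restored_gamma <= 1,
            length(effect_size_lfc) == 2, all(effect_size_lfc > 0),
            effect_size_lfc[1] <= effect_size_lfc[2],
            dispersion > 0, libsize_log_sd >= 0, marker_fold >= 1,
            marker_base_mean > 0,
            platelet_spike$fraction >= 0, platelet_spike$fraction <= 1,
            platelet_spike$level >= 2)
  if (is.null(names(cells_per_group))) {
    cells_per_group <- stats::setNames(rep(as.integer(cells_per_group),
                                           length(organs)), organs)
  }
  if (!all(organs %in% names(cells_per_group)) || any(cells_per_group < 2)) {
    stop("cells_per_group must cover every organ with values >= 2",
         call. = FALSE)
  }
  cfg <- structure(
    list(organs = organs, subtypes = subtypes,
         timepoints = sort(as.integer(timepoints)),
         cells_per_group = cells_per_group,
         n_genes = as.integer(n_genes),
         baseline_log_mean = baseline_log_mean, dispersion = dispersion,
         libsize_log_sd = libsize_log_sd, frac_de = frac_de,
         effect_size_lfc = effect_size_lfc, frac_restored = frac_restored,
         restored_gamma = restored_gamma, marker_panels = marker_panels,
         marker_base_mean = marker_base_mean, marker_fold = marker_fold,
         platelet_spike = platelet_spike,
         animals_per_group = as.integer(animals_per_group),
         planted_effects = planted_effects, seed = as.integer(seed)),
    class = "SynthConfig"
  )
  if (n_genes <= length(synth_reserved_genes(cfg))) {
    stop("n_genes too small for the marker and platelet genes", call. = FALSE)
  }
  cfg
}

synth_reserved_genes <- function(cfg) {
  unique(c(unlist(cfg$marker_panels[cfg$subtypes], use.names = FALSE),
           cfg$platelet_spike$genes))
}

#' Gene identifiers a configuration will generate
#'
#' Marker and platelet genes first, then numbered filler genes, in the exact
#' order [generate_dataset()] emits them. Deterministic and RNG-free, so
#' explicit `planted_effects` tables can be built before generating.
#'
#' @param cfg a `SynthConfig`.
#' @return Character vector of length `cfg$n_genes`.
#' @export
synth_gene_ids <- function(cfg) {
  reserved <- synth_reserved_genes(cfg)
  n_fill <- cfg$n_genes - length(reserved)
  c(reserved, sprintf("g%05d", seq_len(n_fill)))
}

# Diet arms of the study design restricted to the configured timepoints.
synth_arms <- function(cfg) {
  arms <- expand.grid(diet = DIETS, timepoint = cfg$timepoints,
                      stringsAsFactors = FALSE)
  arms <- arms[!(arms$diet == "rev" & !(arms$timepoint %in% REV_TIMEPOINTS)), ]
  arms[order(match(arms$diet, DIETS), arms$timepoint), , drop = FALSE]
}

# Random effect table for one organ x subtype: exact counts per direction
# and per restoration class, magnitudes uniform over the configured range.
plant_random_effects <- function(cfg, eligible_genes) {
  n_de <- round(cfg$frac_de * cfg$n_genes)
  if (n_de > length(eligible_genes)) {
    stop("frac_de requires ", n_de, " DE genes but only ",
         length(eligible_genes), " non-marker genes are available",
         call. = FALSE)
  }
  genes <- sample(eligible_genes, n_de)
  n_up <- ceiling(n_de / 2)
  sign <- rep(c(1, -1), c(n_up, n_de - n_up))
  mag <- stats::runif(n_de, cfg$effect_size_lfc[1], cfg$effect_size_lfc[2])
  restored <- logical(n_de)
  restored[seq_len(n_up)][seq_len(round(cfg$frac_restored * n_up))] <- TRUE
  n_down <- n_de - n_up
  if (n_down > 0) {
    restored[n_up + seq_len(n_down)][
      seq_len(round(cfg$frac_restored * n_down))] <- TRUE
  }
  data.frame(gene = genes, planted_lfc = sign * mag, is_restored = restored,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic EC dataset with known truth
#'
#' Draws negative-binomial counts
#' `NB(mean = base_mean x libsize_factor x marker_mult x exp(effect))`,
#' where the planted effect applies under the Western diet and, for
#' persistent genes, under the reversion diet (restored genes keep
#' `restored_gamma` x effect under rev). Marker genes are multiplied by
#' `marker_fold` in their own subtype; platelet genes are zero except in the
#' exact fraction of spiked cells, which receive `level` counts of one
#' platelet gene (round-robin over the triple). Generation is deterministic
#' given the configuration, and the truth tables share the dataset's gene
#' and cell orderings.
#'
#' @param cfg a [synth_config()] object.
#' @return List with `dataset` (a `CellDataset`) and `truth` (a
#'   `SynthTruth`: `$effects` per organ x subtype x gene, `$cells` per cell).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"))
  set.seed(cfg$seed)
  genes <- synth_gene_ids(cfg)
  n_genes <- length(genes)
  platelet <- cfg$platelet_spike$genes
  base_mean <- stats::rlnorm(n_genes, cfg$baseline_log_mean[[1]],
                             cfg$baseline_log_mean[[2]])
  names(base_mean) <- genes
  marker_genes <- unlist(cfg$marker_panels[cfg$subtypes], use.names = FALSE)
  base_mean[intersect(marker_genes, genes)] <- cfg$marker_base_mean
  base_mean[platelet] <- 0   # ECs do not express platelet genes; spike only
  eligible <- setdiff(genes, synth_reserved_genes(cfg))

  effects <- list()
  for (organ in cfg$organs) {
    for (st in cfg$subtypes) {
      eff <- NULL
      if (!is.null(cfg$planted_effects)) {
        pe <- cfg$planted_effects
        eff <- pe[pe$organ == organ & pe$subtype == st,
                  c("gene", "planted_lfc", "is_restored"), drop = FALSE]
        if (nrow(eff) == 0) eff <- NULL
      }
      if (is.null(eff) && is.null(cfg$planted_effects)) {
        eff <- plant_random_effects(cfg, eligible)
      }
      if (is.null(eff)) {
        eff <- data.frame(gene = character(), planted_lfc = numeric(),
                          is_restored = logical())
      }
      if (!all(eff$gene %in% genes)) {
        stop("planted_effects names gene(s) absent from the gene list",
             call. = FALSE)
      }
      effects[[paste(organ, st, sep = ".")]] <-
        if (nrow(eff)) {
          cbind(organ = organ, subtype = st, eff)
        } else {
          data.frame(organ = character(), subtype = character(),
                     gene = character(), planted_lfc = numeric(),
                     is_restored = logical())
        }
    }
  }

  arms <- synth_arms(cfg)
  blocks <- list()
  meta <- list()
  cell_truth <- list()
  for (organ in cfg$organs) {
    n_cells <- cfg$cells_per_group[[organ]]
    for (st in cfg$subtypes) {
      eff <- effects[[paste(organ, st, sep = ".")]]
      lfc <- stats::setNames(rep(0, n_genes), genes)
      restored <- stats::setNames(rep(FALSE, n_genes), genes)
      lfc[eff$gene] <- eff$planted_lfc
      restored[eff$gene] <- eff$is_restored
      mu_base <- base_mean
      own_markers <- intersect(cfg$marker_panels[[st]], genes)
      mu_base[own_markers] <- mu_base[own_markers] * cfg$marker_fold
      for (a in seq_len(nrow(arms))) {
        diet <- arms$diet[a]
        tp <- arms$timepoint[a]
        effect_mult <- rep(1, n_genes)
        if (diet == "wd") {
          effect_mult <- exp(lfc)
        } else if (diet == "rev") {
          effect_mult <- ifelse(restored, exp(cfg$restored_gamma * lfc),
                                exp(lfc))
        }
        mu <- mu_base * effect_mult
        libfac <- exp(stats::rnorm(n_cells, 0, cfg$libsize_log_sd))
        counts <- matrix(
          stats::rnbinom(n_cells * n_genes, size = cfg$dispersion,
                         mu = libfac %o% mu),
          nrow = n_cells
        )
        n_spike <- round(cfg$platelet_spike$fraction * n_cells)
        spiked <- rep(FALSE, n_cells)
        if (n_spike > 0) {
          spiked[seq_len(n_spike)] <- TRUE
          pg_idx <- match(platelet, genes)
          which_gene <- pg_idx[((seq_len(n_spike) - 1L) %% length(pg_idx)) + 1L]
          counts[cbind(seq_len(n_spike), which_gene)] <- cfg$platelet_spike$level
        }
        ids <- sprintf("%s|%s|%s%d|c%04d", organ, st, diet, tp,
                       seq_len(n_cells))
        blocks[[length(blocks) + 1L]] <-
          methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
        meta[[length(meta) + 1L]] <- data.frame(
          barcode = ids, organ = organ, cluster = st, diet = diet,
          timepoint_months = tp,
          animal = sprintf("%s_%s%d_a%d", organ, diet, tp,
                           ((seq_len(n_cells) - 1L) %%
                              cfg$animals_per_group) + 1L),
          stringsAsFactors = FALSE
        )
        cell_truth[[length(cell_truth) + 1L]] <- data.frame(
          cell_id = ids, true_subtype = st, platelet_positive = spiked,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  counts <- do.call(rbind, blocks)
  meta <- do.call(rbind, meta)
  cell_truth <- do.call(rbind, cell_truth)
  rownames(meta) <- rownames(cell_truth) <- NULL

  effect_rows <- do.call(rbind, lapply(names(effects), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    eff <- effects[[key]]
    full <- data.frame(organ = parts[1], subtype = parts[2], gene = genes,
                       planted_lfc = 0, is_de = FALSE, is_restored = FALSE,
                       stringsAsFactors = FALSE)
    i <- match(eff$gene, genes)
    full$planted_lfc[i] <- eff$planted_lfc
    full$is_de[i] <- eff$planted_lfc != 0
    full$is_restored[i] <- eff$is_restored & eff$planted_lfc != 0
    full
  }))
  rownames(effect_rows) <- NULL

  dataset <- cell_dataset(counts, genes, meta$barcode, meta)
  truth <- structure(list(effects = effect_rows, cells = cell_truth,
                          config = cfg),
                     class = "SynthTruth")
  list(dataset = dataset, truth = truth)
}

#' @exportS3Method base::print
print.SynthTruth <- function(x, ...) {
  cat("SynthTruth:", nrow(x$cells), "cells;",
      sum(x$effects$is_de), "planted DE gene records (",
      sum(x$effects$is_restored), "restored )\n")
  invisible(x)
}

#' Empirical group log fold change against the planted truth
#'
#' Normalizes the raw counts and returns the natural log of the ratio of
#' group-mean de-logged expression, Western diet vs chow, within one
#' organ x subtype (no pseudocount, so the estimate is directly comparable
#' to the planted effect). Intended as a recovery check for the generator.
#'
#' @param ds a `CellDataset` from [generate_dataset()].
#' @param truth the matching `SynthTruth`.
#' @param organ,subtype group selector (subtype refers to the true label).
#' @param gene gene symbol.
#' @param scale_factor normalization scale factor.
#' @return Estimated natural-log fold change (scalar).
#' @export
empirical_group_lfc <- function(ds, truth, organ, subtype, gene,
                                scale_factor = 1e4) {
  if (!gene %in% ds$gene_ids) stop("gene not present: ", gene, call. = FALSE)
  st <- truth$cells$true_subtype[match(ds$cell_ids, truth$cells$cell_id)]
  keep <- which(Matrix::rowSums(ds$counts) > 0)
  nd <- normalize_dataset(subset_cells(ds, cells = keep),
                          scale_factor = scale_factor)
  st <- st[keep]
  g1 <- which(nd$meta$organ == organ & st == subtype & nd$meta$diet == "wd")
  g2 <- which(nd$meta$organ == organ & st == subtype & nd$meta$diet == "chow")
  if (length(g1) == 0 || length(g2) == 0) {
    stop("group absent for organ=", organ, " subtype=", subtype,
         call. = FALSE)
  }
  unname(log_fold_change(nd, g1, g2, genes = gene, pseudocount = 0))
}

#' Write a synthetic fixture to disk
#'
#' Generates a dataset, writes the standard triplet file set plus
#' `truth.tsv` (organ, subtype, gene, planted_lfc, is_de, is_restored),
#' `cell_truth.tsv`, and the generating configuration as `synth_config.yaml`.
#'
#' @param cfg a [synth_config()] object.
#' @param out_dir output directory.
#' @return Named character vector of paths written, invisibly.
#' @export
make_fixture <- function(cfg, out_dir) {
  gen <- generate_dataset(cfg)
  paths <- write_dataset(gen$dataset, out_dir)
  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(gen$truth$effects, truth_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cell_truth_path <- file.path(out_dir, "cell_truth.tsv")
  utils::write.table(gen$truth$cells, cell_truth_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg_path <- file.path(out_dir, "synth_config.yaml")
  cfg_out <- cfg[setdiff(names(cfg), "planted_effects")]
  cfg_out$cells_per_group <- as.list(cfg$cells_per_group)
  yaml::write_yaml(cfg_out, cfg_path)
  invisible(c(paths, truth = truth_path, cell_truth = cell_truth_path,
              config = cfg_path))
}
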