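#' Read and validate a pipeline run configuration
#'
#' A run configuration is a YAML file (or equivalent list) with input
#' paths, QC parameters, DE thresholds, downsampling settings, stage
#' thresholds, an optional GWAS block, a seed and a stage selection.
#' Referenced input paths are checked at validation time, before any stage
#' runs.
#'
#' @param config path to a YAML file, or a named list.
#' @return A validated `RunConfig` list with defaults filled in.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    seed = 1L,
    scale_factor = 1e4,
    qc = list(min_genes = 500L, max_genes = 6000L, max_umi = 25000L,
              max_mito_frac = 0.20, mito_prefix = "mt-"),
    de = list(alpha_adj = 0.05, min_abs_lfc = 0.1),
    downsample = list(n_cells = "auto", n_draws = 1L),
    thresholds = list(shift = 0.5, lfc_gate = 0.1, consistency = 0.2,
                      highlight = 0.1, platelet_min_count = 1L,
                      concord_timepoint = 3L, restore_timepoint = 6L),
    stages = c("qc", "de", "downsample", "concord", "restore", "consist",
               "shifts", "platelet", "gwas")
  )
  for (key in names(defaults)) {
    if (is.null(config[[key]])) {
      config[[key]] <- defaults[[key]]
    } else if (is.list(defaults[[key]])) {
      for (sub in names(defaults[[key]])) {
        if (is.null(config[[key]][[sub]])) {
          config[[key]][[sub]] <- defaults[[key]][[sub]]
        }
      }
    }
  }
  if (is.null(config$out_dir)) stop("config requires out_dir", call. = FALSE)
  if (is.null(config$input) ||
      !all(c("matrix", "genes", "barcodes", "meta") %in%
             names(config$input))) {
    stop("config requires input paths: matrix, genes, barcodes, meta",
         call. = FALSE)
  }
  for (p in unlist(config$input)) {
    if (!file.exists(p)) stop("input path does not exist: ", p,
                              call. = FALSE)
  }
  if (!is.null(config$gwas)) {
    if (is.null(config$gwas$path) || is.null(config$gwas$trait)) {
      stop("gwas block requires path and trait", call. = FALSE)
    }
    if (!file.exists(config$gwas$path)) {
      stop("input path does not exist: ", config$gwas$path, call. = FALSE)
    }
    if (is.null(config$gwas$p_max)) config$gwas$p_max <- 1e-5
  }
  th <- config$thresholds
  stopifnot(th$shift >= 0, th$lfc_gate >= 0, th$consistency >= 0,
            th$highlight >= 0, th$platelet_min_count >= 0,
            config$de$alpha_adj > 0, config$de$alpha_adj < 1)
  class(config) <- c("RunConfig", "list")
  config
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  nrow(df)
}

#' Run the full analysis pipeline
#'
#' Executes QC, normalization, subtype annotation, per-contrast differential
#' expression (WD vs chow per organ x cluster x timepoint),
#' downsampling-equalized DEG counting, cross-organ concordance,
#' reversion-restoration classification, cross-organ consistency ranking,
#' population shifts, platelet-positive fractions and (when configured) the
#' GWAS risk-gene join, writing every intermediate table as TSV plus a
#' manifest and a line-oriented log into the run directory. Identical
#' configuration and seed produce byte-identical outputs.
#'
#' @param config a `RunConfig` (list or YAML path; see [read_run_config()]).
#' @return The run directory path, invisibly; the manifest lists every
#'   output with its record count.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  unlink(log_path)
  log_line <- function(stage, ...) {
    cat(sprintf("stage=%s seed=%d %s\n", stage, cfg$seed,
                paste(..., sep = " ")),
        file = log_path, append = TRUE)
  }
  counts_out <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- QC, normalization, annotation -------------------------------------
  ds <- run_stage("read", read_dataset(cfg$input$matrix, cfg$input$genes,
                                       cfg$input$barcodes, cfg$input$meta))
  log_line("read", paste0("cells=", length(ds$cell_ids)),
           paste0("genes=", length(ds$gene_ids)))
  qc <- run_stage("qc", qc_filter(ds, do.call(qc_params, cfg$qc)))
  ds <- qc$dataset
  counts_out$qc_report.tsv <- write_tsv(qc$report,
                                        file.path(out_dir, "qc_report.tsv"))
  log_line("qc", paste0("cells=", length(ds$cell_ids)),
           paste0("genes=", length(ds$gene_ids)))
  nd <- run_stage("normalize", normalize_dataset(ds, cfg$scale_factor))
  ann <- run_stage("annotate", annotate_subtypes(nd))
  counts_out$assigned_subtypes.tsv <-
    write_tsv(ann, file.path(out_dir, "assigned_subtypes.tsv"))
  log_line("annotate", paste0("records=", nrow(ann)))

  # --- Per-contrast DE ---------------------------------------------------
  meta <- nd$meta
  de_tables <- list()
  contrasts <- list()
  if ("de" %in% cfg$stages) {
    run_stage("de", {
      thr <- deg_thresholds(cfg$de$alpha_adj, cfg$de$min_abs_lfc)
      design <- unique(meta[, c("organ", "cluster", "timepoint_months")])
      design <- design[order(design$organ, design$cluster,
                             design$timepoint_months), ]
      for (i in seq_len(nrow(design))) {
        organ <- design$organ[i]; cl <- design$cluster[i]
        tp <- design$timepoint_months[i]
        g1 <- cells_where(meta, organ = organ, cluster = cl, diet = "wd",
                          timepoint = tp)
        g2 <- cells_where(meta, organ = organ, cluster = cl, diet = "chow",
                          timepoint = tp)
        if (length(g1) == 0 || length(g2) == 0) next
        key <- sprintf("%s_%s_t%d", organ, cl, tp)
        de <- find_degs(nd, g1, g2, thresholds = thr,
                        contrast = list(organ = organ, cluster = cl,
                                        timepoint = tp, diets = "wd_vs_chow"))
        de_tables[[key]] <- de
        contrasts[[key]] <- list(cells1 = g1, cells2 = g2, label = key)
        path <- file.path(out_dir, paste0("de_", key, ".tsv"))
        counts_out[[basename(path)]] <- write_tsv(de, path)
        log_line("de", paste0("contrast=", key),
                 paste0("records=", nrow(de)),
                 paste0("significant=", sum(de$significant)))
      }
    })
  }

  # --- Downsampled DEG counting ------------------------------------------
  if ("downsample" %in% cfg$stages && length(contrasts)) {
    run_stage("downsample", {
      thr <- deg_thresholds(cfg$de$alpha_adj, cfg$de$min_abs_lfc)
      dd <- count_degs_downsampled(nd, contrasts,
                                   n_cells = cfg$downsample$n_cells,
                                   n_draws = cfg$downsample$n_draws,
                                   seed = cfg$seed, thresholds = thr)
      counts_out$downsampled_deg_counts.tsv <-
        write_tsv(dd, file.path(out_dir, "downsampled_deg_counts.tsv"))
      log_line("downsample", paste0("n_cells=", dd$n_cells[1]),
               paste0("records=", nrow(dd)))
    })
  }

  # --- Cross-organ concordance -------------------------------------------
  if ("concord" %in% cfg$stages && length(de_tables)) {
    run_stage("concord", {
      tp <- cfg$thresholds$concord_timepoint
      for (cl in sort(unique(meta$cluster))) {
        keys <- grep(sprintf("_%s_t%d$", cl, tp), names(de_tables),
                     value = TRUE)
        if (length(keys) < 2) next
        tabs <- de_tables[keys]
        names(tabs) <- sub(sprintf("_%s_t%d$", cl, tp), "", keys)
        cc <- deg_concordance(tabs, lfc_gate = cfg$thresholds$lfc_gate)
        df <- data.frame(organ = rownames(cc$r),
                         as.data.frame(cc$r, row.names = NULL))
        path <- file.path(out_dir, paste0("concordance_", cl, ".tsv"))
        counts_out[[basename(path)]] <- write_tsv(df, path)
        log_line("concord", paste0("cluster=", cl),
                 paste0("universe=", length(cc$universe)))
      }
    })
  }

  # --- Restoration classification ----------------------------------------
  if ("restore" %in% cfg$stages && length(de_tables)) {
    run_stage("restore", {
      tp <- cfg$thresholds$restore_timepoint
      summary <- list()
      for (organ in sort(unique(meta$organ))) {
        for (cl in sort(unique(meta$cluster[meta$organ == organ]))) {
          key <- sprintf("%s_%s_t%d", organ, cl, tp)
          has_rev <- length(cells_where(meta, organ = organ, cluster = cl,
                                        diet = "rev", timepoint = tp)) > 0
          if (is.null(de_tables[[key]]) || !has_rev) next
          std <- standardize_to_chow(nd, timepoint = tp, organ = organ,
                                     cluster = cl, diets = "rev")
          rt <- classify_restoration(de_tables[[key]], std$rev)
          path <- file.path(out_dir, paste0("restoration_", key, ".tsv"))
          counts_out[[basename(path)]] <- write_tsv(rt, path)
          pr <- if (nrow(rt)) restored_proportions(rt) else
            list(up = NA, down = NA, n_up = 0L, n_down = 0L)
          summary[[organ]][[cl]] <- pr
          log_line("restore", paste0("contrast=", key),
                   paste0("records=", nrow(rt)),
                   paste0("excluded=", attr(rt, "n_excluded")))
        }
      }
      jsonlite::write_json(summary,
                           file.path(out_dir, "restoration_summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
  }

  # --- Cross-organ consistency ranking -----------------------------------
  if ("consist" %in% cfg$stages && length(de_tables)) {
    run_stage("consist", {
      tp <- cfg$thresholds$restore_timepoint
      for (cl in sort(unique(meta$cluster))) {
        keys <- grep(sprintf("_%s_t%d$", cl, tp), names(de_tables),
                     value = TRUE)
        if (length(keys) < 2) next
        tabs <- de_tables[keys]
        names(tabs) <- sub(sprintf("_%s_t%d$", cl, tp), "", keys)
        cm <- consistency_ranking(tabs,
                                  min_mean_abs_lfc = cfg$thresholds$consistency)
        df <- data.frame(gene = rownames(cm$lfc),
                         as.data.frame(cm$lfc, row.names = NULL),
                         mean_lfc = cm$mean_lfc,
                         included = rownames(cm$lfc) %in% cm$included)
        df <- df[order(-df$mean_lfc), ]
        path <- file.path(out_dir, paste0("consistency_", cl, ".tsv"))
        counts_out[[basename(path)]] <- write_tsv(df, path)
        log_line("consist", paste0("cluster=", cl),
                 paste0("included=", length(cm$included)))
      }
    })
  }

  # --- Population shifts --------------------------------------------------
  if ("shifts" %in% cfg$stages) {
    run_stage("shifts", {
      rows <- list()
      for (organ in sort(unique(meta$organ))) {
        for (tp in sort(unique(meta$timepoint_months))) {
          sub <- meta[meta$organ == organ & meta$timepoint_months == tp, ]
          if (!any(sub$diet == "wd") || !any(sub$diet == "chow")) next
          ps <- population_shifts(sub, condition = "wd", control = "chow",
                                  threshold = cfg$thresholds$shift)
          rows[[length(rows) + 1L]] <-
            cbind(organ = organ, timepoint_months = tp, ps)
        }
      }
      if (length(rows)) {
        shifts <- do.call(rbind, rows)
        counts_out$population_shifts.tsv <-
          write_tsv(shifts, file.path(out_dir, "population_shifts.tsv"))
        log_line("shifts", paste0("records=", nrow(shifts)))
      }
    })
  }

  # --- Platelet-positive fractions ---------------------------------------
  if ("platelet" %in% cfg$stages) {
    run_stage("platelet", {
      arms <- unique(meta[, c("organ", "diet", "timepoint_months")])
      arms <- arms[order(arms$organ, arms$diet, arms$timepoint_months), ]
      rows <- lapply(seq_len(nrow(arms)), function(i) {
        cells <- cells_where(meta, organ = arms$organ[i],
                             diet = arms$diet[i],
                             timepoint = arms$timepoint_months[i])
        pf <- platelet_positive_fraction(
          subset_cells(ds, cells = cells),
          min_count = cfg$thresholds$platelet_min_count)
        data.frame(organ = arms$organ[i], diet = arms$diet[i],
                   timepoint_months = arms$timepoint_months[i],
                   n_cells = length(cells), fraction = pf$fraction)
      })
      pl <- do.call(rbind, rows)
      counts_out$platelet_fractions.tsv <-
        write_tsv(pl, file.path(out_dir, "platelet_fractions.tsv"))
      log_line("platelet", paste0("records=", nrow(pl)))
    })
  }

  # --- GWAS risk-gene join ------------------------------------------------
  if ("gwas" %in% cfg$stages && !is.null(cfg$gwas)) {
    run_stage("gwas", {
      catalog <- read_gwas_catalog(cfg$gwas$path, p_max = cfg$gwas$p_max)
      orth <- NULL
      if (!is.null(cfg$gwas$ortholog_path)) {
        orth <- utils::read.delim(cfg$gwas$ortholog_path,
                                  stringsAsFactors = FALSE)
      }
      tp <- cfg$gwas$timepoint %||% cfg$thresholds$restore_timepoint
      cl <- cfg$gwas$cluster %||% "cap"
      organ <- cfg$gwas$organ %||% sort(unique(meta$organ))[1]
      key <- sprintf("%s_%s_t%d", organ, cl, tp)
      if (is.null(de_tables[[key]])) {
        stop("no DE table for GWAS join target contrast ", key)
      }
      rg <- link_degs_to_gwas(catalog, de_tables[[key]], cfg$gwas$trait,
                              lfc_highlight = cfg$thresholds$highlight,
                              ortholog_table = orth)
      path <- file.path(out_dir,
                        paste0("risk_genes_",
                               gsub("[^A-Za-z0-9]+", "_", cfg$gwas$trait),
                               ".tsv"))
      counts_out[[basename(path)]] <- write_tsv(rg, path)
      log_line("gwas", paste0("trait=", cfg$gwas$trait),
               paste0("records=", nrow(rg)))
    })
  }

  manifest <- list(
    package = "ecrestore",
    version = as.character(utils::packageVersion("ecrestore")),
    seed = cfg$seed,
    scale_factor = cfg$scale_factor,
    qc = cfg$qc, de = cfg$de, thresholds = cfg$thresholds,
    outputs = counts_out
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
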