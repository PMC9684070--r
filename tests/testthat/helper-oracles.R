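# Independent oracles and small hand-built fixtures shared across tests.

# Full-enumeration two-sided Wilcoxon p: every assignment of n1 of the
# pooled values to group 1 is enumerated; stays independent of the
# package's exact path (which uses the closed-form null CDF).
enum_wilcox_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_all <- combn(length(pooled), n1, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Literal step-up Benjamini-Hochberg, written from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in rev(seq_len(m))) {
    prev <- min(prev, m * p[ord[k]] / k)
    adj[ord[k]] <- prev
  }
  pmin(adj, 1)
}

# Hand-built dataset: counts chosen so QC/normalization arithmetic can be
# verified by eye. Scaled-down thresholds go with it (qc_params_small).
tiny_counts <- function() {
  # 10 cells x 7 genes; "mt-Nd1" is mitochondrial, "gz" all-zero
  m <- rbind(
    c(5, 4, 3, 2, 0, 0, 1),    # ok: 5 detected genes, 15 umi, mito 1/15
    c(9, 0, 0, 0, 0, 0, 0),    # low detected (1 gene < 3)
    c(3, 3, 3, 3, 3, 0, 3),    # too many detected (6 > 5)
    c(50, 40, 9, 0, 0, 0, 1),  # umi 100 > 60
    c(2, 2, 1, 0, 0, 0, 5),    # mito 5/10 = 0.5 > 0.2
    c(4, 3, 2, 0, 0, 0, 0),    # ok
    c(1, 1, 1, 0, 0, 0, 0),    # ok: exactly min_genes = 3 detected
    c(20, 20, 19, 0, 0, 0, 1), # ok: exactly max_umi = 60
    c(4, 3, 1, 0, 0, 0, 2),    # ok: mito 2/10 = 0.2 exactly
    c(6, 5, 4, 0, 0, 0, 0)     # ok
  )
  genes <- c("g1", "g2", "g3", "g4", "g5", "gz", "mt-Nd1")
  cells <- sprintf("cell%02d", 1:10)
  meta <- data.frame(barcode = cells, organ = "liver", cluster = "cap",
                     diet = rep(c("chow", "wd"), 5), timepoint_months = 3L,
                     animal = "a1")
  cell_dataset(m, genes, cells, meta)
}

qc_params_small <- function() {
  qc_params(min_genes = 3, max_genes = 5, max_umi = 60, max_mito_frac = 0.2)
}

# Toy GWAS catalog exercising the p filter and multi-gene expansion.
toy_gwas_path <- function() {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "snp_id\tmapped_gene\tp_value\ttrait",
    "rs1\tGENE1\t1e-06\tstroke",
    "rs2\tGENE1\t1e-04\tstroke",
    "rs3\tGENE2\t5e-06\tstroke",
    "rs4\tGENE3\t1e-08\tstroke"
  ), path)
  path
}

# Small generated dataset reused by several annotation/DE tests.
small_synth <- function(seed = 7, ...) {
  cfg <- synth_config(organs = "liver", subtypes = c("art", "cap", "ven"),
                      timepoints = 3L, cells_per_group = 80, n_genes = 300,
                      seed = seed, ...)
  generate_dataset(cfg)
}

# Genes available for explicit effect planting under a config.
synth_effect_pool <- function(cfg) {
  setdiff(synth_gene_ids(cfg),
          c(unlist(cfg$marker_panels, use.names = FALSE),
            cfg$platelet_spike$genes))
}
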