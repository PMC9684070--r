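shift_meta <- function(cond_clusters, ctrl_clusters) {
  data.frame(
    barcode = sprintf("c%03d", seq_len(length(cond_clusters) +
                                         length(ctrl_clusters))),
    organ = "o",
    cluster = c(cond_clusters, ctrl_clusters),
    diet = rep(c("wd", "chow"), c(length(cond_clusters),
                                  length(ctrl_clusters))),
    timepoint_months = 3L, animal = "a")
}

test_that("population shifts compute per-cluster log2 ratios", {
  meta <- shift_meta(c(rep("c1", 40), rep("c2", 60)),
                     c(rep("c1", 10), rep("c2", 90)))
  ps <- population_shifts(meta, threshold = 0.5)
  expect_equal(ps$log2_ratio[ps$cluster == "c1"], 2)   # 40% vs 10%
  expect_true(ps$highlight[ps$cluster == "c1"])
  expect_equal(sum(ps$frac_cond), 1)
  expect_equal(sum(ps$frac_ctrl), 1)
  # identical composition: all zero, none highlighted
  meta2 <- shift_meta(rep(c("c1", "c2"), 25), rep(c("c1", "c2"), 50))
  ps2 <- population_shifts(meta2)
  expect_true(all(ps2$log2_ratio == 0))
  expect_false(any(ps2$highlight))
})

test_that("clusters absent from one arm get an undefined ratio, not dropped", {
  meta <- shift_meta(c(rep("c1", 50), rep("only_wd", 10)), rep("c1", 60))
  ps <- population_shifts(meta)
  row <- ps[ps$cluster == "only_wd", ]
  expect_true(is.na(row$log2_ratio))
  expect_true(row$zero_fraction)
  expect_false(row$highlight)
  expect_error(population_shifts(shift_meta(character(), rep("c1", 5))),
               "no cells")
})

test_that("log2 ratio is antisymmetric under swapping the arms", {
  meta <- shift_meta(c(rep("c1", 30), rep("c2", 70)),
                     c(rep("c1", 55), rep("c2", 45)))
  fwd <- population_shifts(meta, condition = "wd", control = "chow")
  bwd <- population_shifts(meta, condition = "chow", control = "wd")
  expect_equal(fwd$log2_ratio, -bwd$log2_ratio)
})

test_that("concordance matrix has unit diagonal and detects sign flips", {
  t1 <- data.frame(gene = paste0("g", 1:50),
                   lfc = seq(-1, 1, length.out = 50))
  t2 <- t1; t2$lfc <- -t1$lfc
  cc <- deg_concordance(list(a = t1, self = t1, flip = t2), lfc_gate = 0.1)
  expect_equal(unname(diag(cc$r)), rep(1, 3))
  expect_equal(cc$r["a", "self"], 1)
  expect_equal(cc$r["a", "flip"], -1)
  expect_equal(cc$r, t(cc$r))
  # fewer than 3 shared genes: undefined
  t3 <- data.frame(gene = c("g1", "g2"), lfc = c(1, 1))
  t4 <- data.frame(gene = c("g1", "g9"), lfc = c(1, 1))
  cc2 <- deg_concordance(list(x = t3, y = t4))
  expect_true(is.na(cc2$r["x", "y"]))
  expect_identical(cc2$n["x", "y"], 1L)
})

test_that("the gene universe is gated on |lfc| in any table", {
  t1 <- data.frame(gene = c("big", "small"), lfc = c(0.5, 0.05))
  t2 <- data.frame(gene = c("big", "small"), lfc = c(0.4, 0.02))
  cc <- deg_concordance(list(a = t1, b = t2), lfc_gate = 0.1)
  expect_identical(cc$universe, "big")
})

test_that("platelet positivity needs one gene above the strict threshold", {
  meta <- data.frame(barcode = c("c1", "c2", "c3"), organ = "o",
                     cluster = "cap", diet = "chow", timepoint_months = 3L,
                     animal = "a")
  counts <- rbind(c(2, 0, 0, 5),   # Pf4 = 2 -> positive
                  c(1, 1, 1, 5),   # no single gene > 1 -> negative
                  c(0, 0, 3, 5))   # Nrgn = 3 -> positive
  ds <- cell_dataset(counts, c("Pf4", "Ppbp", "Nrgn", "other"),
                     meta$barcode, meta)
  pf <- platelet_positive_fraction(ds)
  expect_equal(pf$fraction, 2 / 3)
  expect_identical(unname(pf$flags), c(TRUE, FALSE, TRUE))
  # monotone non-increasing in min_count
  fr <- vapply(0:3, function(k) {
    platelet_positive_fraction(ds, min_count = k)$fraction
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
  # missing genes are treated as all-zero and reported
  ds2 <- subset_cells(ds, genes = c("Pf4", "other"))
  pf2 <- platelet_positive_fraction(ds2)
  expect_identical(pf2$missing_genes, c("Ppbp", "Nrgn"))
  expect_equal(pf2$fraction, 1 / 3)
  expect_error(platelet_positive_fraction(subset_cells(ds, genes = "other")),
               "platelet genes")
})

test_that("synthetic platelet spike fraction is recovered exactly", {
  cfg <- synth_config(organs = "o", subtypes = "cap", timepoints = 3L,
                      cells_per_group = 50, n_genes = 150, seed = 6,
                      platelet_spike = list(genes = c("Pf4", "Ppbp", "Nrgn"),
                                            fraction = 0.08, level = 2))
  gen <- generate_dataset(cfg)
  pf <- platelet_positive_fraction(gen$dataset)
  expect_identical(pf$fraction, 0.08)
  expect_identical(unname(pf$flags), gen$truth$cells$platelet_positive)
})

test_that("cluster z-scores standardize each gene across clusters", {
  # 4 clusters, 2 cells each; gene means fully controlled
  meta <- data.frame(barcode = sprintf("c%d", 1:8), organ = "o",
                     cluster = rep(paste0("k", 1:4), each = 2),
                     diet = "chow", timepoint_months = 3L, animal = "a")
  # filler column keeps every library size at 10 so normalized values of
  # the constant gene are truly constant
  counts <- cbind(single = c(4, 4, 0, 0, 0, 0, 0, 0),
                  const = rep(2, 8),
                  lib = c(4, 4, 8, 8, 8, 8, 8, 8))
  ds <- cell_dataset(counts, colnames(counts), meta$barcode, meta)
  nd <- normalize_dataset(ds, scale_factor = 10)
  z <- cluster_zscores(nd)
  expect_equal(unname(rowMeans(z)), rep(0, 3))
  expect_gt(z["single", "k1"], 0)
  expect_true(all(z["single", c("k2", "k3", "k4")] < 0))
  expect_true(attr(z, "constant")[["const"]])
  expect_equal(unname(z["const", ]), rep(0, 4))
  expect_error(cluster_zscores(nd, clusters = rep("k1", 8)), "2 clusters")
})

test_that("z-score denominators follow the stated sd convention", {
  means <- c(1, 2, 3)
  meta <- data.frame(barcode = c("c1", "c2", "c3"), organ = "o",
                     cluster = c("k1", "k2", "k3"), diet = "chow",
                     timepoint_months = 3L, animal = "a")
  # single gene with per-cluster normalized means exp-constructed below
  vals <- Matrix::Matrix(matrix(means, ncol = 1), sparse = TRUE)
  nd <- structure(list(values = vals, scale_factor = 1e4, gene_ids = "g",
                       cell_ids = meta$barcode, meta = meta),
                  class = "NormalizedDataset")
  z_pop <- cluster_zscores(nd)
  expect_equal(unname(z_pop["g", ]),
               (means - 2) / sqrt(2 / 3))
  z_smp <- cluster_zscores(nd, sd_type = "sample")
  expect_equal(unname(z_smp["g", ]), (means - 2) / 1)
})
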