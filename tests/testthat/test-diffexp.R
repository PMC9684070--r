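test_that("wilcoxon test reproduces textbook cases", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(wilcoxon_rank_sum(rep(2, 5), rep(2, 7))$p, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("exact path equals the full-enumeration oracle", {
  set.seed(1)
  for (N in 4:10) {
    for (n1 in 1:(N - 1)) {
      x <- sample(seq_len(100), N)   # distinct -> tie-free
      res <- wilcoxon_rank_sum(x[seq_len(n1)], x[-seq_len(n1)])
      expect_equal(res$p, enum_wilcox_p(x[seq_len(n1)], x[-seq_len(n1)]),
                   tolerance = 1e-12)
    }
  }
})

test_that("approximate path stays within its documented error bounds", {
  # the cc-normal approximation cannot track the few-atom exact null at
  # very small group sizes; measured worst cases: 0.13 overall, 0.02 once
  # both groups have >= 5 observations (n1 + n2 <= 12)
  set.seed(2)
  worst_all <- 0; worst_5 <- 0
  for (N in 4:12) {
    for (n1 in 1:(N - 1)) {
      x <- sample(seq_len(200), N)
      for (rep in 1:5) {
        idx <- sample(N, n1)
        pa <- wilcoxon_rank_sum(x[idx], x[-idx], exact_limit = 0L)$p
        pe <- enum_wilcox_p(x[idx], x[-idx])
        d <- abs(pa - pe)
        worst_all <- max(worst_all, d)
        if (min(n1, N - n1) >= 5) worst_5 <- max(worst_5, d)
      }
    }
  }
  expect_lte(worst_all, 0.13)
  expect_lte(worst_5, 0.02)
})

test_that("approximate path matches the reference implementation with ties", {
  set.seed(3)
  for (i in 1:20) {
    x <- rpois(40, 2); y <- rpois(55, 2.5)
    mine <- wilcoxon_rank_sum(x, y)$p
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  for (i in 1:25) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  }
})

test_that("log fold change is the de-logged mean ratio with pseudocount", {
  gen <- small_synth()
  nd <- normalize_dataset(gen$dataset)
  g1 <- cells_where(nd, diet = "wd", cluster = "cap")
  g2 <- cells_where(nd, diet = "chow", cluster = "cap")
  expect_equal(unname(log_fold_change(nd, g1, g1)[1]), 0) # identical groups
  lfc12 <- log_fold_change(nd, g1, g2)
  lfc21 <- log_fold_change(nd, g2, g1)
  expect_equal(unname(lfc12), -unname(lfc21))
  # hand computation: de-logged group means 3 vs 1 -> ln(4) - ln(2)
  meta <- data.frame(barcode = c("c1", "c2"), organ = "o", cluster = "cap",
                     diet = c("wd", "chow"), timepoint_months = 3L,
                     animal = "a")
  vals <- Matrix::Matrix(matrix(log(c(3, 1) + 1), ncol = 1), sparse = TRUE)
  nd2 <- structure(list(values = vals, scale_factor = 1e4,
                        gene_ids = "g", cell_ids = c("c1", "c2"),
                        meta = meta),
                   class = "NormalizedDataset")
  expect_equal(unname(log_fold_change(nd2, 1, 2)), log(4) - log(2))
  expect_equal(unname(log_fold_change(nd2, 1, 2, pseudocount = 0)), log(3))
  expect_error(log_fold_change(nd, integer(0), g2), "non-empty")
})

test_that("find_degs tests exactly the detected gene set and flags power", {
  cfg0 <- synth_config(organs = "o", subtypes = "cap", timepoints = 3L,
                       cells_per_group = 300, n_genes = 400, seed = 13)
  pool <- synth_effect_pool(cfg0)
  eff <- data.frame(organ = "o", subtype = "cap", gene = pool[1:40],
                    planted_lfc = rep(c(1, -1), 20), is_restored = FALSE)
  cfg <- synth_config(organs = "o", subtypes = "cap", timepoints = 3L,
                      cells_per_group = 300, n_genes = 400,
                      planted_effects = eff, seed = 13)
  gen <- generate_dataset(cfg)
  nd <- normalize_dataset(gen$dataset)
  g1 <- cells_where(nd, diet = "wd")
  g2 <- cells_where(nd, diet = "chow")
  de <- find_degs(nd, g1, g2)
  # genes zero in both groups (the un-spiked platelet genes) are untested
  detected <- Matrix::colSums(nd$values[c(g1, g2), ] > 0) > 0
  expect_setequal(de$gene, nd$gene_ids[detected])
  expect_true(all(de$adj_p >= de$p))
  expect_true(all(de$pct1 >= 0 & de$pct1 <= 1))
  # planted |lfc| = 1 at n = 300/group: nearly all recovered
  hits <- intersect(de$gene[de$significant], eff$gene)
  expect_gte(length(hits) / nrow(eff), 0.9)
  expect_error(find_degs(nd, g1, g1), "overlap")
  expect_error(find_degs(nd, integer(0), g2), "empty cell group")
})

test_that("downsampled counting reduces to plain counting at full size", {
  gen <- small_synth(seed = 17)
  nd <- normalize_dataset(gen$dataset)
  ct <- list(cells1 = cells_where(nd, cluster = "cap", diet = "wd"),
             cells2 = cells_where(nd, cluster = "cap", diet = "chow"),
             label = "cap")
  full <- sum(find_degs(nd, ct$cells1, ct$cells2)$significant)
  dd <- count_degs_downsampled(nd, list(ct),
                               n_cells = length(ct$cells1), seed = 1)
  expect_identical(dd$deg_count, full)
})

test_that("auto downsampling size is the minimum group size", {
  cfg <- synth_config(organs = c("A", "B"), subtypes = "cap",
                      timepoints = 3L,
                      cells_per_group = c(A = 73, B = 210), n_genes = 120,
                      seed = 19)
  nd <- normalize_dataset(generate_dataset(cfg)$dataset)
  cts <- lapply(c("A", "B"), function(o) {
    list(cells1 = cells_where(nd, organ = o, diet = "wd"),
         cells2 = cells_where(nd, organ = o, diet = "chow"), label = o)
  })
  # sizes {73, 210} plus an asymmetric 73/210 contrast -> auto = 73
  dd <- count_degs_downsampled(nd, cts, n_cells = "auto", seed = 1)
  expect_true(all(dd$n_cells == 73L))
  expect_error(count_degs_downsampled(nd, cts, n_cells = 100, seed = 1),
               "exceeds")
})

test_that("expected DEG count does not decrease with more cells", {
  cfg0 <- synth_config(organs = "o", subtypes = "cap", timepoints = 3L,
                       cells_per_group = 200, n_genes = 300, seed = 23)
  pool <- synth_effect_pool(cfg0)
  eff <- data.frame(organ = "o", subtype = "cap", gene = pool[1:30],
                    planted_lfc = rep(c(0.8, -0.8), 15), is_restored = FALSE)
  cfg <- synth_config(organs = "o", subtypes = "cap", timepoints = 3L,
                      cells_per_group = 200, n_genes = 300,
                      planted_effects = eff, seed = 23)
  nd <- normalize_dataset(generate_dataset(cfg)$dataset)
  ct <- list(cells1 = cells_where(nd, diet = "wd"),
             cells2 = cells_where(nd, diet = "chow"))
  d50 <- count_degs_downsampled(nd, list(ct), n_cells = 50, n_draws = 5,
                                seed = 2)
  d100 <- count_degs_downsampled(nd, list(ct), n_cells = 100, n_draws = 5,
                                 seed = 2)
  expect_gte(d100$deg_count, d50$deg_count)
})
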