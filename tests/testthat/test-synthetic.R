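test_that("generation is deterministic given the seed", {
  cfg <- synth_config(organs = "liver", timepoints = 3L,
                      cells_per_group = 40, n_genes = 200, seed = 3)
  g1 <- generate_dataset(cfg)
  g2 <- generate_dataset(cfg)
  expect_identical(as.matrix(g1$dataset$counts), as.matrix(g2$dataset$counts))
  expect_identical(g1$truth$effects, g2$truth$effects)
  g3 <- generate_dataset(synth_config(organs = "liver", timepoints = 3L,
                                      cells_per_group = 40, n_genes = 200,
                                      seed = 4))
  expect_false(identical(as.matrix(g1$dataset$counts),
                         as.matrix(g3$dataset$counts)))
  # schema unchanged under seed variation
  expect_identical(names(g1$truth$effects), names(g3$truth$effects))
})

test_that("planted DE counts are exact per organ x subtype", {
  cfg <- synth_config(organs = c("liver", "heart"), timepoints = 3L,
                      cells_per_group = 10, n_genes = 500, frac_de = 0.2,
                      seed = 1)
  truth <- generate_dataset(cfg)$truth$effects
  per_group <- tapply(truth$is_de,
                      paste(truth$organ, truth$subtype), sum)
  expect_true(all(per_group == 100))
  # restoration implies differential expression
  expect_true(all(truth$is_de[truth$is_restored]))
  # signs are balanced
  de <- truth[truth$is_de & truth$organ == "liver" &
                truth$subtype == "cap", ]
  expect_identical(sum(de$planted_lfc > 0), 50L)
})

test_that("a null configuration plants no effects", {
  cfg <- synth_config(organs = "liver", subtypes = "cap", timepoints = 3L,
                      cells_per_group = 30, n_genes = 200, frac_de = 0,
                      seed = 2)
  truth <- generate_dataset(cfg)$truth$effects
  expect_true(all(truth$planted_lfc == 0))
  expect_false(any(truth$is_de))
})

test_that("counts follow the negative-binomial mean-variance relation", {
  cfg <- synth_config(organs = "o", subtypes = "cap", timepoints = 3L,
                      cells_per_group = 2000, n_genes = 120, frac_de = 0,
                      libsize_log_sd = 0, dispersion = 2, seed = 9,
                      platelet_spike = list(genes = c("Pf4", "Ppbp", "Nrgn"),
                                            fraction = 0, level = 3))
  gen <- generate_dataset(cfg)
  chow <- cells_where(gen$dataset, diet = "chow")
  cm <- as.matrix(gen$dataset$counts[chow, ])
  m <- colMeans(cm)
  v <- apply(cm, 2, stats::var)
  keep <- m > 0.5
  expected <- m[keep] + m[keep]^2 / 2
  expect_lt(median(abs(v[keep] / expected - 1)), 0.15)
  expect_gt(mean(v[keep] > m[keep]), 0.9)   # overdispersed
})

test_that("platelet spike is assigned by exact count at level >= 2", {
  cfg <- synth_config(organs = "o", subtypes = "cap", timepoints = 3L,
                      cells_per_group = 50, n_genes = 200, seed = 5,
                      platelet_spike = list(genes = c("Pf4", "Ppbp", "Nrgn"),
                                            fraction = 0.1, level = 3))
  gen <- generate_dataset(cfg)
  expect_identical(mean(gen$truth$cells$platelet_positive), 0.1)
  spiked <- gen$truth$cells$cell_id[gen$truth$cells$platelet_positive]
  sub <- gen$dataset$counts[spiked, c("Pf4", "Ppbp", "Nrgn")]
  expect_true(all(Matrix::rowSums(sub >= 2) > 0))
  unspiked <- gen$truth$cells$cell_id[!gen$truth$cells$platelet_positive]
  expect_true(all(gen$dataset$counts[unspiked, c("Pf4", "Ppbp", "Nrgn")] == 0))
})

test_that("truth tables share the dataset's orderings", {
  gen <- small_synth()
  expect_identical(gen$truth$cells$cell_id, gen$dataset$cell_ids)
  expect_identical(unique(gen$truth$effects$gene), gen$dataset$gene_ids)
})

test_that("empirical group lfc recovers a planted effect", {
  cfg0 <- synth_config(organs = "o", subtypes = "cap", timepoints = 3L,
                       cells_per_group = 2000, n_genes = 300, seed = 11)
  pool <- synth_effect_pool(cfg0)
  eff <- data.frame(organ = "o", subtype = "cap", gene = pool[1:30],
                    planted_lfc = rep(c(0.7, -0.7), 15),
                    is_restored = FALSE)
  cfg <- synth_config(organs = "o", subtypes = "cap", timepoints = 3L,
                      cells_per_group = 2000, n_genes = 300,
                      planted_effects = eff, seed = 11)
  gen <- generate_dataset(cfg)
  est <- empirical_group_lfc(gen$dataset, gen$truth, "o", "cap", pool[1])
  expect_lt(abs(est - 0.7), 0.1)
  null_est <- empirical_group_lfc(gen$dataset, gen$truth, "o", "cap",
                                  pool[40])
  expect_lt(abs(null_est), 0.1)
  expect_error(empirical_group_lfc(gen$dataset, gen$truth, "o", "cap",
                                   "no_such_gene"), "not present")
})

test_that("per-organ group sizes and config invariants are enforced", {
  cfg <- synth_config(organs = c("A", "B"), subtypes = "cap",
                      timepoints = 3L, cells_per_group = c(A = 10, B = 25),
                      n_genes = 150, seed = 1)
  gen <- generate_dataset(cfg)
  tab <- table(gen$dataset$meta$organ, gen$dataset$meta$diet)
  expect_identical(unname(tab["A", "chow"]), 10L)
  expect_identical(unname(tab["B", "wd"]), 25L)
  expect_error(synth_config(frac_de = 1.5), "frac_de")
  expect_error(synth_config(effect_size_lfc = c(-0.1, 0.5)),
               "effect_size_lfc")
  expect_error(synth_config(cells_per_group = 1), "cells_per_group")
})
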