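test_that("configuration invariants are enforced", {
  expect_error(cohort_config(hk_fraction = 0.6, marker_fraction = 0.5),
               "< 1")
  expect_error(cohort_config(dropout_rate = 1.2), "fractions")
  expect_error(cohort_config(noise_sd = -1), "non-negative")
  a <- default_composition_alpha(default_cell_types())
  a["blood", "Melanoma"] <- 1
  expect_error(cohort_config(composition_alpha = a), "malignant")
  # too few genes to host markers and housekeeping
  expect_error(generate_type_profiles(cohort_config(n_genes = 200,
                                                    marker_fraction = 0.02)),
               "too few genes")
})

test_that("type profiles respect source shifts, housekeeping and determinism", {
  cfg0 <- cohort_config(n_genes = 600, marker_fraction = 0.08,
                        source_shift_sd = 0, seed = 5)
  p0 <- generate_type_profiles(cfg0)
  expect_identical(p0$profiles$blood, p0$profiles$tumorA)
  expect_identical(p0$profiles$blood, p0$profiles$tumorB)

  cfg <- cohort_config(n_genes = 600, marker_fraction = 0.08, seed = 5)
  p <- generate_type_profiles(cfg)
  # housekeeping rows constant across types and sources
  for (src in names(p$profiles)) {
    hk <- p$profiles[[src]][p$hk_genes, ]
    expect_true(all(hk == hk[, 1]))
    expect_identical(hk, p$profiles$blood[p$hk_genes, ])
  }
  # marker logic: AND genes high in their type, zero in unrelated types
  spec <- p$marker_spec_major
  b <- p$profiles$blood
  expect_true(all(b[spec[["B cell"]]$AND, "B cell"] > 0))
  expect_true(all(b[spec[["B cell"]]$AND, "NK cell"] == 0))
  # T-lineage markers cover all subsets
  expect_true(all(b[spec[["T cell"]]$AND, c("CD4 T cell", "CD8 T cell",
                                            "Treg")] > 0))
  # seeded determinism
  expect_identical(generate_type_profiles(cfg), p)
})

test_that("simulated samples have exact TPM scaling and realized truth", {
  cfg <- plain_config()
  p <- generate_type_profiles(cfg)
  comp <- stats::setNames(rep(0, 11), colnames(p$profiles$blood))
  comp[c("CD4 T cell", "B cell")] <- c(0.5, 0.5)
  s <- simulate_sample(p, comp, 200, "P1", "blood", cfg, seed = 3)
  expect_true(max(abs(colSums(s$expr) - 1e6)) < 1e-6 * 1e6)
  expect_equal(sum(s$truth$composition), 1)
  expect_equal(s$truth$composition,
               prop.table(table(factor(s$annotation$cell_type,
                                       names(comp)))) [names(comp)],
               ignore_attr = TRUE)
})

test_that("degenerate compositions and empty samples behave", {
  cfg <- plain_config()
  p <- generate_type_profiles(cfg)
  one <- stats::setNames(c(1), "CD8 T cell")
  s <- simulate_sample(p, one, 50, "P1", "blood", cfg, seed = 1)
  expect_true(all(s$annotation$cell_type == "CD8 T cell"))
  # two noiseless cells of one type are identical columns
  expect_identical(s$expr[, 1], s$expr[, 2], ignore_attr = TRUE)

  e <- simulate_sample(p, one, 0, "P1", "blood", cfg)
  expect_identical(ncol(e$expr), 0L)
  expect_identical(nrow(e$annotation), 0L)

  expect_error(simulate_sample(p, stats::setNames(c(0.5, 0.5),
                                                  c("Melanoma", "B cell")),
                               10, "P1", "blood", cfg),
               "malignant")
})

test_that("realized fractions fall in the exact binomial interval", {
  cfg <- plain_config()
  p <- generate_type_profiles(cfg)
  comp <- stats::setNames(c(0.5, 0.5), c("CD4 T cell", "B cell"))
  s <- simulate_sample(p, comp, 1000, "P1", "blood", cfg, seed = 11)
  lo <- qbinom(0.005, 1000, 0.5) / 1000
  hi <- qbinom(0.995, 1000, 0.5) / 1000
  f <- s$truth$composition["CD4 T cell"]
  expect_true(f >= lo && f <= hi)
})

test_that("a default-shaped cohort has 27 samples and clean blood", {
  co <- noisy_cohort()
  cfg27 <- cohort_config()
  expect_identical(sum(cfg27$n_patients_per_source), 27)
  blood <- co$sample_info$sample_id[co$sample_info$source == "blood"]
  mal <- co$config$cell_types$name[co$config$cell_types$is_malignant]
  for (sid in blood)
    expect_false(any(co$samples[[sid]]$annotation$cell_type %in% mal))
  expect_true(all(abs(rowSums(co$truth_composition) - 1) < 1e-9))
})

test_that("cohort simulation is reproducible from the seed", {
  cfg <- cohort_config(n_genes = 600, marker_fraction = 0.08,
                       n_patients_per_source = c(blood = 1, tumorA = 2,
                                                 tumorB = 1),
                       cells_per_sample = 40, seed = 77)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$truth_composition, c2$truth_composition)
  expect_identical(c1$samples[[2]]$expr, c2$samples[[2]]$expr)
})

test_that("source shifts reduce between-source within-type correlation", {
  co <- noisy_cohort()
  pooled <- cohort_expression(co)
  logm <- log2(pooled$expr + 1)
  ann <- pooled$annotation
  set.seed(9)
  within <- c(); between <- c()
  for (tp in c("B cell", "Macrophage", "CD8 T cell")) {
    bl <- ann$cell_id[ann$cell_type == tp & ann$source == "blood"]
    tu <- ann$cell_id[ann$cell_type == tp & ann$source == "tumorA"]
    bl <- sample(bl, min(15, length(bl)))
    tu <- sample(tu, min(15, length(tu)))
    cw <- cor(logm[, bl])
    within <- c(within, mean(cw[upper.tri(cw)]))
    between <- c(between, mean(cor(logm[, bl], logm[, tu])))
  }
  expect_true(mean(between) < mean(within))
})

test_that("content sweep fixes the malignant fraction", {
  cfg <- cohort_config(n_genes = 600, marker_fraction = 0.08,
                       cells_per_sample = 300, seed = 13)
  sw <- simulate_content_sweep(cfg, fractions = c(0.2, 0.6))
  f <- sw$truth_composition[, "Melanoma"]
  expect_true(all(abs(f - c(0.2, 0.6)) < 0.08))
})
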