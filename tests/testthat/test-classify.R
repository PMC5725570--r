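test_that("t-SNE embedding is seeded-deterministic and guards perplexity", {
  set.seed(2)
  m <- tiny_matrix(matrix(rnorm(50 * 120, 5), 50, 120))
  expr_scale(m) <- "LOG2"
  e1 <- embed_tsne(m, perplexity = 20, seed = 4)
  e2 <- embed_tsne(m, perplexity = 20, seed = 4)
  expect_identical(e1, e2)
  expect_error(embed_tsne(m[, 1:20], perplexity = 20), "perplexity")
})

test_that("duplicated cells land close together in the embedding", {
  set.seed(3)
  m <- tiny_matrix(matrix(rnorm(40 * 99, 5), 40, 99))
  m <- cbind(m, dup = m[, 1])
  expr_scale(m) <- "LOG2"
  e <- embed_tsne(m, perplexity = 15, seed = 1)
  d_dup <- sqrt(sum((e[1, ] - e[100, ])^2))
  d_all <- mean(dist(e))
  expect_lt(d_dup, d_all)
})

test_that("DBSCAN satisfies the brute-force neighbourhood conditions", {
  set.seed(8)
  pts <- rbind(matrix(rnorm(60, 0, 0.5), ncol = 2),
               matrix(rnorm(60, 10, 0.5), ncol = 2),
               matrix(runif(20, -20, 30), ncol = 2))
  ca <- cluster_dbscan(pts, min_pts = 10, eps = 1.5)
  d <- as.matrix(dist(pts))
  core <- rowSums(d <= 1.5) >= 10
  # every core point is clustered
  expect_true(all(ca$cluster[core] != -1))
  # density-connectivity: a core point's neighbours share its cluster
  for (i in which(core))
    expect_true(all(ca$cluster[d[i, ] <= 1.5] == ca$cluster[i]))
  # noise points are non-core and not within eps of any core point
  noise <- ca$cluster == -1
  expect_true(all(!core[noise]))
  if (any(noise))
    expect_true(all(d[noise, core, drop = FALSE] > 1.5))
})

test_that("DBSCAN handles the canonical degenerate layouts", {
  two <- rbind(matrix(0, 30, 2), matrix(100, 30, 2))
  ca <- cluster_dbscan(two, min_pts = 25, eps = 1.5)
  expect_identical(max(ca$cluster), 2L)
  expect_identical(sum(ca$cluster == -1), 0L)
  # identical points form one cluster
  same <- cluster_dbscan(matrix(1, 40, 2), min_pts = 25, eps = 1.5)
  expect_identical(unique(same$cluster), 1L)
  # too few points for the core condition: all noise
  few <- cluster_dbscan(matrix(rnorm(20), 10, 2), min_pts = 25, eps = 1.5)
  expect_true(all(few$cluster == -1))
})

test_that("marker scores follow the AND/OR/NOT algebra", {
  # 3 cells, one AND gene (0,2,4), one NOT gene (4,0,0):
  # normalized AND (0,.5,1), NOT (1,0,0) -> scores (0, .5, 1)
  m <- tiny_matrix(rbind(a = c(0, 2, 4), n = c(4, 0, 0)),
                   genes = c("a", "n"))
  expr_scale(m) <- "LOG2"
  spec <- list(X = list(AND = "a", OR = character(), NOT = "n"))
  sc <- score_markers(m, spec)
  expect_equal(unname(sc[, "X"]), c(0, 0.5, 1))

  # all AND genes at their per-gene maximum, no OR/NOT -> score 1;
  # one AND gene at zero -> AND contribution gated to 0
  m2 <- tiny_matrix(rbind(a1 = c(5, 0), a2 = c(3, 1)))
  expr_scale(m2) <- "LOG2"
  sc2 <- score_markers(m2, list(Y = list(AND = c("a1", "a2"),
                                         OR = character(),
                                         NOT = character())))
  expect_equal(unname(sc2[, "Y"]), c(1, 0))

  expect_error(score_markers(m2, list(Z = list(AND = character(),
                                               OR = character(),
                                               NOT = "a1"))),
               "no resolvable")
  expect_warning(score_markers(m2, list(Y = list(AND = c("a1", "ghost"),
                                                 OR = character(),
                                                 NOT = character()))),
                 "ghost")
})

test_that("cluster labelling applies the 75% predominance rule", {
  scores <- matrix(c(10, 5, 10, 8), 2, 2, byrow = TRUE,
                   dimnames = list(c("c1", "c2"), c("T1", "T2")))
  # cluster of c1 alone: totals (10, 5); 5 < 7.5, unique pass -> labelled
  ca1 <- structure(list(cluster = c(1L, -1L)), class = "cluster_assignment")
  expect_equal(unname(label_clusters(scores, ca1)), c("T1", NA))
  # cluster of c2 alone: totals (10, 8); both pass -> unlabelled
  ca2 <- structure(list(cluster = c(-1L, 1L)), class = "cluster_assignment")
  expect_equal(unname(label_clusters(scores, ca2)), c(NA_character_, NA))
  # single-type spec: every non-noise cluster gets that type
  ca3 <- structure(list(cluster = c(1L, 2L)), class = "cluster_assignment")
  lab <- label_clusters(scores[, "T1", drop = FALSE], ca3)
  expect_equal(unname(lab), c("T1", "T1"))
})

test_that("tree training, posterior thresholding and invariances", {
  set.seed(5)
  n <- 60
  m <- tiny_matrix(rbind(f1 = c(rnorm(n, 10), rnorm(n, 0)),
                         f2 = c(rnorm(n, 0), rnorm(n, 10))))
  expr_scale(m) <- "LOG2"
  labels <- rep(c("A", "B"), each = n)
  clf <- train_classifier(m, labels)
  ann <- classify_cells(clf, m)
  expect_true(all(ann$cell_type == labels))
  expect_true(all(ann$posterior == 1))
  # row-order invariance
  ann2 <- classify_cells(clf, m[rev(rownames(m)), ])
  expect_identical(ann2$cell_type, ann$cell_type)
  # empty matrix -> empty annotation
  expect_identical(nrow(classify_cells(clf, m[, 0, drop = FALSE])), 0L)
  # missing genes are named
  expect_error(classify_cells(clf, m[1, , drop = FALSE]), "f2")
  expect_error(train_classifier(m, rep("A", 2 * n)), "two labelled classes")
})

test_that("cells reaching impure leaves fall below the posterior threshold", {
  # indistinguishable features with a 60/40 label split: the tree cannot
  # split, every cell sits in a 0.6-posterior leaf -> unknown
  m <- tiny_matrix(matrix(1, 2, 50))
  expr_scale(m) <- "LOG2"
  labels <- rep(c("A", "B"), c(30, 20))
  clf <- train_classifier(m, labels)
  ann <- classify_cells(clf, m)
  expect_true(all(ann$cell_type == "unknown"))
  expect_true(all(abs(ann$posterior - 0.6) < 1e-12))
})

test_that("cross-validation is stratified, guarded and calibrated to chance", {
  set.seed(6)
  n <- 100
  m <- tiny_matrix(rbind(f1 = c(rnorm(n, 8), rnorm(n, 0)),
                         f2 = rnorm(2 * n)))
  expr_scale(m) <- "LOG2"
  labels <- rep(c("A", "B"), each = n)
  expect_equal(cross_validate(m, labels, k = 5, seed = 2), 1)
  expect_error(cross_validate(m, rep("A", 2 * n), k = 5), "two classes")
  expect_error(cross_validate(m, c(rep("C", 3), labels[-(1:3)]), k = 5),
               "smaller than k")
  # pure-noise features: accuracy stays near chance
  m_noise <- tiny_matrix(matrix(rnorm(10 * 200), 10, 200))
  expr_scale(m_noise) <- "LOG2"
  acc <- cross_validate(m_noise, rep(c("A", "B"), each = 100), k = 5,
                        seed = 3)
  expect_true(acc >= 0.35 && acc <= 0.65)
})

test_that("two-stage classification resolves T subsets without leakage", {
  co <- noisy_cohort()
  pooled <- cohort_expression(co)
  m <- housekeeping_normalize(log_transform(pooled$expr), co$hk_genes)
  res <- classify_two_stage(m[co$signature_genes, ], co$marker_spec_major,
                            co$marker_spec_tsub, seed = 2)
  truth <- pooled$annotation$cell_type
  pred <- res$annotation$cell_type
  known <- pred != "unknown"
  expect_gt(mean(pred[known] == truth[known]), 0.9)
  expect_lt(mean(!known), 0.05)
  # subset labels only arise inside the stage-2 (T cell) domain
  subsets <- c("CD4 T cell", "CD8 T cell", "Treg")
  expect_true(all(res$annotation$cell_id[pred %in% subsets] %in%
                    res$stage2$annotation$cell_id))
  # stage-2 domain is exactly the stage-1 T-cell calls
  expect_setequal(res$stage2$annotation$cell_id,
                  res$stage1$annotation$cell_id[
                    res$stage1$annotation$cell_type == "T cell"])
})

test_that("a cohort without T cells skips the subtype stage with a warning", {
  co <- noisy_cohort()
  pooled <- cohort_expression(co)
  keep <- !(pooled$annotation$cell_type %in%
              c("CD4 T cell", "CD8 T cell", "Treg"))
  m <- log_transform(pooled$expr[, keep])
  spec <- co$marker_spec_major[setdiff(names(co$marker_spec_major), "T cell")]
  spec_t <- co$marker_spec_major["T cell"]
  expect_warning(
    res <- classify_two_stage(m[co$signature_genes, ], c(spec, spec_t),
                              co$marker_spec_tsub, seed = 2),
    "no T cells")
  expect_null(res$stage2)
  expect_identical(res$annotation, res$stage1$annotation)
})
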