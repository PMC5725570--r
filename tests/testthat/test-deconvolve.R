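test_that("SVR standardization follows the affine convention and matches hand arithmetic", {
  B <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("A", "B")))
  m <- c(g1 = 2, g2 = 4, g3 = 6)
  s <- standardize_for_svr(B, m)
  expect_equal(s$B, (B - mean(B)) / sd(as.vector(B)))
  expect_equal(s$m, (m - mean(m)) / sd(m))
  expect_equal(s$rescale, sd(m) / sd(as.vector(B)))
  # already standardized input is unchanged
  s2 <- standardize_for_svr(s$B, s$m)
  expect_equal(s2$B, s$B, tolerance = 1e-12)
  expect_equal(s2$m, s$m, tolerance = 1e-12)
  # identical columns carry no information
  Bdeg <- cbind(A = c(1, 2, 3), B = c(1, 2, 3))
  rownames(Bdeg) <- rownames(B)
  expect_error(standardize_for_svr(Bdeg, m), "degenerate")
})

test_that("pseudo-inverse solver matches normal-equation oracles", {
  # orthonormal columns: coefficients read off directly
  B <- cbind(A = c(1, 0, 0), B = c(0, 1, 0))
  rownames(B) <- paste0("g", 1:3)
  expect_equal(deconvolve_pinv(B, 0.2 * B[, 1] + 0.8 * B[, 2]),
               c(A = 0.2, B = 0.8))
  # hand-solved normal equations: B = [[1,0],[0,1],[1,1]], m = (.3,.7,1)
  B2 <- matrix(c(1, 0, 1, 0, 1, 1), 3, 2,
               dimnames = list(paste0("g", 1:3), c("A", "B")))
  m2 <- c(0.3, 0.7, 1.0)
  expect_equal(deconvolve_pinv(B2, m2), c(A = 0.3, B = 0.7))
  # rank-deficient duplicate columns: minimum-norm splits the weight
  B3 <- cbind(A = c(1, 2, 3), B = c(1, 2, 3))
  rownames(B3) <- paste0("g", 1:3)
  expect_equal(deconvolve_pinv(B3, c(1, 2, 3)), c(A = 0.5, B = 0.5))
})

test_that("intercept least squares recovers weights and offsets exactly", {
  mix <- random_mixture(seed = 2)
  w <- deconvolve_lm_intercept(mix$B, mix$m)
  expect_equal(unclass(w)[names(mix$w)], mix$w, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(attr(w, "intercept"), 0, tolerance = 1e-8)
  w2 <- deconvolve_lm_intercept(mix$B, mix$m + 5)
  expect_equal(attr(w2, "intercept"), 5, tolerance = 1e-8)
  expect_equal(unclass(w2)[names(mix$w)], mix$w, tolerance = 1e-9,
               ignore_attr = TRUE)
  # single-column slope equals the classical regression coefficient
  b <- mix$B[, 1, drop = FALSE]
  y <- mix$m
  slope <- cov(b[, 1], y) / var(b[, 1])
  w3 <- deconvolve_lm_intercept(b, y)
  expect_equal(unname(unclass(w3)[1]), slope, tolerance = 1e-9)
})

test_that("regularized NNLS matches grid-search and QP oracles", {
  set.seed(3)
  B <- matrix(rexp(40 * 2, 1 / 10), 40, 2,
              dimnames = list(sprintf("g%02d", 1:40), c("A", "B")))
  m <- drop(B %*% c(0.35, 0.45)) + rnorm(40, 0, 0.5)
  w <- deconvolve_reg_nnls(B, m, lambda = 1)
  # brute-force grid at 1e-3 resolution
  grid <- seq(0, 1, 1e-3)
  BtB <- crossprod(B); Btm <- crossprod(B, m)
  obj <- function(w1, w2) {
    v <- c(w1, w2)
    drop(v %*% BtB %*% v) - 2 * drop(Btm) %*% v + sum(v^2)
  }
  best <- c(0, 0); bestv <- Inf
  for (w1 in grid) {
    # inner dimension solved in closed form, then clipped to the grid
    w2 <- (Btm[2] - BtB[1, 2] * w1) / (BtB[2, 2] + 1)
    w2 <- max(0, min(1, round(w2 * 1000) / 1000))
    v <- obj(w1, w2)
    if (v < bestv) { bestv <- v; best <- c(w1, w2) }
  }
  expect_lt(max(abs(w - best)), 2e-3)
  # independent QP cross-check
  if (requireNamespace("quadprog", quietly = TRUE)) {
    qp <- quadprog::solve.QP(Dmat = 2 * (BtB + diag(2)),
                             dvec = 2 * drop(Btm),
                             Amat = diag(2), bvec = c(0, 0))
    expect_equal(unname(w), qp$solution, tolerance = 1e-6)
  }
  # penalty limits
  Borth <- cbind(A = c(1, 0), B = c(0, 1))
  rownames(Borth) <- c("g1", "g2")
  expect_equal(deconvolve_reg_nnls(Borth, c(0.3, 0.7), lambda = 0),
               c(A = 0.3, B = 0.7))
  expect_lt(sum(deconvolve_reg_nnls(B, m, lambda = 1e9)), 1e-4)
})

test_that("nu-SVR recovers noiseless mixtures and ignores gene order", {
  mix <- random_mixture(n_genes = 50, seed = 4)
  w <- deconvolve_nusvr(mix$B, mix$m)
  expect_lt(max(abs(w / sum(w) - mix$w)), 0.02)
  expect_lt(max(abs(w - mix$w)), 0.02)
  # pure sample
  wp <- deconvolve_nusvr(mix$B, mix$B[, "B"])
  expect_lt(max(abs(wp - c(A = 0, B = 1, C = 0))), 0.02)
  # permuting the gene rows leaves the solution unchanged
  p <- sample(nrow(mix$B))
  wperm <- deconvolve_nusvr(mix$B[p, ], mix$m[p])
  expect_equal(w, wperm, tolerance = 1e-3)
})

test_that("post-processing enforces the composition simplex", {
  e1 <- postprocess_weights(c(A = 0.6, B = 0.4))
  expect_equal(e1$w_unknown, 0)
  e2 <- postprocess_weights(c(A = 0.5, B = 0.3))
  expect_equal(e2$w_unknown, 0.2)
  e3 <- postprocess_weights(c(A = -0.1, B = 0.9))
  expect_equal(e3$w, c(A = 0, B = 0.9))
  expect_equal(e3$w_unknown, 0.1)
  # sum > 1 is renormalized
  e4 <- postprocess_weights(c(A = 0.8, B = 0.6))
  expect_equal(sum(e4$w), 1)
  expect_equal(e4$w_unknown, 0)
  # invariant over random raw weights
  set.seed(8)
  for (i in 1:50) {
    e <- postprocess_weights(rnorm(5))
    expect_true(all(e$w >= 0))
    expect_gte(e$w_unknown, 0)
    expect_equal(sum(e$w) + e$w_unknown, 1)
  }
  expect_error(postprocess_weights(c(1, NA)), "finite")
})

test_that("all four solvers agree on noiseless well-conditioned mixtures", {
  for (seed in 1:3) {
    mix <- random_mixture(n_genes = 80, seed = seed)
    ests <- lapply(c("nusvr", "pinv", "lm", "regnnls"), function(s)
      coef(deconvolve(mix$m, mix$B, solver = s)))
    for (i in 2:4)
      expect_lt(max(abs(ests[[1]] - ests[[i]])), 0.02)
    expect_lt(max(abs(ests[[2]][names(mix$w)] - mix$w)), 1e-6)
  }
})

test_that("positive rescaling of the bulk leaves normalized weights unchanged", {
  mix <- random_mixture(n_genes = 60, seed = 9)
  for (s in c("pinv", "regnnls")) {
    w1 <- deconvolve(mix$m, mix$B, solver = s)$w
    w2 <- deconvolve(mix$m * 7, mix$B, solver = s)$w
    expect_equal(w1 / sum(w1), w2 / sum(w2), tolerance = 1e-6)
  }
  w1 <- deconvolve(mix$m, mix$B, solver = "nusvr")$w
  w2 <- deconvolve(mix$m * 7, mix$B, solver = "nusvr")$w
  expect_equal(w1 / sum(w1), w2 / sum(w2), tolerance = 0.02)
})

test_that("mass of a type missing from the signature lands in the unknown fraction", {
  P <- orthogonal_profiles(n_types = 4)
  lin <- 2^P - 1  # linear-scale profiles, disjoint support
  lin <- sweep(lin, 2, colSums(lin), "/") * 1e6
  f <- 0.3
  m <- drop(lin %*% c(f, 0.3, 0.2, 0.2))
  names(m) <- rownames(lin)
  est <- deconvolve(m, lin[, -1], solver = "pinv")
  expect_lt(abs(est$w_unknown - f), 0.05)
  expect_error(deconvolve(m, lin[, -1], gene_set = "nope"), "intersection")
})

test_that("the estimator object supports the standard model interface", {
  mix <- random_mixture(seed = 11)
  est <- deconvolve(mix$m, mix$B, solver = "pinv")
  expect_s3_class(est, "composition_estimate")
  expect_named(coef(est), c("A", "B", "C", "unknown"))
  expect_equal(unname(fitted(est)), unname(mix$m), tolerance = 1e-6)
  expect_lt(max(abs(residuals(est))), 1e-6)
  s <- summary(est)
  expect_identical(s$cell_type, c("A", "B", "C", "unknown"))
  expect_output(print(est), "pinv")
})
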