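# Accuracy benchmarking: per-cell-type correlation between estimated and
# true fractions across samples, bootstrap uncertainty, RMSD, T-cell subset
# ratios, leave-one-type-out robustness, and the five-configuration
# benchmark over a synthetic cohort.

#' Pearson correlation between estimated and true fractions
#'
#' Correlation across samples for one cell type. A constant truth vector
#' makes the correlation undefined; it is reported as `NA` (not 0), since
#' correlation is not a meaningful accuracy measure when the true proportion
#' barely varies.
#'
#' @param est,truth per-sample fraction vectors (NA pairs dropped).
#' @return Pearson rho, or `NA`.
#' @export
correlation_accuracy <- function(est, truth) {
  ok <- is.finite(est) & is.finite(truth)
  est <- est[ok]; truth <- truth[ok]
  if (length(est) < 3) stopf("need at least 3 samples")
  if (stats::sd(truth) == 0 || stats::sd(est) == 0) return(NA_real_)
  stats::cor(est, truth)
}

#' Root-mean-square deviation between estimated and true fractions
#' @inheritParams correlation_accuracy
#' @return RMSD.
#' @export
rmsd_accuracy <- function(est, truth) {
  ok <- is.finite(est) & is.finite(truth)
  sqrt(mean((est[ok] - truth[ok])^2))
}

#' Bootstrap uncertainty of the accuracy correlation
#'
#' Resamples samples (not cells) with replacement, recomputes the Pearson
#' correlation, and summarizes the bootstrap distribution by its median and
#' quartiles. Degenerate resamples (constant truth or estimate) are redrawn.
#'
#' @inheritParams correlation_accuracy
#' @param reps bootstrap replications.
#' @param seed RNG seed.
#' @return Named vector `c(median, q25, q75)`.
#' @export
bootstrap_accuracy <- function(est, truth, reps = 100, seed = 1L) {
  ok <- is.finite(est) & is.finite(truth)
  est <- est[ok]; truth <- truth[ok]
  n <- length(est)
  if (n < 3) stopf("need at least 3 samples")
  with_seed(seed, {
    rho <- numeric(reps)
    for (r in seq_len(reps)) {
      for (tries in 1:100) {
        idx <- sample.int(n, n, replace = TRUE)
        if (stats::sd(truth[idx]) > 0 && stats::sd(est[idx]) > 0) break
      }
      rho[r] <- stats::cor(est[idx], truth[idx])
    }
    q <- stats::quantile(rho, c(0.5, 0.25, 0.75), names = FALSE)
    c(median = q[1], q25 = q[2], q75 = q[3])
  })
}

#' Therapeutically relevant T-cell subset ratios
#'
#' Computes Treg/CD4, CD8/Treg and CD4/CD8 from a composition vector.
#' Ratios whose denominator falls below `eps` are `NA` (flagged for
#' exclusion from downstream correlation).
#'
#' @param w named fraction vector containing `"CD4 T cell"`, `"CD8 T cell"`,
#'   `"Treg"` (missing subsets are treated as absent -> `NA` ratios).
#' @param eps minimal denominator.
#' @return Named vector `c("Treg/CD4", "CD8/Treg", "CD4/CD8")`.
#' @export
tcell_ratios <- function(w, eps = 1e-4) {
  g <- function(nm) if (nm %in% names(w)) unname(w[nm]) else NA_real_
  cd4 <- g("CD4 T cell"); cd8 <- g("CD8 T cell"); treg <- g("Treg")
  ratio <- function(num, den)
    if (!is.na(den) && den >= eps && !is.na(num)) num / den else NA_real_
  c("Treg/CD4" = ratio(treg, cd4),
    "CD8/Treg" = ratio(cd8, treg),
    "CD4/CD8" = ratio(cd4, cd8))
}

#' Aggregate T-cell subsets into a total T-cell fraction
#'
#' Replaces the subset entries by their sum under the name `"T cell"`;
#' the total over all entries (and hence any unknown fraction) is unchanged.
#'
#' @param w named fraction vector (or a `composition_estimate`).
#' @param subsets subset names to collapse.
#' @return Vector (or estimate) with subsets collapsed.
#' @export
aggregate_t_cells <- function(w, subsets = c("CD4 T cell", "CD8 T cell",
                                             "Treg")) {
  if (inherits(w, "composition_estimate")) {
    w$w <- aggregate_t_cells(w$w, subsets)
    return(w)
  }
  present <- intersect(subsets, names(w))
  if (length(present) == 0) return(c(w, "T cell" = 0))
  total <- sum(w[present])
  out <- w[setdiff(names(w), present)]
  c(out, "T cell" = unname(total))
}

# Internal: per-sample deconvolution of a cohort under one configuration.
# Returns samples x types estimate matrix (types never available under the
# configuration are NA) and the per-sample unknown fraction.
deconvolve_cohort_config <- function(cohort, bulks, config, annotations,
                                     gene_set, solver, space = "linear") {
  pooled <- list(expr = attr(bulks, "pooled_expr"), config = cohort$config)
  info <- cohort$sample_info
  types_all <- cohort$config$cell_types$name
  E <- matrix(NA_real_, nrow(info), length(types_all),
              dimnames = list(info$sample_id, types_all))
  wu <- stats::setNames(numeric(nrow(info)), info$sample_id)

  cacheB <- new.env(parent = emptyenv())
  get_B <- function(src, pat) {
    key <- switch(config, RGEP1 = "global", RGEP2 = "global",
                  RGEP3 = src, paste(src, pat))
    if (is.null(cacheB[[key]]))
      cacheB[[key]] <- suppressWarnings(build_rgep(
        pooled, annotations, config = config, source = src, patient = pat,
        space = space))
    cacheB[[key]]
  }
  for (i in seq_len(nrow(info))) {
    sid <- info$sample_id[i]
    B <- get_B(info$source[i], info$patient[i])
    est <- deconvolve(bulks[, sid], B, gene_set = gene_set, solver = solver)
    E[sid, names(est$w)] <- est$w
    E[sid, setdiff(types_all, names(est$w))] <- 0
    wu[sid] <- est$w_unknown
  }
  # types with no contributing cells anywhere in the configuration's pool
  # are never estimable: no estimate rather than zero
  ann <- annotations[annotations$cell_type != "unknown", ]
  pool <- switch(config,
                 RGEP1 = ann[ann$source == "blood", ],
                 ann)
  never <- setdiff(types_all, unique(pool$cell_type))
  E[, never] <- NA_real_
  list(estimates = E, unknown = wu)
}

#' Benchmark deconvolution accuracy across reference configurations
#'
#' For every sample of a (typically synthetic) cohort: builds the
#' pseudobulk, builds the configuration-appropriate signature matrix,
#' deconvolves, and compares estimated with true fractions. Reports, per
#' configuration and cell type (T subsets individually plus the aggregated
#' T-cell total), the Pearson correlation with bootstrap median/quartiles
#' and the RMSD, and the same for the three T-cell ratios.
#'
#' @param cohort an `sc_cohort`.
#' @param configs subset of [rgep_configs()].
#' @param gene_set deconvolution gene set; default the cohort's signature
#'   gene set.
#' @param solver deconvolution solver (see [deconvolve()]).
#' @param annotations cell annotations used for signature construction;
#'   default ground-truth labels (pass classifier output for the full
#'   pipeline).
#' @param bootstrap_reps,seed bootstrap settings.
#' @param ratio_eps minimal denominator for T-cell ratios.
#' @return Object of class `benchmark_report`: `per_type` and `ratios`
#'   data.frames, per-config estimate matrices, unknown fractions, and the
#'   truth matrix.
#' @export
run_benchmark <- function(cohort, configs = rgep_configs(), gene_set = NULL,
                          solver = c("nusvr", "pinv", "lm", "regnnls"),
                          annotations = NULL, bootstrap_reps = 100,
                          seed = 1L, ratio_eps = 1e-4) {
  solver <- match.arg(solver)
  if (is.null(gene_set)) gene_set <- cohort$signature_genes
  pooled <- cohort_expression(cohort)
  if (is.null(annotations)) annotations <- pooled$annotation

  bulks <- vapply(cohort$samples, function(s) build_pseudobulk(s$expr),
                  numeric(nrow(pooled$expr)))
  attr(bulks, "pooled_expr") <- pooled$expr

  truth <- cohort$truth_composition
  truth_agg <- cbind(truth, "T cell" = rowSums(
    truth[, intersect(colnames(truth), c("CD4 T cell", "CD8 T cell", "Treg")),
          drop = FALSE]))

  res <- lapply(stats::setNames(configs, configs), function(cf)
    deconvolve_cohort_config(cohort, bulks, cf, annotations, gene_set,
                             solver))

  per_type <- list()
  ratios <- list()
  for (cf in configs) {
    E <- res[[cf]]$estimates
    Eagg <- cbind(E, "T cell" = rowSums(
      E[, intersect(colnames(E), c("CD4 T cell", "CD8 T cell", "Treg")),
        drop = FALSE]))
    for (tp in colnames(truth_agg)) {
      est <- Eagg[, tp]
      if (all(is.na(est))) {
        per_type[[length(per_type) + 1]] <-
          data.frame(config = cf, cell_type = tp, rho = NA, rho_median = NA,
                     rho_q25 = NA, rho_q75 = NA, rmsd = NA, available = FALSE)
        next
      }
      tr <- truth_agg[, tp]
      rho <- correlation_accuracy(est, tr)
      bt <- if (is.na(rho)) c(median = NA, q25 = NA, q75 = NA)
            else bootstrap_accuracy(est, tr, reps = bootstrap_reps,
                                    seed = seed)
      per_type[[length(per_type) + 1]] <-
        data.frame(config = cf, cell_type = tp, rho = rho,
                   rho_median = unname(bt["median"]),
                   rho_q25 = unname(bt["q25"]), rho_q75 = unname(bt["q75"]),
                   rmsd = rmsd_accuracy(est, tr), available = TRUE)
    }
    # T-cell ratio accuracy
    er <- t(apply(E, 1, tcell_ratios, eps = ratio_eps))
    tr_r <- t(apply(truth, 1, tcell_ratios, eps = ratio_eps))
    for (rn in colnames(er)) {
      ok <- is.finite(er[, rn]) & is.finite(tr_r[, rn])
      if (sum(ok) < 3) {
        ratios[[length(ratios) + 1]] <-
          data.frame(config = cf, ratio = rn, rho = NA, rho_median = NA,
                     rho_q25 = NA, rho_q75 = NA, rmsd = NA,
                     n_samples = sum(ok))
        next
      }
      rho <- correlation_accuracy(er[ok, rn], tr_r[ok, rn])
      bt <- if (is.na(rho)) c(median = NA, q25 = NA, q75 = NA)
            else bootstrap_accuracy(er[ok, rn], tr_r[ok, rn],
                                    reps = bootstrap_reps, seed = seed)
      ratios[[length(ratios) + 1]] <-
        data.frame(config = cf, ratio = rn, rho = rho,
                   rho_median = unname(bt["median"]),
                   rho_q25 = unname(bt["q25"]), rho_q75 = unname(bt["q75"]),
                   rmsd = rmsd_accuracy(er[ok, rn], tr_r[ok, rn]),
                   n_samples = sum(ok))
    }
  }
  structure(list(
    per_type = do.call(rbind, c(per_type, make.row.names = FALSE)),
    ratios = do.call(rbind, c(ratios, make.row.names = FALSE)),
    estimates = lapply(res, `[[`, "estimates"),
    unknown = vapply(res, `[[`, numeric(nrow(truth)), "unknown"),
    truth = truth_agg, solver = solver, configs = configs),
    class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, digits = 3, ...) {
  cat(sprintf("Deconvolution benchmark (%s): %d configurations\n",
              x$solver, length(x$configs)))
  agg <- stats::aggregate(rho ~ config, data = x$per_type, FUN = stats::median,
                          na.action = stats::na.omit)
  agg$rho <- round(agg$rho, digits)
  names(agg)[2] <- "median_rho"
  print(agg[match(x$configs, agg$config), ], row.names = FALSE)
  invisible(x)
}

#' Leave-one-type-out signature robustness
#'
#' Removes one cell-type column at a time from the indication-specific
#' (RGEP3-style) signatures, re-deconvolves all samples and reports the
#' change in per-type accuracy relative to the full signature. Closely
#' related retained types absorb the removed type's mass and degrade most.
#'
#' @inheritParams run_benchmark
#' @return data.frame with `removed_type`, `cell_type`, `rho_full`,
#'   `rho_removed`, `delta_rho` (removed type's own row has `NA`
#'   `rho_removed`).
#' @export
leave_one_type_out <- function(cohort, gene_set = NULL,
                               solver = c("pinv", "nusvr", "lm", "regnnls"),
                               annotations = NULL) {
  solver <- match.arg(solver)
  if (is.null(gene_set)) gene_set <- cohort$signature_genes
  pooled <- cohort_expression(cohort)
  if (is.null(annotations)) annotations <- pooled$annotation
  info <- cohort$sample_info
  bulks <- vapply(cohort$samples, function(s) build_pseudobulk(s$expr),
                  numeric(nrow(pooled$expr)))
  cohlike <- list(expr = pooled$expr, config = cohort$config)
  sigs <- lapply(stats::setNames(unique(info$source), unique(info$source)),
                 function(src) suppressWarnings(
                   build_rgep(cohlike, annotations, config = "RGEP3",
                              source = src, space = "linear")))
  truth <- cohort$truth_composition

  run_with <- function(drop_type) {
    E <- matrix(NA_real_, nrow(info), ncol(truth),
                dimnames = list(info$sample_id, colnames(truth)))
    for (i in seq_len(nrow(info))) {
      B <- sigs[[info$source[i]]]
      B <- B[, setdiff(colnames(B), drop_type), drop = FALSE]
      est <- deconvolve(bulks[, info$sample_id[i]], B, gene_set = gene_set,
                        solver = solver)
      E[i, names(est$w)] <- est$w
      E[i, setdiff(colnames(truth), names(est$w))] <- 0
    }
    if (!is.null(drop_type)) E[, drop_type] <- NA_real_
    E
  }
  rho_of <- function(E) vapply(colnames(truth), function(tp) {
    if (all(is.na(E[, tp]))) return(NA_real_)
    correlation_accuracy(E[, tp], truth[, tp])
  }, numeric(1))

  rho_full <- rho_of(run_with(NULL))
  out <- list()
  for (dt in colnames(truth)) {
    rho_rm <- rho_of(run_with(dt))
    out[[dt]] <- data.frame(removed_type = dt, cell_type = colnames(truth),
                            rho_full = unname(rho_full),
                            rho_removed = unname(rho_rm),
                            delta_rho = unname(rho_rm - rho_full),
                            row.names = NULL)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
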