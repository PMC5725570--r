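# Patient-specific tumour expression purification: subtract the explained
# non-malignant portion from the bulk profile and rescale by the estimated
# tumour fraction,
#   t = (m - B_nontumour w_nontumour) / w_tumour.

#' Estimate the tumour-cell expression profile of one sample
#'
#' Applies the weighted-subtraction formula genewise. Negative purified
#' values (measurement noise pushed below zero) are floored at 0 and
#' counted. Fails when the tumour fraction is at or below `eps`
#' (purification is uninformative without tumour signal) and warns below
#' 0.2, where subtraction is known to add little.
#'
#' @param m named bulk gene vector.
#' @param B_nontumor genes x types signature matrix of the non-malignant
#'   types.
#' @param w_nontumor their estimated fractions (named, aligned to columns).
#' @param w_tumor estimated tumour fraction.
#' @param eps minimal usable tumour fraction.
#' @return Object of class `tumor_profile_estimate`: purified profile `t`
#'   (pre-floor copy in `t_raw`), floored-gene count, tumour fraction used.
#' @export
estimate_tumor_profile <- function(m, B_nontumor, w_nontumor, w_tumor,
                                   eps = 0.01) {
  if (w_tumor <= eps)
    stopf("tumour content (%.3f) too low for purification", w_tumor)
  if (w_tumor < 0.2)
    warnf("tumour content %.2f < 0.2: purified profile will be unreliable",
          w_tumor)
  if (length(w_nontumor) != ncol(B_nontumor))
    stopf("w_nontumor must match the signature columns")
  if (!is.null(names(w_nontumor)) && !is.null(colnames(B_nontumor)))
    w_nontumor <- w_nontumor[colnames(B_nontumor)]
  genes <- intersect(names(m), rownames(B_nontumor))
  if (length(genes) == 0) stopf("no common genes")
  t_raw <- (m[genes] - drop(B_nontumor[genes, , drop = FALSE] %*%
                              w_nontumor)) / w_tumor
  t_flo <- pmax(t_raw, 0)
  structure(list(t = t_flo, t_raw = t_raw, n_floored = sum(t_raw < 0),
                 tumor_fraction_used = w_tumor),
            class = "tumor_profile_estimate")
}

#' @export
print.tumor_profile_estimate <- function(x, ...) {
  cat(sprintf(
    "Purified tumour profile: %d genes, tumour fraction %.3f, %d floored\n",
    length(x$t), x$tumor_fraction_used, x$n_floored))
  invisible(x)
}

#' Baseline correlation between non-malignant and tumour profiles
#'
#' Genes such as housekeeping genes correlate between all cells irrespective
#' of type, so any non-malignant profile shows a baseline correlation with
#' the true tumour profile; purification is only useful to the extent it
#' exceeds this baseline.
#'
#' @param nontumor_profiles genes x types matrix of non-malignant consensus
#'   profiles (log2 scale recommended for correlation).
#' @param t_true true tumour profile on the same scale and gene index.
#' @return list with `per_type` correlations and their `mean`.
#' @export
baseline_correlation <- function(nontumor_profiles, t_true) {
  genes <- intersect(rownames(nontumor_profiles), names(t_true))
  per <- apply(nontumor_profiles[genes, , drop = FALSE], 2,
               stats::cor, y = t_true[genes])
  list(per_type = per, mean = mean(per))
}

#' Tumour-profile accuracy as a function of tumour content
#'
#' For every cohort sample containing malignant cells: deconvolve its
#' pseudobulk against the indication-specific signature, purify the tumour
#' profile by weighted subtraction, and correlate it (log2 scale, all genes)
#' with the sample's true tumour profile - the realized mean of its
#' malignant cells. The uncorrected bulk's correlation with the truth is
#' reported alongside for the improvement comparison, and a gene-bootstrap
#' quartile band quantifies uncertainty.
#'
#' @param cohort an `sc_cohort`.
#' @param gene_set deconvolution gene set (default the cohort's signature
#'   set; correlation always uses all genes).
#' @param solver deconvolution solver.
#' @param config signature configuration for the non-malignant profiles.
#' @param use_true_composition bypass deconvolution and use ground-truth
#'   fractions in the subtraction (isolates the purification step).
#' @param eps minimal tumour fraction; samples whose estimated fraction is
#'   at or below it are skipped with `NA` results.
#' @param bootstrap_reps,seed gene-bootstrap settings.
#' @return data.frame per sample: true and estimated tumour fraction,
#'   `rho_est` (purified vs true), `rho_bulk` (uncorrected bulk vs true),
#'   bootstrap quartiles of `rho_est`, floored-gene count.
#' @export
profile_accuracy_vs_content <- function(cohort, gene_set = NULL,
                                        solver = c("nusvr", "pinv", "lm",
                                                   "regnnls"),
                                        config = c("RGEP3", "CNTR1", "RGEP2"),
                                        use_true_composition = FALSE,
                                        eps = 0.01, bootstrap_reps = 100,
                                        seed = 1L) {
  solver <- match.arg(solver)
  config <- match.arg(config)
  if (is.null(gene_set)) gene_set <- cohort$signature_genes
  pooled <- cohort_expression(cohort)
  annotations <- pooled$annotation
  cohlike <- list(expr = pooled$expr, config = cohort$config)
  mal_types <- cohort$config$cell_types$name[cohort$config$cell_types$is_malignant]
  info <- cohort$sample_info
  truth <- cohort$truth_composition

  out <- list()
  for (i in seq_len(nrow(info))) {
    sid <- info$sample_id[i]
    true_mal <- truth[sid, mal_types]
    if (sum(true_mal) <= 0) next  # samples without tumour cells excluded
    mal <- mal_types[which.max(true_mal)]
    smp <- cohort$samples[[sid]]
    is_mal_cell <- smp$annotation$cell_type == mal
    t_true <- rowMeans(smp$expr[, is_mal_cell, drop = FALSE])
    bulk <- build_pseudobulk(smp$expr)

    B <- suppressWarnings(build_rgep(cohlike, annotations, config = config,
                                     source = info$source[i], patient = sid,
                                     space = "linear"))
    if (use_true_composition) {
      w <- truth[sid, colnames(B)]
      names(w) <- colnames(B)
    } else {
      est <- deconvolve(bulk, B, gene_set = gene_set, solver = solver)
      w <- est$w
    }
    w_tum <- sum(w[intersect(names(w), mal_types)])
    nt <- setdiff(colnames(B), mal_types)
    row <- data.frame(sample_id = sid, source = info$source[i],
                      true_fraction = unname(sum(true_mal)),
                      est_fraction = unname(w_tum),
                      rho_est = NA_real_, rho_bulk = NA_real_,
                      rho_q25 = NA_real_, rho_q75 = NA_real_,
                      n_floored = NA_integer_)
    if (w_tum > eps) {
      tp <- suppressWarnings(estimate_tumor_profile(
        bulk, B[, nt, drop = FALSE], w[nt], w_tum, eps = eps))
      lt <- log2(tp$t + 1)
      ltt <- log2(t_true[names(tp$t)] + 1)
      lb <- log2(bulk[names(tp$t)] + 1)
      row$rho_est <- stats::cor(lt, ltt)
      row$rho_bulk <- stats::cor(lb, ltt)
      row$n_floored <- tp$n_floored
      bt <- with_seed(seed + i, {
        n <- length(lt)
        vapply(seq_len(bootstrap_reps), function(r) {
          idx <- sample.int(n, n, replace = TRUE)
          stats::cor(lt[idx], ltt[idx])
        }, numeric(1))
      })
      row$rho_q25 <- stats::quantile(bt, 0.25, names = FALSE)
      row$rho_q75 <- stats::quantile(bt, 0.75, names = FALSE)
    }
    out[[sid]] <- row
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
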