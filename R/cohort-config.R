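# Configuration for the synthetic single-cell cohort generator.

#' Default cell-type table for synthetic cohorts
#'
#' Nine major cell types plus three T-cell subtypes, mirroring a typical
#' tumour-microenvironment panel: immune types found in blood and tumours,
#' stromal types (cancer-associated fibroblasts, endothelial cells) found
#' only in tumour tissue, and one malignant type per tumour indication.
#' T subtypes carry `parent = "T cell"` and are the simulated leaves; the
#' parent itself is never simulated directly.
#'
#' @return data.frame with columns `name`, `is_malignant`, `parent`.
#' @export
default_cell_types <- function() {
  data.frame(
    name = c("CD4 T cell", "CD8 T cell", "Treg",
             "B cell", "Macrophage", "NK cell", "Dendritic cell",
             "CAF", "EC", "Melanoma", "Ovarian carcinoma"),
    is_malignant = c(rep(FALSE, 9), TRUE, TRUE),
    parent = c(rep("T cell", 3), rep(NA_character_, 8)),
    stringsAsFactors = FALSE
  )
}

default_composition_alpha <- function(types) {
  sources <- c("blood", "tumorA", "tumorB")
  a <- matrix(0, length(sources), nrow(types),
              dimnames = list(sources, types$name))
  a["blood", ] <- c(6, 4, 1, 3, 2.5, 1.5, 0.8, 0, 0, 0, 0)
  a["tumorA", ] <- c(2, 2, 0.8, 1, 1.5, 0.5, 0.4, 1, 1, 7, 0)
  a["tumorB", ] <- c(2, 2, 1, 1, 3, 0.8, 0.5, 1, 1, 0, 5)
  a
}

#' Configure a synthetic single-cell cohort
#'
#' Defines the statistical structure of a simulated multi-source single-cell
#' study: a gene universe partitioned into marker genes (driving AND/OR/NOT
#' classification logic), housekeeping genes (one stable expression level
#' across every cell type and tissue source) and background genes; per-type
#' mean log2 expression profiles built from a shared gene baseline plus
#' type-specific effects; tissue-source shifts for non-blood sources;
#' patient-specific effects for malignant cells; per-cell Gaussian noise and
#' Bernoulli dropout on the log2 scale.
#'
#' Default sample counts per source are (4, 19, 4), i.e. 27 samples: four
#' blood donors, nineteen patients of one tumour indication and four of a
#' second.
#'
#' @param n_genes number of genes in the simulated universe.
#' @param cell_types data.frame as [default_cell_types()].
#' @param n_patients_per_source named counts for sources
#'   `c(blood=, tumorA=, tumorB=)`.
#' @param cells_per_sample cells simulated per sample.
#' @param composition_alpha sources x types Dirichlet concentration matrix;
#'   zero entries mark types absent from a source. Malignant types must be
#'   zero for blood.
#' @param base_expression_scale mean log2 expression of expressed background
#'   genes.
#' @param type_effect_sd sd of per-gene type-specific deviations from the
#'   shared baseline (controls between-type profile correlation).
#' @param subset_effect_sd sd of T-subtype deviations from the shared T-cell
#'   base profile (subtypes form a continuum around one lineage profile).
#' @param marker_fraction fraction of genes reserved as markers.
#' @param hk_fraction fraction of genes reserved as housekeeping genes.
#' @param marker_level log2 expression of a marker gene in the cell types it
#'   marks (zero elsewhere).
#' @param source_shift_sd sd of per-gene log2 shifts applied to non-blood
#'   sources (tissue-microenvironment effect).
#' @param patient_shift_sd sd of per-gene patient effects on malignant
#'   profiles.
#' @param noise_sd per-cell log2 noise sd.
#' @param dropout_rate maximal dropout probability. An entry with log2 value
#'   `y` is zeroed with probability
#'   `dropout_rate * plogis(dropout_midpoint - y)`: lowly expressed genes
#'   drop out at close to the full rate, highly expressed genes almost
#'   never, matching the expression-dependent zero inflation of real
#'   single-cell data.
#' @param dropout_midpoint log2 expression at which the dropout probability
#'   is half of `dropout_rate`.
#' @param n_signature_genes size of the simulated signature gene set
#'   (markers plus the most type-discriminating background genes), the
#'   analogue of a merged deconvolution gene list.
#' @param seed integer seed; the cohort is reproducible from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_genes = 1500,
                          cell_types = default_cell_types(),
                          n_patients_per_source = c(blood = 4, tumorA = 19,
                                                    tumorB = 4),
                          cells_per_sample = 200,
                          composition_alpha = NULL,
                          base_expression_scale = 4,
                          type_effect_sd = 1.1,
                          subset_effect_sd = 0.5,
                          marker_fraction = 0.032,
                          hk_fraction = 0.1,
                          marker_level = 9,
                          source_shift_sd = 0.5,
                          patient_shift_sd = 0.5,
                          noise_sd = 0.3,
                          dropout_rate = 0.5,
                          dropout_midpoint = 2,
                          n_signature_genes = 300,
                          seed = 1L) {
  if (is.null(composition_alpha))
    composition_alpha <- default_composition_alpha(cell_types)
  cfg <- structure(
    list(n_genes = n_genes, cell_types = cell_types,
         n_patients_per_source = n_patients_per_source,
         cells_per_sample = cells_per_sample,
         composition_alpha = composition_alpha,
         base_expression_scale = base_expression_scale,
         type_effect_sd = type_effect_sd,
         subset_effect_sd = subset_effect_sd,
         marker_fraction = marker_fraction, hk_fraction = hk_fraction,
         marker_level = marker_level,
         source_shift_sd = source_shift_sd,
         patient_shift_sd = patient_shift_sd,
         noise_sd = noise_sd, dropout_rate = dropout_rate,
         dropout_midpoint = dropout_midpoint,
         n_signature_genes = n_signature_genes,
         seed = as.integer(seed)),
    class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d genes, %d leaf cell types, %d samples x %d cells\n",
              x$n_genes, nrow(x$cell_types),
              sum(x$n_patients_per_source), x$cells_per_sample))
  cat(sprintf("  source shift sd %.2f, noise sd %.2f, dropout %.2f, seed %d\n",
              x$source_shift_sd, x$noise_sd, x$dropout_rate, x$seed))
  invisible(x)
}

validate_cohort_config <- function(cfg) {
  ct <- cfg$cell_types
  if (!all(c("name", "is_malignant", "parent") %in% names(ct)))
    stopf("cell_types needs columns name, is_malignant, parent")
  if (anyDuplicated(ct$name)) stopf("duplicate cell type names")
  fr <- c(marker_fraction = cfg$marker_fraction, hk_fraction = cfg$hk_fraction,
          dropout_rate = cfg$dropout_rate)
  if (any(fr < 0 | fr > 1)) stopf("fractions must lie in [0, 1]")
  if (cfg$marker_fraction + cfg$hk_fraction >= 1)
    stopf("marker_fraction + hk_fraction must be < 1")
  if (any(c(cfg$source_shift_sd, cfg$patient_shift_sd, cfg$noise_sd) < 0))
    stopf("shift and noise sds must be non-negative")
  a <- cfg$composition_alpha
  if (!identical(colnames(a), ct$name))
    stopf("composition_alpha columns must match cell type names")
  if (any(a < 0)) stopf("composition_alpha must be non-negative")
  if (any(a["blood", ct$is_malignant] > 0))
    stopf("malignant cell types must be absent from the blood source")
  if (all(rowSums(a) <= 0)) stopf("composition_alpha is all zero")
  srcs <- names(cfg$n_patients_per_source)
  if (!identical(sort(srcs), sort(rownames(a))))
    stopf("n_patients_per_source names must match composition_alpha sources")
  invisible(cfg)
}
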