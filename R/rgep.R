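# Pseudobulk construction and the five reference-profile (signature matrix)
# configurations of increasing tissue and patient specificity:
#   RGEP1  blood-derived consensus profiles only
#   RGEP2  consensus over all tissue sources
#   RGEP3  consensus from the target sample's source (indication-specific)
#   CNTR1  RGEP3 with a patient-specific malignant column
#   CNTR2  every column patient-specific
# The controls are not applicable in practice (they require the patient's own
# single cells) but bound what deconvolution can achieve.

#' Pseudobulk profile of a single-cell sample
#'
#' Averages the TPM columns of a sample's cells and rescales to TPM sum 1e6,
#' the in-silico analogue of aggregating reads from all cell barcodes. Under
#' equal per-cell depth the pseudobulk is an exact linear mixture of the
#' per-type mean profiles, weighted by the realized cell-type fractions.
#'
#' @param m genes x cells TPM matrix with at least one cell.
#' @return Named gene vector summing to 1e6 (attribute
#'   `provenance = "pseudobulk"`).
#' @export
build_pseudobulk <- function(m) {
  check_matrix(m)
  if (ncol(m) == 0) stopf("cannot build a pseudobulk from an empty sample")
  v <- rowMeans(m)
  v <- v / sum(v) * 1e6
  attr(v, "provenance") <- "pseudobulk"
  v
}

rgep_configs <- function() c("RGEP1", "RGEP2", "RGEP3", "CNTR1", "CNTR2")

#' Build a reference gene expression profile (signature) matrix
#'
#' Computes one consensus column per cell type as the cell-weighted mean of
#' the selected cells' profiles. Which cells contribute depends on the
#' configuration: `RGEP1` uses blood-source cells only (tumour-associated
#' types therefore have no column), `RGEP2` pools all sources, `RGEP3` uses
#' the target source only, `CNTR1` is `RGEP3` with the malignant column
#' restricted to the target patient, and `CNTR2` restricts every column to
#' the target patient. Cells labelled `"unknown"` are excluded; types with
#' no contributing cells are dropped with a warning (their mass then appears
#' in the unknown fraction after deconvolution).
#'
#' @param cohort an `sc_cohort`, or a list with elements `expr`
#'   (genes x cells TPM matrix) and `config` (for malignant-type lookup).
#' @param annotations cell annotation data.frame (`cell_id`, `cell_type`,
#'   `patient`, `source`); defaults to the cohort's ground-truth labels.
#' @param config one of `"RGEP1"`, `"RGEP2"`, `"RGEP3"`, `"CNTR1"`,
#'   `"CNTR2"`.
#' @param source target sample's tissue source (required for RGEP3/CNTR1/2).
#' @param patient target patient id (required for CNTR1/2).
#' @param space `"log"` averages cells on the log2(TPM+1) scale and reports
#'   the column on that scale; `"linear"` averages TPM columns.
#' @return genes x types signature matrix with attributes `config`,
#'   `context` and `space`.
#' @export
build_rgep <- function(cohort, annotations = NULL,
                       config = rgep_configs(),
                       source = NULL, patient = NULL,
                       space = c("log", "linear")) {
  config <- match.arg(config)
  space <- match.arg(space)
  if (inherits(cohort, "sc_cohort")) {
    pooled <- cohort_expression(cohort)
    expr <- pooled$expr
    if (is.null(annotations)) annotations <- pooled$annotation
    ct <- cohort$config$cell_types
  } else {
    expr <- cohort$expr
    ct <- cohort$config$cell_types
    if (is.null(annotations)) stopf("annotations are required")
  }
  if (!all(annotations$cell_id %in% colnames(expr)))
    stopf("annotations contain cells absent from the expression matrix")
  ann <- annotations[annotations$cell_type != "unknown", , drop = FALSE]
  mal_types <- ct$name[ct$is_malignant]

  if (config %in% c("RGEP3", "CNTR1", "CNTR2") && is.null(source))
    stopf("%s requires a target source", config)
  if (config %in% c("CNTR1", "CNTR2") && is.null(patient))
    stopf("%s requires a target patient", config)

  sel <- switch(config,
    RGEP1 = ann$source == "blood",
    RGEP2 = rep(TRUE, nrow(ann)),
    RGEP3 = ,
    CNTR1 = ann$source == source,
    CNTR2 = ann$patient == patient)
  ann <- ann[sel, , drop = FALSE]
  if (config == "CNTR1")
    ann <- ann[!(ann$cell_type %in% mal_types) | ann$patient == patient, ,
               drop = FALSE]

  types <- unique(ann$cell_type)
  vals <- if (space == "log") log2(expr + 1) else expr
  cols <- lapply(types, function(tp) {
    cells <- ann$cell_id[ann$cell_type == tp]
    rowMeans(vals[, cells, drop = FALSE])
  })
  dropped <- character()
  # types known to the cohort but with no contributing cells
  all_types <- unique(annotations$cell_type[annotations$cell_type != "unknown"])
  dropped <- setdiff(all_types, types)
  if (length(dropped))
    warnf("no contributing cells for type(s) %s under %s; column(s) dropped",
          paste(dropped, collapse = ", "), config)
  B <- do.call(cbind, cols)
  dimnames(B) <- list(rownames(expr), types)
  attr(B, "config") <- config
  attr(B, "context") <- list(source = source, patient = patient)
  attr(B, "space") <- space
  B
}
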