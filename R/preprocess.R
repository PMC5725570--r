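# Preprocessing: TPM -> log2 -> housekeeping normalization, gene-symbol
# repair, gene-set filtering. All downstream analyses (classification,
# reference-profile construction, deconvolution) consume matrices produced
# here.

#' Log-transform a TPM expression matrix
#'
#' Applies the elementwise transform `y = log2(TPM + 1)` used throughout the
#' pipeline. Refuses to transform a matrix already on the log scale so the
#' transform cannot be applied twice by accident.
#'
#' @param m genes x columns matrix on TPM scale (see [expr_scale()]).
#' @return Matrix of the same shape with scale `"LOG2"`.
#' @examples
#' m <- matrix(c(0, 1, 7, 3), 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
#' log_transform(rescale_tpm(m) * 0 + m) # small demo values
#' @export
log_transform <- function(m) {
  check_matrix(m)
  if (expr_scale(m) == "LOG2")
    stopf("matrix is already LOG2-scaled; refusing to log-transform twice")
  if (any(m < 0)) stopf("TPM matrix has negative entries")
  out <- log2(m + 1)
  expr_scale(out) <- "LOG2"
  out
}

#' Housekeeping-gene normalization
#'
#' Rescales every column of a log2 expression matrix so that its mean
#' expression over a housekeeping gene set equals the global housekeeping
#' mean: column i is multiplied by `HKbar / HK_i`, where `HK_i` is column i's
#' mean over the housekeeping genes and `HKbar` is the mean of the `HK_i`
#' (or an externally supplied target, so that independently processed data
#' sets can share one scale).
#'
#' The operation is idempotent: after normalization every column's
#' housekeeping mean equals `HKbar`, so a second application multiplies by 1.
#'
#' @param m genes x columns matrix on LOG2 scale.
#' @param hk_genes character vector of housekeeping gene ids (genes missing
#'   from the matrix are ignored; at least one must be present).
#' @param target optional external global housekeeping mean `HKbar`; default
#'   is the mean over the columns of `m`.
#' @return Normalized matrix, with attributes `hk_target` (the `HKbar` used)
#'   and `hk_factors` (per-column scale factors).
#' @export
housekeeping_normalize <- function(m, hk_genes, target = NULL) {
  check_matrix(m)
  if (expr_scale(m, default = "LOG2") != "LOG2")
    stopf("housekeeping normalization expects a LOG2 matrix; run log_transform() first")
  hk <- intersect(hk_genes, rownames(m))
  if (length(hk) == 0)
    stopf("no housekeeping genes found in the matrix")
  hk_i <- colMeans(m[hk, , drop = FALSE])
  bad <- hk_i <= 0
  if (any(bad))
    stopf("zero housekeeping mean in column(s): %s",
          paste(colnames(m)[bad], collapse = ", "))
  hkbar <- if (is.null(target)) mean(hk_i) else target
  fac <- hkbar / hk_i
  out <- sweep(m, 2, fac, "*")
  expr_scale(out) <- "LOG2"
  attr(out, "hk_target") <- hkbar
  attr(out, "hk_factors") <- fac
  out
}

# Gene symbols corrupted by spreadsheet date auto-conversion, with the HGNC
# symbols they stand for. Only symbols that round-trip to a date are listed.
excel_symbol_table <- function() {
  data.frame(
    month = c(rep("Mar", 11), rep("Sep", 12), rep("Dec", 2)),
    day = c(1:11, 1:12, 1:2),
    symbol = c(paste0("MARCH", 1:11), paste0("SEPT", 1:12),
               paste0("DEC", 1:2)),
    stringsAsFactors = FALSE
  )
}

#' Repair gene symbols mangled by spreadsheet date conversion
#'
#' Gene families such as MARCH, SEPT and DEC are silently converted to dates
#' by spreadsheet software ("MARCH1" becomes "1-Mar"). This maps date-form
#' identifiers back to the HGNC symbols; all other identifiers pass through
#' unchanged. Recognized dialects: `"1-Mar"`, `"Mar-1"`/`"Mar-01"`, and
#' dotted day.month(.year) dates such as `"01.03.2016"`.
#'
#' @param gene_ids character vector of gene identifiers.
#' @return Repaired identifier vector (same length/order). Errors if the
#'   repair would create duplicate identifiers.
#' @examples
#' repair_excel_gene_symbols(c("1-Mar", "GAPDH", "1-Sep"))
#' @export
repair_excel_gene_symbols <- function(gene_ids) {
  tab <- excel_symbol_table()
  key <- paste(tab$month, tab$day)
  lookup <- stats::setNames(tab$symbol, key)
  out <- gene_ids

  mnum <- c(Mar = 3, Sep = 9, Dec = 12)
  hit1 <- regmatches(gene_ids,
                     regexec("^([0-9]{1,2})-(Mar|Sep|Dec)$", gene_ids))
  hit2 <- regmatches(gene_ids,
                     regexec("^(Mar|Sep|Dec)-([0-9]{1,2})$", gene_ids))
  hit3 <- regmatches(gene_ids,
                     regexec("^([0-9]{1,2})\\.(03|09|12)(\\.[0-9]{4})?$",
                             gene_ids))
  for (i in seq_along(gene_ids)) {
    k <- NULL
    if (length(hit1[[i]]))
      k <- paste(hit1[[i]][3], as.integer(hit1[[i]][2]))
    else if (length(hit2[[i]]))
      k <- paste(hit2[[i]][2], as.integer(hit2[[i]][3]))
    else if (length(hit3[[i]])) {
      mon <- names(mnum)[match(as.integer(hit3[[i]][3]), mnum)]
      k <- paste(mon, as.integer(hit3[[i]][2]))
    }
    if (!is.null(k) && k %in% names(lookup)) out[i] <- lookup[[k]]
  }
  dup <- out[duplicated(out)]
  if (length(dup))
    stopf("symbol repair would create duplicate ids: %s",
          paste(unique(dup), collapse = ", "))
  out
}

#' Restrict an expression matrix to a gene set
#'
#' Subsets rows to the genes of a signature/classification gene set,
#' preserving the gene set's order. The number of genes retained is recorded
#' in the `n_retained` attribute (signature gene lists routinely contain
#' genes absent from a given data set).
#'
#' @param m genes x columns matrix.
#' @param gene_set character vector of gene ids (non-empty).
#' @param on_missing `"drop"` (default) silently drops absent genes;
#'   `"error"` fails if any are absent.
#' @return Row-subset matrix; errors if the intersection is empty.
#' @export
filter_to_gene_set <- function(m, gene_set, on_missing = c("drop", "error")) {
  check_matrix(m)
  on_missing <- match.arg(on_missing)
  if (length(gene_set) == 0) stopf("gene_set is empty")
  keep <- gene_set[gene_set %in% rownames(m)]
  if (length(keep) == 0)
    stopf("no genes of the gene set are present in the matrix")
  if (on_missing == "error" && length(keep) < length(gene_set))
    stopf("%d gene(s) of the gene set are absent from the matrix",
          length(gene_set) - length(keep))
  out <- m[keep, , drop = FALSE]
  expr_scale(out) <- expr_scale(m, default = "TPM")
  attr(out, "n_retained") <- length(keep)
  out
}
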