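# Plain-text readers and writers for the pipeline's exchange formats:
# genes x columns TSV matrices, MatrixMarket sparse triplets with gene and
# barcode index files, annotation tables, marker-spec JSON, gene lists with
# '#' comments, and whole-cohort export with a YAML configuration sidecar.

#' Write / read an expression matrix as TSV
#'
#' Genes x columns with a `gene` id column and a header row of column ids.
#'
#' @param m matrix with gene rownames and column ids.
#' @param path file path.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param scale scale flag attached to the matrix read back.
#' @export
read_expression_tsv <- function(path, scale = "TPM") {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  expr_scale(m) <- scale
  m
}

#' Write / read an expression matrix in MatrixMarket layout
#'
#' Writes `matrix.mtx` (sparse triplets), `genes.tsv` and `barcodes.tsv`
#' into a directory, the layout common for sparse single-cell matrices.
#'
#' @param m matrix (genes x cells).
#' @param dir output directory (created if needed).
#' @export
write_expression_mtx <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "genes.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_expression_mtx
#' @param scale scale flag attached to the matrix read back.
#' @export
read_expression_mtx <- function(dir, scale = "TPM") {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  expr_scale(m) <- scale
  m
}

#' Write / read a cell annotation table (TSV)
#' @param annotation data.frame with `cell_id`, `cell_type`, `patient`,
#'   `source`.
#' @param path file path.
#' @export
write_annotation_tsv <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a marker specification (JSON)
#'
#' Format: `{"type": {"AND": [...], "OR": [...], "NOT": [...]}}`.
#'
#' @param spec named list of `list(AND=, OR=, NOT=)`.
#' @param path file path.
#' @export
write_marker_spec <- function(spec, path) {
  jsonlite::write_json(spec, path, pretty = TRUE)
  invisible(path)
}

#' @rdname write_marker_spec
#' @export
read_marker_spec <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(spec, function(x)
    list(AND = as.character(x$AND %||% character()),
         OR = as.character(x$OR %||% character()),
         NOT = as.character(x$NOT %||% character())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a gene list (one symbol per line, '#' comments)
#' @param genes character vector.
#' @param path file path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Export a synthetic cohort to a directory
#'
#' One subdirectory per sample (matrix as TSV or MatrixMarket), a combined
#' annotation TSV, marker-spec JSONs, housekeeping and signature gene lists,
#' the true composition matrix, and the configuration as YAML.
#'
#' @param cohort an `sc_cohort`.
#' @param dir output directory.
#' @param format `"tsv"` or `"mtx"` per-sample matrix format.
#' @export
write_cohort <- function(cohort, dir, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(cohort$samples)) {
    sd <- file.path(dir, "samples", sid)
    dir.create(sd, showWarnings = FALSE, recursive = TRUE)
    if (format == "tsv")
      write_expression_tsv(cohort$samples[[sid]]$expr,
                           file.path(sd, "matrix.tsv"))
    else write_expression_mtx(cohort$samples[[sid]]$expr, sd)
  }
  ann <- do.call(rbind, c(lapply(cohort$samples, `[[`, "annotation"),
                          make.row.names = FALSE))
  write_annotation_tsv(ann, file.path(dir, "annotation.tsv"))
  write_marker_spec(cohort$marker_spec_major,
                    file.path(dir, "markers_major.json"))
  write_marker_spec(cohort$marker_spec_tsub,
                    file.path(dir, "markers_tsub.json"))
  write_gene_list(cohort$hk_genes, file.path(dir, "housekeeping.txt"))
  write_gene_list(cohort$signature_genes, file.path(dir, "signature.txt"))
  utils::write.table(
    data.frame(sample_id = rownames(cohort$truth_composition),
               cohort$truth_composition, check.names = FALSE),
    file.path(dir, "true_composition.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  cfg <- cohort$config
  cfg$cell_types <- as.list(cfg$cell_types)
  cfg$composition_alpha <- apply(cohort$config$composition_alpha, 1, as.list,
                                 simplify = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
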