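# Two-stage marker-driven single-cell classification:
# t-SNE embedding -> DBSCAN clustering -> AND/OR/NOT marker scoring ->
# predominance-based sparse cluster labelling -> decision-tree classifier
# with a posterior "unknown" threshold -> five-fold cross-validation.
# The same machinery is re-run on the T-cell subset (different DBSCAN Eps)
# to resolve T subtypes.

#' t-SNE embedding of single cells
#'
#' Barnes-Hut t-SNE of the cells (columns) of a log2 expression matrix, with
#' PCA pre-reduction. Deterministic for a given seed.
#'
#' @param m genes x cells matrix on LOG2 scale.
#' @param pca_dims number of principal components retained before t-SNE.
#' @param perplexity t-SNE perplexity; requires at least `3 * perplexity + 2`
#'   cells.
#' @param seed RNG seed.
#' @return cells x 2 coordinate matrix.
#' @export
embed_tsne <- function(m, pca_dims = 50, perplexity = 30, seed = 1L) {
  check_matrix(m)
  n <- ncol(m)
  if (n < 3 * perplexity + 2)
    stopf(paste("too few cells (%d) for perplexity %d;",
                "use perplexity <= %d"), n, perplexity, floor((n - 2) / 3))
  x <- t(m)
  emb <- with_seed(seed, Rtsne::Rtsne(
    x, dims = 2, perplexity = perplexity,
    initial_dims = min(pca_dims, n - 1, nrow(m)),
    pca = TRUE, check_duplicates = FALSE, verbose = FALSE))$Y
  rownames(emb) <- colnames(m)
  colnames(emb) <- c("tsne1", "tsne2")
  emb
}

#' DBSCAN density clustering
#'
#' Euclidean DBSCAN on an embedding. A point is a core point when its
#' eps-neighbourhood (including itself) holds at least `min_pts` points;
#' clusters are the connected components of core points plus their border
#' points; the rest is noise (`-1`). Cluster ids are contiguous, starting
#' at 1.
#'
#' @param embedding points x d coordinate matrix (finite values).
#' @param min_pts minimum neighbourhood size of a core point.
#' @param eps neighbourhood radius.
#' @return Object of class `cluster_assignment`: list with `cluster`
#'   (integer per point, `-1` = noise) and `embedding`.
#' @export
cluster_dbscan <- function(embedding, min_pts = 25, eps = 1.5) {
  embedding <- as.matrix(embedding)
  if (!all(is.finite(embedding))) stopf("embedding must be finite")
  n <- nrow(embedding)
  cl <- rep(-1L, n)
  if (n > 0) {
    d <- as.matrix(stats::dist(embedding))
    nbs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
    core <- lengths(nbs) >= min_pts
    cid <- 0L
    for (i in seq_len(n)) {
      if (!core[i] || cl[i] != -1L) next
      cid <- cid + 1L
      queue <- i
      cl[i] <- cid
      while (length(queue)) {
        j <- queue[[1]]
        queue <- queue[-1]
        for (k in nbs[[j]]) {
          if (cl[k] == -1L) {
            cl[k] <- cid
            if (core[k]) queue <- c(queue, k)
          }
        }
      }
    }
  }
  structure(list(cluster = cl, embedding = embedding,
                 min_pts = min_pts, eps = eps),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  k <- max(0, x$cluster)
  cat(sprintf("DBSCAN: %d clusters, %d/%d noise (MinPts=%g, Eps=%g)\n",
              k, sum(x$cluster == -1), length(x$cluster), x$min_pts, x$eps))
  invisible(x)
}

resolve_marker_spec <- function(spec, gene_ids) {
  out <- lapply(names(spec), function(tp) {
    sl <- spec[[tp]]
    sl <- lapply(sl[c("AND", "OR", "NOT")], function(g) {
      g <- if (is.null(g)) character() else g
      miss <- setdiff(g, gene_ids)
      if (length(miss))
        warnf("marker gene(s) absent and dropped for '%s': %s", tp,
              paste(miss, collapse = ", "))
      intersect(g, gene_ids)
    })
    if (length(sl$AND) == 0 && length(sl$OR) == 0)
      stopf("cell type '%s' has no resolvable AND or OR marker genes", tp)
    sl
  })
  names(out) <- names(spec)
  out
}

#' Marker-based cell-type scores
#'
#' Each marker gene is min-max normalized to \[0, 1\] across cells. For a
#' cell and a type the score is
#' `mean(AND) * 1[all AND raw > 0] + max(OR) - mean(NOT)`, floored at 0,
#' where the three terms use normalized values, an empty OR list contributes
#' 0 and an empty NOT list subtracts 0. AND genes are all required, one OR
#' gene suffices, NOT genes are a negative criterion. The score describes
#' how likely a cell is to belong to each type.
#'
#' @param m genes x cells LOG2 matrix.
#' @param spec marker specification: named list of `list(AND=, OR=, NOT=)`
#'   gene-id vectors (disjoint within a type). Genes absent from the matrix
#'   are dropped with a warning.
#' @return cells x types score matrix.
#' @export
score_markers <- function(m, spec) {
  check_matrix(m)
  spec <- resolve_marker_spec(spec, rownames(m))
  genes <- unique(unlist(spec, use.names = FALSE))
  norm <- t(apply(m[genes, , drop = FALSE], 1, function(x) {
    r <- max(x) - min(x)
    if (r == 0) rep(0, length(x)) else (x - min(x)) / r
  }))
  if (ncol(m) == 1) norm <- matrix(0, length(genes), 1,
                                   dimnames = list(genes, colnames(m)))
  scores <- matrix(0, ncol(m), length(spec),
                   dimnames = list(colnames(m), names(spec)))
  for (tp in names(spec)) {
    sl <- spec[[tp]]
    and_term <- if (length(sl$AND)) {
      gate <- apply(m[sl$AND, , drop = FALSE] > 0, 2, all)
      colMeans(norm[sl$AND, , drop = FALSE]) * gate
    } else 0
    or_term <- if (length(sl$OR))
      apply(norm[sl$OR, , drop = FALSE], 2, max) else 0
    not_term <- if (length(sl$NOT))
      colMeans(norm[sl$NOT, , drop = FALSE]) else 0
    scores[, tp] <- pmax(0, and_term + or_term - not_term)
  }
  scores
}

#' Predominance-based cluster labelling
#'
#' Sums the marker scores of each cluster's members per cell type. Types
#' whose total exceeds `predominance` times the cluster maximum "pass"; the
#' cluster is labelled only when exactly one type passes (an ambiguous
#' cluster - two closely related types both passing - stays unlabelled,
#' preventing misclassification). Noise cells are never labelled. The result
#' is a sparse training-label vector.
#'
#' @param scores cells x types score matrix.
#' @param clusters a [cluster_dbscan()] assignment over the same cells.
#' @param predominance fraction of the maximal total score required.
#' @return character vector of per-cell labels (`NA` = unlabelled).
#' @export
label_clusters <- function(scores, clusters, predominance = 0.75) {
  cl <- clusters$cluster
  if (length(cl) != nrow(scores))
    stopf("scores and clusters cover different cells")
  labels <- rep(NA_character_, length(cl))
  for (k in setdiff(unique(cl), -1L)) {
    idx <- which(cl == k)
    totals <- colSums(scores[idx, , drop = FALSE])
    smax <- max(totals)
    if (smax <= 0) next
    pass <- names(totals)[totals > predominance * smax]
    if (length(pass) == 1) labels[idx] <- pass
  }
  names(labels) <- rownames(scores)
  labels
}

# genes x cells -> data.frame of features (cells as rows) with syntactic
# names; mapping kept so prediction uses the same columns.
feature_frame <- function(m, genes) {
  miss <- setdiff(genes, rownames(m))
  if (length(miss))
    stopf("matrix lacks classifier gene(s): %s",
          paste(utils::head(miss, 5), collapse = ", "))
  x <- t(m[genes, , drop = FALSE])
  colnames(x) <- make.names(genes)
  as.data.frame(x)
}

#' Train the cell-type decision tree
#'
#' Fits a classification tree (Gini impurity, leaf class fractions as
#' posterior probabilities) on the sparsely labelled cells over a
#' classification gene set.
#'
#' @param m genes x cells LOG2 matrix (already filtered to the
#'   classification gene set, or supply `genes`).
#' @param labels per-cell labels (`NA` = unlabelled, excluded from training).
#' @param genes gene set used as features; default all rows of `m`.
#' @param posterior_threshold cells classified with a posterior below this
#'   are reported "unknown" by [classify_cells()].
#' @param seed seed (tree fitting is deterministic; the seed fixes any
#'   surrogate tie-breaking).
#' @return Object of class `cell_classifier`.
#' @export
train_classifier <- function(m, labels, genes = rownames(m),
                             posterior_threshold = 0.99, seed = 1L) {
  keep <- !is.na(labels)
  if (length(labels) != ncol(m))
    stopf("labels must match the matrix columns")
  classes <- sort(unique(labels[keep]))
  if (length(classes) < 2)
    stopf("training needs at least two labelled classes")
  df <- feature_frame(m[, keep, drop = FALSE], genes)
  df$.class <- factor(labels[keep], levels = classes)
  fit <- with_seed(seed, rpart::rpart(
    .class ~ ., data = df, method = "class",
    control = rpart::rpart.control(minsplit = 5, cp = 1e-4, xval = 0)))
  structure(list(tree = fit, classes = classes, genes = genes,
                 posterior_threshold = posterior_threshold),
            class = "cell_classifier")
}

#' @export
print.cell_classifier <- function(x, ...) {
  cat(sprintf("Decision-tree cell classifier: %d classes, %d genes, unknown below posterior %.2f\n",
              length(x$classes), length(x$genes), x$posterior_threshold))
  invisible(x)
}

#' Classify cells with a trained classifier
#'
#' Assigns each cell the class with maximal posterior probability; cells
#' whose maximal posterior falls below the classifier's threshold are marked
#' `"unknown"`.
#'
#' @param clf a [train_classifier()] result.
#' @param m genes x cells LOG2 matrix containing the classifier's gene set
#'   (row order is irrelevant).
#' @return data.frame with `cell_id`, `cell_type`, `posterior`.
#' @export
classify_cells <- function(clf, m) {
  if (ncol(m) == 0)
    return(data.frame(cell_id = character(), cell_type = character(),
                      posterior = numeric()))
  df <- feature_frame(m, clf$genes)
  post <- stats::predict(clf$tree, newdata = df, type = "prob")
  best <- max.col(post, ties.method = "first")
  pmax_ <- post[cbind(seq_len(nrow(post)), best)]
  lab <- colnames(post)[best]
  lab[pmax_ < clf$posterior_threshold] <- "unknown"
  data.frame(cell_id = colnames(m), cell_type = lab, posterior = pmax_,
             stringsAsFactors = FALSE)
}

#' Stratified k-fold cross-validation of the tree classifier
#'
#' @param m genes x cells LOG2 matrix.
#' @param labels per-cell labels; `NA` cells are excluded.
#' @param k number of folds; every class must have at least `k` members.
#' @param genes feature gene set; default all rows.
#' @param seed seed for the fold assignment.
#' @return Overall accuracy (pooled over folds) in \[0, 1\].
#' @export
cross_validate <- function(m, labels, k = 5, genes = rownames(m), seed = 1L) {
  keep <- which(!is.na(labels))
  y <- labels[keep]
  classes <- unique(y)
  if (length(classes) < 2) stopf("cross-validation needs at least two classes")
  sizes <- table(y)
  if (any(sizes < k))
    stopf("class(es) smaller than k = %d: %s", k,
          paste(names(sizes)[sizes < k], collapse = ", "))
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in classes) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- keep[folds != f]
      te <- keep[folds == f]
      df <- feature_frame(m[, tr, drop = FALSE], genes)
      df$.class <- factor(labels[tr])
      fit <- rpart::rpart(.class ~ ., data = df, method = "class",
                          control = rpart::rpart.control(minsplit = 5,
                                                         cp = 1e-4, xval = 0))
      pred <- stats::predict(fit,
                             newdata = feature_frame(m[, te, drop = FALSE],
                                                     genes),
                             type = "class")
      correct <- correct + sum(as.character(pred) == labels[te])
    }
    correct / length(y)
  })
}

# One full stage: embed -> cluster -> score -> label -> train -> classify.
classify_stage <- function(m, spec, genes, eps, min_pts, perplexity,
                           predominance, posterior_threshold, seed) {
  emb <- embed_tsne(m, perplexity = perplexity, seed = seed)
  clusters <- cluster_dbscan(emb, min_pts = min_pts, eps = eps)
  scores <- score_markers(m, spec)
  training <- label_clusters(scores, clusters, predominance = predominance)
  clf <- train_classifier(m, training, genes = genes,
                          posterior_threshold = posterior_threshold,
                          seed = seed)
  ann <- classify_cells(clf, m)
  list(annotation = ann, classifier = clf, clusters = clusters,
       scores = scores, training_labels = training, embedding = emb)
}

#' Two-stage cell-type classification
#'
#' Stage 1 classifies all cells into major types (T cells undivided). Stage 2
#' repeats the identical pipeline (embedding, DBSCAN with a larger Eps,
#' marker scoring, predominance labelling, tree training, posterior
#' thresholding) on the cells classified "T cell", resolving the T subtypes;
#' the final annotation replaces the "T cell" label by the subtype where one
#' was assigned. Non-T cells never receive a subtype label.
#'
#' @param m genes x cells LOG2 matrix (normalized).
#' @param spec_major marker spec for the major types (must contain
#'   `"T cell"` for stage 2 to run).
#' @param spec_tsub marker spec for the T subtypes.
#' @param genes classification gene set; default all rows of `m`.
#' @param eps_major,eps_tsub DBSCAN Eps for the two stages.
#' @param min_pts DBSCAN MinPts (both stages).
#' @param perplexity t-SNE perplexity; automatically capped for the smaller
#'   stage-2 population.
#' @param predominance cluster-labelling predominance fraction.
#' @param posterior_threshold "unknown" threshold (applied at both stages).
#' @param seed seed.
#' @return list with `annotation` (final labels), `stage1`, `stage2` (the
#'   per-stage results; `stage2` is `NULL` when no T cells were found).
#' @export
classify_two_stage <- function(m, spec_major, spec_tsub,
                               genes = rownames(m),
                               eps_major = 1.5, eps_tsub = 1.75,
                               min_pts = 25, perplexity = 30,
                               predominance = 0.75,
                               posterior_threshold = 0.99, seed = 1L) {
  s1 <- classify_stage(m, spec_major, genes, eps_major, min_pts,
                       perplexity, predominance, posterior_threshold, seed)
  ann <- s1$annotation
  tcells <- ann$cell_id[ann$cell_type == "T cell"]
  if (length(tcells) == 0) {
    warnf("no T cells found; subtype stage skipped")
    return(list(annotation = ann, stage1 = s1, stage2 = NULL))
  }
  mT <- m[, tcells, drop = FALSE]
  perp2 <- min(perplexity, floor((ncol(mT) - 2) / 3))
  s2 <- classify_stage(mT, spec_tsub, genes, eps_tsub, min_pts,
                       perp2, predominance, posterior_threshold, seed)
  sub <- stats::setNames(s2$annotation$cell_type, s2$annotation$cell_id)
  hit <- ann$cell_id %in% names(sub) & sub[ann$cell_id] != "unknown"
  ann$cell_type[hit] <- sub[ann$cell_id[hit]]
  list(annotation = ann, stage1 = s1, stage2 = s2)
}
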