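# Deconvolution of a bulk profile m against a signature matrix B:
# m ~ B w with cell-type weights w. Four solvers (nu-SVR, pseudo-inverse,
# least squares with intercept, L2-regularized NNLS) share one
# post-processing rule: negative weights are zeroed and the unknown fraction
# w_unknown = 1 - sum(w) absorbs mass not explained by the signature's
# cell types.

#' Standardize a signature system for SVR
#'
#' Centres and scales the signature matrix by its global (all-entries) mean
#' and standard deviation, and the bulk vector by its own mean and standard
#' deviation - the standardization convention of the reference SVR
#' deconvolution method. Both transforms are affine, so the fitted SVR
#' weights map back to the original absolute scale through the ratio of the
#' two standard deviations (returned as `rescale`); a weight vector that
#' sums to less than 1 then correctly leaves mass to the unknown fraction.
#' Gene-row standardization is deliberately avoided: centring every row
#' across types makes the standardized columns sum to zero per gene, which
#' leaves the weight level unidentifiable.
#'
#' A signature whose gene rows are all constant across types (identical
#' columns) carries no deconvolution information and is an error.
#'
#' @param B genes x types signature matrix.
#' @param m bulk vector on the same gene index.
#' @return list with standardized `B`, `m`, the gene ids, and the `rescale`
#'   factor mapping fitted weights back to the original scale.
#' @export
standardize_for_svr <- function(B, m) {
  if (all(apply(B, 1, stats::sd) == 0))
    stopf("degenerate signature: all gene rows have zero variance")
  b_sd <- stats::sd(as.vector(B))
  m_sd <- stats::sd(m)
  if (b_sd == 0) stopf("degenerate signature: constant matrix")
  if (m_sd == 0) stopf("constant bulk profile cannot be deconvolved")
  list(B = (B - mean(B)) / b_sd, m = (m - mean(m)) / m_sd,
       genes = rownames(B), rescale = m_sd / b_sd)
}

#' nu-support-vector regression solver
#'
#' Linear-kernel nu-SVR (nu = 0.5, cost 1) of the standardized bulk on the
#' standardized signature columns (see [standardize_for_svr()]); the primal
#' weight vector, mapped back to the original scale, is returned as raw
#' weights. The epsilon-insensitive loss with L2 regularization makes the
#' solver robust to noise and unknown mixture content.
#'
#' @param B,m signature matrix and bulk vector (same gene index).
#' @param nu nu parameter.
#' @return Raw (possibly negative) weight vector, one entry per type.
#' @export
deconvolve_nusvr <- function(B, m, nu = 0.5) {
  if (nrow(B) < ncol(B)) stopf("need at least as many genes as cell types")
  s <- standardize_for_svr(B, m)
  fit <- e1071::svm(x = s$B, y = s$m, scale = FALSE, type = "nu-regression",
                    kernel = "linear", nu = nu, cost = 1)
  w <- drop(t(fit$coefs) %*% fit$SV) * s$rescale
  stats::setNames(as.numeric(w), colnames(B))
}

#' Pseudo-inverse (minimum-norm least squares) solver
#'
#' `w = pinv(B) m`, the minimum-norm solution of the least-squares problem.
#'
#' @inheritParams deconvolve_nusvr
#' @return Raw weight vector.
#' @export
deconvolve_pinv <- function(B, m) {
  stats::setNames(as.numeric(MASS::ginv(B) %*% m), colnames(B))
}

#' Least squares with intercept
#'
#' Ordinary least squares of the bulk on the signature columns plus an
#' intercept; the intercept is reported as an attribute and excluded from
#' the weights.
#'
#' @inheritParams deconvolve_nusvr
#' @return Raw weight vector with attribute `intercept`.
#' @export
deconvolve_lm_intercept <- function(B, m) {
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, B), m)
  co <- fit$coefficients
  co[is.na(co)] <- 0
  w <- stats::setNames(as.numeric(co[-1]), colnames(B))
  attr(w, "intercept") <- unname(co[1])
  w
}

#' L2-regularized non-negative least squares solver
#'
#' Minimizes `||B w - m||^2 + lambda ||w||^2` subject to `w >= 0`, solved
#' exactly as ordinary NNLS (Lawson-Hanson) on the augmented system
#' `[B; sqrt(lambda) I]`.
#'
#' @inheritParams deconvolve_nusvr
#' @param lambda ridge penalty (default 1).
#' @return Raw (non-negative) weight vector.
#' @export
deconvolve_reg_nnls <- function(B, m, lambda = 1) {
  k <- ncol(B)
  A <- rbind(B, sqrt(lambda) * diag(k))
  b <- c(m, numeric(k))
  w <- pracma::lsqnonneg(A, b)$x
  stats::setNames(as.numeric(w), colnames(B))
}

#' Post-process raw deconvolution weights
#'
#' Negative weights are replaced by zero. If the clipped weights sum to more
#' than 1 they are renormalized to sum 1 (unknown fraction 0); otherwise the
#' unknown fraction is `1 - sum(w)`, the mass attributable to cell types
#' absent from the signature. The invariant `sum(w) + w_unknown = 1` always
#' holds.
#'
#' @param raw_w finite raw weight vector.
#' @param solver solver label recorded in the estimate.
#' @return Object of class `composition_estimate`.
#' @export
postprocess_weights <- function(raw_w, solver = "unknown") {
  if (any(!is.finite(raw_w))) stopf("raw weights must be finite")
  w <- pmax(as.numeric(raw_w), 0)
  names(w) <- names(raw_w)
  s <- sum(w)
  if (s > 1) {
    w <- w / s
    wu <- 0
  } else wu <- 1 - s
  structure(list(w = w, w_unknown = wu, raw_w = raw_w, solver = solver),
            class = "composition_estimate")
}

#' Deconvolve a bulk profile against a signature matrix
#'
#' The central estimator: restricts bulk and signature to their common genes
#' (optionally intersected with a signature gene set), solves `m ~ B w` with
#' the chosen solver, and post-processes the weights into a composition
#' estimate with an unknown fraction. Inputs are expected on a common linear
#' TPM-consistent scale (see the vignette for the scale discussion; pass
#' log-scale inputs deliberately if desired - the formula is scale-agnostic).
#'
#' @param bulk named bulk gene vector.
#' @param B genes x types signature matrix, e.g. from [build_rgep()].
#' @param gene_set optional signature gene set to restrict the system to.
#' @param solver `"nusvr"`, `"pinv"`, `"lm"` or `"regnnls"`.
#' @param nu,lambda solver parameters.
#' @return Object of class `composition_estimate`: weights `w` per type,
#'   unknown fraction `w_unknown`, raw solver output `raw_w`, the solver,
#'   the number of genes used, and the fitted system (for
#'   [fitted.composition_estimate()] / [residuals.composition_estimate()]).
#' @examples
#' B <- matrix(c(1, 0, 1, 0, 1, 1), 3, 2,
#'             dimnames = list(c("g1", "g2", "g3"), c("A", "B")))
#' m <- c(g1 = 0.3, g2 = 0.7, g3 = 1.0)
#' coef(deconvolve(m, B, solver = "pinv"))
#' @export
deconvolve <- function(bulk, B, gene_set = NULL,
                       solver = c("nusvr", "pinv", "lm", "regnnls"),
                       nu = 0.5, lambda = 1) {
  solver <- match.arg(solver)
  if (is.null(names(bulk)) || is.null(rownames(B)))
    stopf("bulk and signature must carry gene ids")
  genes <- intersect(names(bulk), rownames(B))
  if (!is.null(gene_set)) genes <- intersect(genes, gene_set)
  if (length(genes) == 0)
    stopf("empty gene intersection between bulk, signature and gene set")
  Bg <- B[genes, , drop = FALSE]
  mg <- bulk[genes]
  raw <- switch(solver,
                nusvr = deconvolve_nusvr(Bg, mg, nu = nu),
                pinv = deconvolve_pinv(Bg, mg),
                lm = deconvolve_lm_intercept(Bg, mg),
                regnnls = deconvolve_reg_nnls(Bg, mg, lambda = lambda))
  est <- postprocess_weights(raw, solver = solver)
  est$n_genes <- length(genes)
  est$B <- Bg
  est$m <- mg
  est$intercept <- attr(raw, "intercept")
  est
}

#' @export
print.composition_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("Composition estimate (%s, %d genes)\n", x$solver, x$n_genes))
  print(round(c(x$w, unknown = x$w_unknown), digits))
  invisible(x)
}

#' @export
coef.composition_estimate <- function(object, ...) {
  c(object$w, unknown = object$w_unknown)
}

#' @export
summary.composition_estimate <- function(object, ...) {
  out <- data.frame(cell_type = c(names(object$w), "unknown"),
                    fraction = c(object$w, object$w_unknown),
                    raw_weight = c(as.numeric(object$raw_w), NA),
                    row.names = NULL)
  attr(out, "solver") <- object$solver
  out
}

#' Fitted bulk profile of a composition estimate
#' @param object a `composition_estimate` from [deconvolve()].
#' @param ... unused.
#' @export
fitted.composition_estimate <- function(object, ...) {
  drop(object$B %*% object$w) +
    if (is.null(object$intercept)) 0 else object$intercept
}

#' @export
residuals.composition_estimate <- function(object, ...) {
  object$m - fitted(object)
}
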