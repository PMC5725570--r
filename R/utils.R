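# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions do not
#' disturb the caller's random number stream.
#'
#' @param seed integer seed, or `NULL` to leave the stream untouched.
#' @param expr expression to evaluate.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Dirichlet draw via normalized gammas; alpha entries equal to zero yield
# structural zeros (types absent from a tissue source).
rdirichlet1 <- function(alpha) {
  x <- numeric(length(alpha))
  pos <- alpha > 0
  g <- stats::rgamma(sum(pos), shape = alpha[pos], rate = 1)
  # guard against all-zero draws at tiny alphas
  if (sum(g) <= 0) g[which.max(alpha[pos])] <- 1
  x[pos] <- g / sum(g)
  names(x) <- names(alpha)
  x
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Expression-scale attribute
#'
#' Expression matrices carry a `"scale"` attribute, either `"TPM"` (linear
#' transcripts-per-million) or `"LOG2"` (log2(TPM + 1), possibly
#' housekeeping-normalized). [expr_scale()] reads it; the replacement form
#' sets it.
#'
#' @param m numeric matrix (genes x columns).
#' @param default value returned when the attribute is unset.
#' @return The scale string.
#' @export
expr_scale <- function(m, default = "TPM") {
  s <- attr(m, "scale")
  if (is.null(s)) default else s
}

#' @rdname expr_scale
#' @param value `"TPM"` or `"LOG2"`.
#' @export
`expr_scale<-` <- function(m, value) {
  value <- match.arg(value, c("TPM", "LOG2"))
  attr(m, "scale") <- value
  m
}

#' Rescale columns to TPM (sum 1e6)
#'
#' @param m non-negative matrix on a linear scale.
#' @return Matrix whose non-empty columns each sum to 1e6, scale `"TPM"`.
#' @export
rescale_tpm <- function(m) {
  cs <- colSums(m)
  nz <- cs > 0
  m[, nz] <- sweep(m[, nz, drop = FALSE], 2, cs[nz] / 1e6, "/")
  expr_scale(m) <- "TPM"
  m
}

check_matrix <- function(m, what = "expression matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    stopf("%s must be a numeric matrix", what)
  if (is.null(rownames(m)))
    stopf("%s must have gene ids as rownames", what)
  if (anyDuplicated(rownames(m)))
    stopf("%s has duplicated gene ids", what)
  invisible(m)
}
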