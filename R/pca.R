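#' Scatter-matrix principal component analysis
#'
#' Fits the orthonormal projection that diagonalizes the scatter matrix
#' \eqn{F_v = \sum_i (x_i - \mu)^T (x_i - \mu)} of the mean-centered
#' training rows: the columns of `components` are the top-K unit-norm
#' eigenvectors of \eqn{F_v} (the directions maximizing
#' \eqn{M_k^T F_v M_k} under \eqn{M_k^T M_k = 1}), `eigenvalues` the
#' matching scatter eigenvalues in non-increasing order. With far fewer
#' rows than columns the decomposition is computed via a thin SVD of the
#' centered data, which has the same eigenstructure as the explicit
#' F x F scatter. Each component's sign is fixed so that its
#' largest-magnitude entry is positive, making results reproducible.
#'
#' Fit the projection on the *training* partition only and transform both
#' partitions; fitting on all rows leaks test information into the
#' reduction.
#'
#' @param x N x F numeric training matrix (N >= 2).
#' @param n_components K, number of components
#'   (`K <= min(N - 1, F)`).
#' @return An object of class `"scatter_pca"`: `mean` (length F),
#'   `components` (F x K), `eigenvalues` (length K), `n_fit`,
#'   `total_scatter` (trace of the full scatter matrix).
#' @examples
#' x <- matrix(rnorm(60), 20, 3)
#' p <- fit_pca(x, 2)
#' crossprod(p$components)  # ~ identity
#' @export
fit_pca <- function(x, n_components) {
  x <- as.matrix(x)
  n <- nrow(x); f <- ncol(x)
  if (n < 2L) stopf("need at least 2 rows to fit a PCA")
  k <- as.integer(n_components)
  if (k < 1L || k > min(n - 1L, f))
    stopf("'n_components' must be in 1..min(N-1, F) = %d", min(n - 1L, f))
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  total <- sum(xc^2)
  if (total <= 1e-12) stopf("zero-variance input: scatter matrix is null")
  sv <- La.svd(xc, nu = 0, nv = min(n, f))
  comp <- t(sv$vt[seq_len(k), , drop = FALSE])
  # deterministic sign: largest-magnitude entry of each component positive
  for (j in seq_len(k)) {
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) comp[, j] <- -comp[, j]
  }
  structure(
    list(mean = mu, components = comp, eigenvalues = sv$d[seq_len(k)]^2,
         n_fit = n, total_scatter = total),
    class = "scatter_pca")
}

#' @export
print.scatter_pca <- function(x, ...) {
  cat(sprintf("<scatter_pca> %d components in %d dims (fit on %d rows); scatter captured %.1f%%\n",
              ncol(x$components), nrow(x$components), x$n_fit,
              100 * sum(x$eigenvalues) / x$total_scatter))
  invisible(x)
}

#' Project feature rows onto fitted principal components
#'
#' Computes \eqn{y_i = M^T (x_i - \mu)} for every row.
#'
#' @param proj A [scatter_pca][fit_pca] projection.
#' @param x Matrix (or single vector) with F columns.
#' @return N x K matrix of reduced coordinates.
#' @export
pca_transform <- function(proj, x) {
  stopifnot(inherits(proj, "scatter_pca"))
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(proj$mean))
    stopf("input has %d columns but the projection expects %d",
          ncol(x), length(proj$mean))
  sweep(as.matrix(x), 2L, proj$mean) %*% proj$components
}

#' @param object A `"scatter_pca"` projection.
#' @param newdata Matrix with F columns.
#' @param ... Ignored.
#' @rdname pca_transform
#' @export
predict.scatter_pca <- function(object, newdata, ...)
  pca_transform(object, newdata)
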