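#' Ridge-regularized partial-correlation netmat
#'
#' Estimates a partial-correlation network matrix from a subject's node time
#' series with L2 regularization. Columns are demeaned, the covariance is
#' normalized by its mean diagonal so the ridge penalty is scale-free, then
#' `rho * I` is added before inversion. Partial correlations are derived
#' from the precision matrix (`r_ij = -P_ij / sqrt(P_ii P_jj)`) and mapped
#' to z-scores with Fisher's transformation; the diagonal is zeroed.
#'
#' @param ts `T x N` matrix of node time series (no missing values).
#' @param rho ridge penalty (default 0.01).
#' @return `N x N` symmetric matrix of Fisher-z partial correlations with
#'   zero diagonal; attribute `kind = "partial_ridge"`.
#' @examples
#' ts <- matrix(rnorm(300), 100, 3)
#' z <- partial_netmat_ridge(ts)
#' @export
partial_netmat_ridge <- function(ts, rho = 0.01) {
  ts <- as.matrix(ts)
  if (rho < 0) stop("`rho` must be non-negative", call. = FALSE)
  if (nrow(ts) <= ncol(ts)) {
    warning("fewer time points than nodes; estimates will be poorly conditioned")
  }
  X <- demean_cols(ts)
  C <- crossprod(X) / (nrow(X) - 1)
  C <- C / mean(diag(C))
  Creg <- C + diag(rho, ncol(C))
  P <- tryCatch(chol2inv(chol(Creg)), error = function(e) {
    stop("regularized covariance is singular; use rho > 0", call. = FALSE)
  })
  r <- precision_to_partial(P)
  z <- atanh(cap_correlations(r))
  z <- (z + t(z)) / 2
  diag(z) <- 0
  structure(z, kind = "partial_ridge", rho = rho)
}

#' Full-correlation netmat
#'
#' Fisher-z of the Pearson correlation matrix of the node time series, with
#' zero diagonal. Correlations of magnitude 1 (e.g. duplicated nodes) are
#' capped at `1 - 1e-15` before the transform, with a warning.
#'
#' @param ts `T x N` matrix of node time series.
#' @return `N x N` symmetric Fisher-z matrix, zero diagonal; attribute
#'   `kind = "full"`.
#' @export
full_netmat <- function(ts) {
  ts <- as.matrix(ts)
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    stop(sprintf("constant node time series at node(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  r <- stats::cor(ts)
  diag(r) <- 0
  if (any(abs(r) >= 1)) {
    warning("correlations of magnitude 1 capped before Fisher transform")
  }
  z <- atanh(cap_correlations(r))
  diag(z) <- 0
  structure(z, kind = "full")
}

cap_correlations <- function(r, cap = 1 - 1e-15) {
  pmin(pmax(r, -cap), cap)
}

#' Half-vectorize a symmetric matrix
#'
#' Extracts the strict upper triangle (`i < j`) in row-major order, the
#' fixed edge order used throughout the package: `(1,2), (1,3), ...,
#' (1,N), (2,3), ...`. For `N` nodes the result has `N(N-1)/2` elements
#' (19 900 for `N = 200`).
#'
#' @param m symmetric `N x N` matrix.
#' @param tol asymmetry tolerance.
#' @return numeric edge vector of length `N(N-1)/2`.
#' @seealso [unhalfvec()], [edge_index()]
#' @export
halfvec <- function(m, tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > tol) {
    stop("`m` must be a symmetric square matrix", call. = FALSE)
  }
  t(m)[lower.tri(m)]
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [halfvec()]: places the edge vector into the upper and lower
#' triangles (row-major `i < j` order) with a zero diagonal.
#'
#' @param v edge vector of length `N(N-1)/2`.
#' @param n number of nodes `N`.
#' @return symmetric `n x n` matrix with zero diagonal.
#' @export
unhalfvec <- function(v, n) {
  if (length(v) != n * (n - 1) / 2) {
    stop("edge vector length does not match n(n-1)/2", call. = FALSE)
  }
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m <- t(m)
  m[lower.tri(m)] <- v
  m
}

#' Edge index map
#'
#' Node-pair labels for the package's fixed edge order (upper triangle,
#' `i < j`, row-major, 1-based indices).
#'
#' @param n number of nodes.
#' @return tibble with `edge_id`, `node_i`, `node_j`.
#' @export
edge_index <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ord <- order(pairs[, "row"], pairs[, "col"])
  tibble::tibble(edge_id = seq_len(nrow(pairs)),
                 node_i = pairs[ord, "row"],
                 node_j = pairs[ord, "col"])
}

#' Assemble the subjects-by-edges matrix
#'
#' Half-vectorizes each subject's netmat and stacks the edge vectors into a
#' `subjects x E` matrix (row order = subject order).
#'
#' @param netmats named list of `N x N` symmetric netmats.
#' @return list with `values` (`subjects x E` matrix, rownames = subject
#'   ids) and `edge_index` (see [edge_index()]).
#' @export
assemble_edges <- function(netmats) {
  ns <- vapply(netmats, nrow, integer(1))
  if (length(unique(ns)) != 1L) stop("netmats have inconsistent dimensions", call. = FALSE)
  n <- ns[[1]]
  values <- do.call(rbind, lapply(netmats, halfvec))
  rownames(values) <- names(netmats)
  list(values = values, edge_index = edge_index(n))
}

#' Group-average netmat
#'
#' Element-wise mean of the subjects' Fisher-z netmats.
#'
#' @param netmats list of `N x N` matrices with identical dimensions.
#' @return `N x N` matrix.
#' @export
group_average <- function(netmats) {
  ns <- vapply(netmats, nrow, integer(1))
  if (length(unique(ns)) != 1L) stop("netmats have inconsistent dimensions", call. = FALSE)
  Reduce(`+`, netmats) / length(netmats)
}
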