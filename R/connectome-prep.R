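#' Prepare connectome edge features (N0 through N3)
#'
#' From the raw subjects-by-edges matrix `N0`, two feature blocks are built
#' and horizontally concatenated. `N1` is `N0` column-demeaned and globally
#' variance-normalized (one scale factor for the whole block). `N2` divides
#' each column of `N0` by the absolute value of its mean, drops columns
#' whose absolute mean is below `low_mean_threshold`, then column-demeans
#' and globally variance-normalizes the block. `N3 = [N1 | N2]`. Dropped
#' column ids are ledgered. The absolute mean is used because
#' partial-correlation z edges can be negative and division by near-zero
#' signed means is unstable.
#'
#' @param n0 `subjects x E` edge matrix (or the list returned by
#'   [assemble_edges()]).
#' @param low_mean_threshold drop threshold on `|column mean|`
#'   (default 0.1).
#' @return an object of class `prepared_connectome` (through `N3`): list
#'   with `N0`, `N1`, `N2`, `N3`, `dropped` (tibble: `edge_id`,
#'   `column_mean`).
#' @export
prepare_edge_features <- function(n0, low_mean_threshold = 0.1) {
  if (is.list(n0) && !is.matrix(n0)) n0 <- n0$values
  n0 <- as.matrix(n0)
  if (ncol(n0) < 1L) stop("edge matrix must have at least one column", call. = FALSE)
  mu <- colMeans(n0)

  N1 <- demean_cols(n0)
  N1 <- N1 / global_sd(N1)

  keep <- abs(mu) >= low_mean_threshold
  if (!any(keep)) {
    stop("all edge columns dropped by the low-mean rule; lower `low_mean_threshold`",
         call. = FALSE)
  }
  N2 <- sweep(n0[, keep, drop = FALSE], 2, abs(mu[keep]), "/")
  N2 <- demean_cols(N2)
  N2 <- N2 / global_sd(N2)

  dropped <- tibble::tibble(edge_id = which(!keep), column_mean = mu[!keep])
  structure(list(N0 = n0, N1 = N1, N2 = N2, N3 = cbind(N1, N2),
                 dropped = dropped),
            class = "prepared_connectome")
}

#' PCA scores by truncated SVD
#'
#' `N5` is the first `d` columns of `U %*% Sigma` from the singular value
#' decomposition of the (deconfounded) feature matrix; equivalently the
#' top-`d` principal component scores. Each component's sign is fixed so
#' that the largest-magnitude element of its feature-space singular vector
#' is positive, making scores reproducible across subject subsets.
#'
#' @param x numeric matrix (subjects x features), no missing values.
#' @param d number of components.
#' @return `subjects x d` score matrix, columns ordered by decreasing
#'   singular value.
#' @export
pca_scores_svd <- function(x, d = 70) {
  x <- as.matrix(x)
  if (d > min(dim(x))) stop("`d` exceeds min(subjects, features)", call. = FALSE)
  sv <- svd(x, nu = d, nv = d)
  scores <- sv$u %*% diag(sv$d[seq_len(d)], d)
  for (k in seq_len(d)) {
    j <- which.max(abs(sv$v[, k]))
    if (sv$v[j, k] < 0) scores[, k] <- -scores[, k]
  }
  rownames(scores) <- rownames(x)
  scores
}

#' Prepare the connectome view for CCA
#'
#' Runs the staged connectome pipeline: `N0` (subjects-by-edges) ->
#' `N1`/`N2`/`N3` (see [prepare_edge_features()]) -> `N4` (confounds
#' regressed out) -> `N5` (top-`d` SVD scores).
#'
#' @param n0 `subjects x E` edge matrix or the list from [assemble_edges()].
#' @param confounds confound regressor matrix from [build_confounds()].
#' @param d number of components (default 70; desk scale typically 30).
#' @param low_mean_threshold see [prepare_edge_features()].
#' @return an object of class `prepared_connectome`: list with `N0`..`N5`
#'   and the dropped-column ledger.
#' @export
prepare_connectome <- function(n0, confounds, d = 70, low_mean_threshold = 0.1) {
  pc <- prepare_edge_features(n0, low_mean_threshold = low_mean_threshold)
  pc$N4 <- deconfound(pc$N3, confounds)
  if (d > min(dim(pc$N4))) d <- min(dim(pc$N4))
  pc$N5 <- pca_scores_svd(pc$N4, d = d)
  pc
}
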