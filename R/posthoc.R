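#' Positive-negative axis of subject measures
#'
#' Correlates every (deconfounded) SM column — those used in the CCA and
#' any held-out SMs — with the primary-mode SM variate `V1`, and computes
#' the percentage of variance of each SM explained by the mode via the
#' projection formula `100 * var(V1 %*% pinv(V1) %*% s) / var(s)` (with
#' `V1` and `s` demeaned over observed rows), which equals `100 * r^2`
#' algebraically. Per-SM z-scores come from a family-restricted permutation
#' null of the correlation by default, or from the Fisher transformation.
#'
#' @param s8 subjects x SMs matrix of deconfounded SMs (`NA` allowed);
#'   column names label the axis.
#' @param v1 primary-mode SM variate (length = subjects).
#' @param included optional logical vector (per SM) marking SMs that
#'   entered the CCA (others are held out); defaults to all `TRUE`.
#' @param blocks optional [build_blocks()] result for permutation z-scores.
#' @param P permutations for the z-score null (default 1000).
#' @param z_method `"permutation"` (default, requires `blocks`) or
#'   `"fisher"`.
#' @return a tibble of class `pn_axis`: `sm_name`, `r`, `pct_variance`,
#'   `z`, `included_in_cca`, ordered by `r`.
#' @export
positive_negative_axis <- function(s8, v1, included = NULL, blocks = NULL,
                                   P = 1000, z_method = c("permutation", "fisher")) {
  z_method <- match.arg(z_method)
  s8 <- as.matrix(s8)
  v1 <- as.numeric(v1)
  v1 <- v1 - mean(v1)
  nm <- colnames(s8) %||% sprintf("sm_%03d", seq_len(ncol(s8)))
  included <- included %||% rep(TRUE, ncol(s8))

  sds <- apply(s8, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE)) {
    warning(sprintf("%d zero-variance SM(s) excluded from the axis", sum(sds == 0)))
    keep <- !(sds == 0 | is.na(sds))
    s8 <- s8[, keep, drop = FALSE]
    nm <- nm[keep]
    included <- included[keep]
  }

  r <- cor_vec_cols(v1, s8)
  pct <- vapply(seq_len(ncol(s8)), function(j) {
    x <- s8[, j]
    ok <- !is.na(x)
    xo <- x[ok] - mean(x[ok])
    vo <- v1[ok] - mean(v1[ok])
    V1 <- matrix(vo, ncol = 1)
    proj <- V1 %*% MASS::ginv(V1) %*% matrix(xo, ncol = 1)
    100 * stats::var(as.vector(proj)) / stats::var(xo)
  }, numeric(1))

  z <- rep(NA_real_, ncol(s8))
  if (z_method == "permutation") {
    if (is.null(blocks)) stop("permutation z-scores require `blocks`", call. = FALSE)
    null_r <- matrix(NA_real_, P, ncol(s8))
    for (b in seq_len(P)) {
      p <- sample_permutation(blocks)
      null_r[b, ] <- cor_vec_cols(v1[p], s8)
    }
    mu <- colMeans(null_r, na.rm = TRUE)
    sdv <- apply(null_r, 2, stats::sd, na.rm = TRUE)
    z <- (r - mu) / sdv
  } else {
    m_obs <- colSums(!is.na(s8))
    z <- atanh(cap_correlations(r)) * sqrt(pmax(m_obs - 3, 1))
  }

  out <- tibble::tibble(sm_name = nm, r = r, pct_variance = pct, z = z,
                        included_in_cca = included)
  out <- dplyr::arrange(out, dplyr::desc(.data$r))
  class(out) <- c("pn_axis", class(out))
  out
}

#' Edge weights of the primary mode
#'
#' Correlates the primary-mode connectome variate `U1` with every column of
#' the raw subjects-by-edges matrix `N0`, giving the full-length edge
#' weight vector that maps the mode back onto the original connectome.
#'
#' @param u1 primary-mode connectome variate (length = subjects).
#' @param n0 subjects x E edge matrix.
#' @return numeric vector of length E (per-edge Pearson correlations).
#' @export
edge_weights <- function(u1, n0) {
  n0 <- if (is.list(n0) && !is.matrix(n0)) n0$values else as.matrix(n0)
  cor_vec_cols_complete(as.numeric(u1), n0)
}

#' Correlate edge weights with the population-mean connectome
#'
#' @param a_f1 edge weight vector from [edge_weights()].
#' @param mean_netmat group-average netmat (matrix, half-vectorized
#'   internally) or an already half-vectorized edge vector.
#' @return Pearson correlation (scalar).
#' @export
correlate_with_mean <- function(a_f1, mean_netmat) {
  v <- if (is.matrix(mean_netmat)) halfvec(mean_netmat) else as.numeric(mean_netmat)
  stats::cor(a_f1, v)
}

#' Top edges by absolute weight
#'
#' The `k` edges most strongly related to the primary mode, sorted by
#' decreasing `|weight|` with deterministic ties broken by edge id, each
#' annotated with its node pair and sign.
#'
#' @param a_f1 edge weight vector.
#' @param edge_idx edge index map from [edge_index()].
#' @param k number of edges to keep (default 30).
#' @return tibble: `rank`, `edge_id`, `node_i`, `node_j`, `weight`, `sign`.
#' @export
top_edges <- function(a_f1, edge_idx, k = 30) {
  if (k > length(a_f1)) stop("`k` exceeds the number of edges", call. = FALSE)
  ord <- order(-abs(a_f1), seq_along(a_f1))
  sel <- ord[seq_len(k)]
  tibble::tibble(rank = seq_len(k),
                 edge_id = sel,
                 node_i = edge_idx$node_i[sel],
                 node_j = edge_idx$node_j[sel],
                 weight = a_f1[sel],
                 sign = ifelse(a_f1[sel] >= 0, "positive", "negative"))
}

#' Ward clustering of the group connectome
#'
#' Agglomerative Ward clustering (`ward.D2`) on Euclidean distances
#' between the rows of the group-averaged full-correlation netmat, cut at
#' `k` clusters; the dendrogram leaf order gives a deterministic display
#' order.
#'
#' @param netmat symmetric `N x N` group netmat.
#' @param k number of clusters (default 4).
#' @return list with `labels` (tibble: `node`, `cluster`, `leaf_position`)
#'   and the `hclust` object.
#' @export
ward_clusters <- function(netmat, k = 4) {
  netmat <- as.matrix(netmat)
  if (k > nrow(netmat)) stop("`k` exceeds the number of nodes", call. = FALSE)
  hc <- stats::hclust(stats::dist(netmat), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  leaf_pos <- match(seq_len(nrow(netmat)), hc$order)
  list(labels = tibble::tibble(node = seq_len(nrow(netmat)),
                               cluster = unname(cl),
                               leaf_position = leaf_pos),
       hclust = hc)
}
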