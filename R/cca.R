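#' Fit a canonical correlation analysis
#'
#' Estimates demixing matrices `A` (connectome side) and `B` (SM side) such
#' that the canonical variates `U = N5 %*% A` and `V = S5 %*% B` are
#' maximally correlated column-pair by column-pair, with each variate
#' matrix column-centred, unit-variance and mutually uncorrelated. The fit
#' uses the QR decomposition of the centred inputs followed by an SVD of
#' the cross-product of their orthonormal bases. Rank-deficient inputs
#' reduce the number of modes with a warning. The sign of each mode is
#' fixed so that the largest-magnitude correlation between `V_k` and the
#' columns of the SM-side input is positive, making the axes reproducible.
#'
#' @param n5 connectome-side score matrix (subjects x d1).
#' @param s5 SM-side score matrix (subjects x d2).
#' @return an object of class `cca_fit`: list with `A`, `B`, `U`, `V`,
#'   canonical correlations `r` (non-increasing, in `[0, 1]`), `d` and `n`.
#' @examples
#' X <- matrix(rnorm(150), 50, 3); Y <- X + matrix(rnorm(150), 50, 3)
#' fit <- fit_cca(X, Y)
#' fit$r
#' @export
fit_cca <- function(n5, s5) {
  X <- as.matrix(n5)
  Y <- as.matrix(s5)
  if (nrow(X) != nrow(Y)) stop("views must have the same subject count", call. = FALSE)
  n <- nrow(X)
  if (n < 3L) stop("at least 3 subjects are required", call. = FALSE)
  X <- demean_cols(X)
  Y <- demean_cols(Y)
  qx <- qr(X)
  qy <- qr(Y)
  rx <- qx$rank
  ry <- qy$rank
  if (rx == 0L || ry == 0L) stop("an input matrix has rank zero after centering", call. = FALSE)
  if (rx < ncol(X) || ry < ncol(Y)) {
    warning(sprintf("rank-deficient input; modes reduced to %d", min(rx, ry)))
  }
  d <- min(rx, ry)
  Qx <- qr.Q(qx)[, seq_len(rx), drop = FALSE]
  Qy <- qr.Q(qy)[, seq_len(ry), drop = FALSE]
  sv <- svd(crossprod(Qx, Qy), nu = d, nv = d)
  r <- pmin(pmax(sv$d[seq_len(d)], 0), 1)

  A <- matrix(0, ncol(X), d)
  A[qx$pivot[seq_len(rx)], ] <-
    backsolve(qr.R(qx)[seq_len(rx), seq_len(rx), drop = FALSE], sv$u) * sqrt(n - 1)
  B <- matrix(0, ncol(Y), d)
  B[qy$pivot[seq_len(ry)], ] <-
    backsolve(qr.R(qy)[seq_len(ry), seq_len(ry), drop = FALSE], sv$v) * sqrt(n - 1)
  U <- X %*% A
  V <- Y %*% B

  # deterministic sign: strongest SM-side loading positive per mode
  loadings <- suppressWarnings(stats::cor(V, Y))
  for (k in seq_len(d)) {
    lk <- loadings[k, ]
    lk[is.na(lk)] <- 0
    s <- sign(lk[which.max(abs(lk))])
    if (is.na(s) || s == 0) s <- 1
    A[, k] <- s * A[, k]
    B[, k] <- s * B[, k]
    U[, k] <- s * U[, k]
    V[, k] <- s * V[, k]
  }
  rownames(U) <- rownames(X)
  rownames(V) <- rownames(Y)
  structure(list(A = A, B = B, U = U, V = V, r = r, d = d, n = n),
            class = "cca_fit")
}

#' @export
print.cca_fit <- function(x, ...) {
  cat("<cca_fit>", x$d, "modes on", x$n, "subjects; r_1 =",
      signif(x$r[1], 3), "\n")
  invisible(x)
}

#' Canonical correlations with optional permutation p-values
#'
#' Pearson correlations of the paired canonical variate columns (equal to
#' the canonical correlations by construction), with familywise-error
#' corrected p-values from a family-restricted permutation null when one is
#' supplied.
#'
#' @param fit a [fit_cca()] result.
#' @param null optional [permutation_null()] result.
#' @return tibble with `mode`, `r`, and (if `null` given) `p_fwe`.
#' @export
mode_weight_correlations <- function(fit, null = NULL) {
  out <- tibble::tibble(mode = seq_len(fit$d), r = fit$r)
  if (!is.null(null)) {
    out$p_fwe <- fwe_pvalues(fit$r, null$perm_r)
  }
  out
}

# max-statistic FWE p-values: compare each observed r to the null of the
# first (maximal) canonical correlation; (1 + b) / (1 + P) convention
fwe_pvalues <- function(r_obs, perm_r) {
  max_null <- if (is.matrix(perm_r)) perm_r[, 1] else perm_r
  vapply(r_obs, function(r) (1 + sum(max_null >= r)) / (1 + length(max_null)),
         numeric(1))
}

#' Variance of an original data matrix explained by mode weights
#'
#' For each mode `k`, the variance-weighted mean of squared correlations
#' between the subject weight vector and every column of the original
#' matrix: `ve_k = sum_j r^2(w_k, x_j) var(x_j) / sum_j var(x_j)`, using
#' pairwise-complete rows on columns with missing data. This equals the
#' fraction of total variance captured by a rank-1 regression of the matrix
#' on the weight vector.
#'
#' @param weights subjects x d matrix of canonical variates (columns are
#'   centred internally).
#' @param original subjects x M data matrix (`NA` allowed).
#' @return numeric vector of length d, fractions in `[0, 1]`.
#' @export
mode_variance_explained <- function(weights, original) {
  W <- demean_cols(as.matrix(weights))
  X <- as.matrix(original)
  v <- apply(X, 2, stats::var, na.rm = TRUE)
  bad <- !is.finite(v) | v == 0
  if (any(bad)) {
    warning(sprintf("%d zero-variance column(s) excluded from variance explained",
                    sum(bad)))
    X <- X[, !bad, drop = FALSE]
    v <- v[!bad]
  }
  R <- suppressWarnings(stats::cor(W, X, use = "pairwise.complete.obs"))
  R[!is.finite(R)] <- 0
  as.vector((R^2 %*% v) / sum(v))
}

#' Variance-explained profile of a CCA against permutation nulls
#'
#' Combines the observed canonical correlations, the per-mode variance
#' explained in the original connectome (`N0`) and SM (`S2`) matrices, and
#' the permutation null distributions into one per-mode table with
#' z-scores (`(observed - null mean) / null sd`), 5th/95th null
#' percentiles, and familywise-error p-values for the canonical
#' correlations.
#'
#' @param fit a [fit_cca()] result.
#' @param conn_ref original connectome matrix (`N0`).
#' @param sm_ref original SM matrix (`S2`, Gaussianized, pre-deconfounding).
#' @param null a [permutation_null()] result with variance-explained draws.
#' @param n_modes number of leading modes to report (default all).
#' @return a tibble of class `pn_variance_profile`.
#' @export
variance_profile <- function(fit, conn_ref, sm_ref, null, n_modes = NULL) {
  d_ve <- ncol(null$perm_ve_conn)
  n_modes <- min(n_modes %||% d_ve, d_ve, fit$d)
  idx <- seq_len(n_modes)
  ve_conn <- mode_variance_explained(fit$U[, idx, drop = FALSE], conn_ref)
  ve_sm <- mode_variance_explained(fit$V[, idx, drop = FALSE], sm_ref)
  zpb <- function(obs, draws) {
    mu <- colMeans(draws)
    sdv <- apply(draws, 2, stats::sd)
    list(z = (obs - mu) / sdv,
         p5 = apply(draws, 2, stats::quantile, 0.05, names = FALSE),
         p95 = apply(draws, 2, stats::quantile, 0.95, names = FALSE))
  }
  zc <- zpb(ve_conn, null$perm_ve_conn[, idx, drop = FALSE])
  zs <- zpb(ve_sm, null$perm_ve_sm[, idx, drop = FALSE])
  out <- tibble::tibble(
    mode = idx,
    r = fit$r[idx],
    p_fwe = fwe_pvalues(fit$r[idx], null$perm_r),
    ve_conn = ve_conn, z_conn = zc$z, p5_conn = zc$p5, p95_conn = zc$p95,
    ve_sm = ve_sm, z_sm = zs$z, p5_sm = zs$p5, p95_sm = zs$p95
  )
  class(out) <- c("pn_variance_profile", class(out))
  out
}

#' Evaluate the pre-registered replication criteria
#'
#' Given a variance profile, checks: (1) some mode explains a significant
#' amount of variance (above the 95th null percentile) in *both* the
#' connectome and SM matrices — that mode is the primary mode (ties broken
#' by the larger SM-side z); (2) the primary mode's z-scores exceed the
#' next-largest mode's z by at least `factors["conn"]` on the connectome
#' side and `factors["sm"]` on the SM side; (3) the primary mode's
#' familywise-error p-value is below `alpha`.
#'
#' @param vp a [variance_profile()] tibble.
#' @param factors named numeric vector with elements `conn` and `sm`.
#' @param alpha significance level for criterion 3 (default 0.001).
#' @return a list with `primary_mode` (or `NA` if no mode passes
#'   criterion 1), the per-criterion booleans, and the observed z-ratios.
#' @export
evaluate_replication_criteria <- function(vp, factors = c(conn = 2, sm = 3),
                                          alpha = 0.001) {
  sig_both <- vp$ve_conn > vp$p95_conn & vp$ve_sm > vp$p95_sm
  if (!any(sig_both)) {
    return(list(primary_mode = NA_integer_, criterion1 = FALSE,
                criterion2 = NA, criterion3 = NA,
                z_ratio_conn = NA_real_, z_ratio_sm = NA_real_,
                note = "no primary mode"))
  }
  cand <- which(sig_both)
  primary <- cand[which.max(vp$z_sm[cand])]
  ratio <- function(z) {
    others <- z[-primary]
    if (length(others) == 0 || max(others) <= 0) Inf else z[primary] / max(others)
  }
  z_ratio_conn <- ratio(vp$z_conn)
  z_ratio_sm <- ratio(vp$z_sm)
  list(
    primary_mode = vp$mode[primary],
    criterion1 = TRUE,
    criterion2 = z_ratio_conn >= factors[["conn"]] && z_ratio_sm >= factors[["sm"]],
    criterion3 = vp$p_fwe[primary] < alpha,
    z_ratio_conn = z_ratio_conn,
    z_ratio_sm = z_ratio_sm,
    note = NULL
  )
}
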