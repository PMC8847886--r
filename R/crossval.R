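#' Family-respecting train/test split
#'
#' Assigns whole families to the training set greedily (largest families
#' first, randomized among equal sizes) until the target training fraction
#' is reached; no family ever spans both sets, so the achieved fraction is
#' within one family of the target.
#'
#' @param families family table (`subject_id`, `family_id`, `member_type`).
#' @param train_frac target training fraction (default 0.8).
#' @return list with `train` and `test` subject-id vectors and
#'   `achieved_frac`.
#' @export
family_split <- function(families, train_frac = 0.8) {
  if (train_frac <= 0 || train_frac >= 1) stop("`train_frac` must be in (0, 1)", call. = FALSE)
  fam <- split(families$subject_id, families$family_id)
  if (length(fam) < 2L) stop("cannot split a single-family cohort", call. = FALSE)
  sizes <- lengths(fam)
  ord <- sample.int(length(fam))              # randomize, then stable-sort by size
  ord <- ord[order(-sizes[ord])]
  n <- nrow(families)
  target <- round(train_frac * n)
  train <- character(0)
  test <- character(0)
  n_train <- 0L
  for (fi in ord) {
    if (n_train < target) {
      train <- c(train, fam[[fi]])
      n_train <- n_train + sizes[fi]
    } else {
      test <- c(test, fam[[fi]])
    }
  }
  if (length(test) == 0L) {
    stop("test set is empty; lower `train_frac` or supply more families", call. = FALSE)
  }
  list(train = train, test = test, achieved_frac = unname(n_train) / n)
}

# Prepare both views for one subject subset; re-estimates confounds,
# deconfounding and PCA within the subset (the literal convention).
prepare_views_subset <- function(sm, conf_base, n0, ids, d,
                                 low_mean_threshold = 0.1, filter_sm = TRUE) {
  rows <- match(ids, sm$subject_id)
  conf <- build_confounds(conf_base[rows, , drop = FALSE])
  sm_prep <- prepare_sm(sm[rows, , drop = FALSE], conf, d = d, filter = filter_sm)
  conn_prep <- prepare_connectome(n0[rows, , drop = FALSE], conf, d = d,
                                  low_mean_threshold = low_mean_threshold)
  list(sm = sm_prep, conn = conn_prep, confounds = conf)
}

#' Train/test CCA evaluation
#'
#' Fits a CCA on the training subset and evaluates it on the held-out
#' subset: `U_test = N5_test %*% A_train`, `V_test = S5_test %*% B_train`,
#' reporting the correlation of the requested mode's columns. By default
#' the test-side matrices are prepared by re-estimating deconfounding and
#' PCA within the test subset (the literal convention); with
#' `strict = TRUE` the training deconfounding coefficients and PCA bases
#' are applied to the test data instead (the strict-generalization
#' contract).
#'
#' @param sm SM tibble (with `subject_id`).
#' @param conf_base base confound table (7 columns, rows aligned with
#'   `sm`).
#' @param n0 subjects x E edge matrix, rows aligned with `sm` (rownames =
#'   subject ids).
#' @param split a [family_split()] result.
#' @param d number of PCA/CCA dimensions.
#' @param mode mode index evaluated (default 1).
#' @param strict apply training bases to the test data (default `FALSE`).
#' @param filter_sm run the quantitative SM filter inside each subset.
#' @return list with `r_test`, the training `fit`, and the test variate
#'   matrices `U_test`, `V_test`.
#' @export
train_test_cca <- function(sm, conf_base, n0, split, d, mode = 1,
                           strict = FALSE, filter_sm = TRUE) {
  tr <- prepare_views_subset(sm, conf_base, n0, split$train, d,
                             filter_sm = filter_sm)
  if (length(split$test) <= d) {
    stop("test set smaller than `d`; use a smaller dimensionality", call. = FALSE)
  }
  fit <- suppressWarnings(fit_cca(tr$conn$N5, tr$sm$S5))
  if (strict) {
    te <- project_views_strict(sm, conf_base, n0, split$test, tr, d,
                               filter_sm = filter_sm)
  } else {
    te_prep <- prepare_views_subset(sm, conf_base, n0, split$test, d,
                                    filter_sm = filter_sm)
    te <- align_test_scores(tr, te_prep)
  }
  dd <- min(ncol(te$N5), ncol(fit$A))
  U_test <- te$N5[, seq_len(dd), drop = FALSE] %*% fit$A[seq_len(dd), , drop = FALSE]
  dd <- min(ncol(te$S5), ncol(fit$B))
  V_test <- te$S5[, seq_len(dd), drop = FALSE] %*% fit$B[seq_len(dd), , drop = FALSE]
  r_test <- stats::cor(U_test[, mode], V_test[, mode])
  list(r_test = r_test, fit = fit, U_test = U_test, V_test = V_test)
}

# Sign-align independently re-estimated test-side PCA components to the
# training basis: component k of the test scores is flipped when its
# feature-space loading vector points opposite the training component's.
# Connectome loadings are compared on the N1 block (whose columns are the
# same edges in both subsets); SM loadings on the shared kept SM columns.
align_test_scores <- function(tr, te_prep) {
  E <- ncol(tr$conn$N0)
  L_tr <- crossprod(tr$conn$N4, tr$conn$N5)[seq_len(E), , drop = FALSE]
  L_te <- crossprod(te_prep$conn$N4, te_prep$conn$N5)[seq_len(E), , drop = FALSE]
  dd <- min(ncol(L_tr), ncol(L_te))
  N5_te <- te_prep$conn$N5
  for (k in seq_len(dd)) {
    if (sum(L_tr[, k] * L_te[, k]) < 0) N5_te[, k] <- -N5_te[, k]
  }
  shared <- intersect(colnames(tr$sm$S1), colnames(te_prep$sm$S1))
  Ls_tr <- crossprod(impute_zero(tr$sm$S3[, shared, drop = FALSE]), tr$sm$S5)
  Ls_te <- crossprod(impute_zero(te_prep$sm$S3[, shared, drop = FALSE]), te_prep$sm$S5)
  dd <- min(ncol(Ls_tr), ncol(Ls_te))
  S5_te <- te_prep$sm$S5
  for (k in seq_len(dd)) {
    if (sum(Ls_tr[, k] * Ls_te[, k]) < 0) S5_te[, k] <- -S5_te[, k]
  }
  list(N5 = N5_te, S5 = S5_te)
}

# strict generalization: training deconfounding betas and PCA bases applied
# to the held-out subjects
project_views_strict <- function(sm, conf_base, n0, ids, tr, d, filter_sm = TRUE) {
  rows <- match(ids, sm$subject_id)
  conf_te <- build_confounds(conf_base[rows, , drop = FALSE])
  design_tr <- cbind(1, tr$confounds)

  # connectome side: reuse training column means / scales / drop set
  n0_tr <- tr$conn$N0
  mu_tr <- colMeans(n0_tr)
  n0_te <- n0[rows, , drop = FALSE]
  N1_te <- sweep(n0_te, 2, mu_tr, "-") / global_sd(sweep(n0_tr, 2, mu_tr, "-"))
  keep <- !(seq_len(ncol(n0_te)) %in% tr$conn$dropped$edge_id)
  N2_tr_raw <- sweep(n0_tr[, keep, drop = FALSE], 2, abs(mu_tr[keep]), "/")
  N2_te <- sweep(n0_te[, keep, drop = FALSE], 2, abs(mu_tr[keep]), "/")
  N2_te <- sweep(N2_te, 2, colMeans(N2_tr_raw), "-") /
    global_sd(demean_cols(N2_tr_raw))
  N3_te <- cbind(N1_te, N2_te)
  beta_conn <- qr.coef(qr(design_tr), tr$conn$N3)
  N4_te <- N3_te - cbind(1, conf_te) %*% beta_conn
  sv <- svd(tr$conn$N4, nu = 0, nv = min(d, min(dim(tr$conn$N4))))
  N5_te <- N4_te %*% sv$v

  # SM side: per-column Gaussianization is rank-based within the subset;
  # deconfound with training betas, then map through the training subject-
  # space PCA via the SM-space basis W = pinv(S3_train) %*% S5_train
  rows_all <- match(ids, sm$subject_id)
  sm_te <- sm[rows_all, , drop = FALSE]
  keep_sm <- colnames(tr$sm$S1)
  S1_te <- as.matrix(sm_te[keep_sm])
  S2_te <- apply(S1_te, 2, function(x) {
    if (length(unique(x[!is.na(x)])) < 2L) rep(0, length(x)) else inverse_normal_transform(x)
  })
  beta_sm <- qr.coef(qr(design_tr), impute_zero(tr$sm$S2))
  S3_te <- S2_te - cbind(1, conf_te) %*% beta_sm
  W <- MASS::ginv(impute_zero(tr$sm$S3)) %*% tr$sm$S5
  S5_te <- impute_zero(S3_te) %*% W
  list(N5 = N5_te, S5 = S5_te)
}

impute_zero <- function(x) {
  x[is.na(x)] <- 0
  x
}

#' Repeated family-respecting cross-validation
#'
#' Repeats the 80-20 train/test evaluation with independent random
#' family-respecting splits; each repetition's test-set correlation is
#' tested against a family-restricted permutation null in which the
#' test-side SM rows are shuffled within test-set family blocks.
#'
#' @inheritParams train_test_cca
#' @param families family table for the whole cohort.
#' @param reps number of repetitions (default 10).
#' @param perms permutations per repetition (default 1000).
#' @param train_frac training fraction (default 0.8).
#' @param seed master seed; repetition `i` is seeded with `seed + i`.
#' @return a tibble of class `pn_cv` (`rep`, `r_test`, `p`, `n_train`,
#'   `n_test`) with `mean_r` and `sd_r` attributes.
#' @export
repeated_cv <- function(sm, conf_base, n0, families, d, reps = 10,
                        perms = 1000, train_frac = 0.8, mode = 1,
                        strict = FALSE, filter_sm = TRUE, seed = 1L) {
  if (reps < 1) stop("`reps` must be at least 1", call. = FALSE)
  out <- vector("list", reps)
  for (i in seq_len(reps)) {
    set.seed(seed + i)
    split <- family_split(families, train_frac = train_frac)
    tt <- train_test_cca(sm, conf_base, n0, split, d = d, mode = mode,
                         strict = strict, filter_sm = filter_sm)
    te_fams <- families[families$subject_id %in% split$test, , drop = FALSE]
    te_fams <- te_fams[match(split$test, te_fams$subject_id), ]
    blocks <- suppressWarnings(build_blocks(te_fams))
    r_null <- numeric(perms)
    for (b in seq_len(perms)) {
      p <- sample_permutation(blocks)
      r_null[b] <- stats::cor(tt$U_test[, mode], tt$V_test[p, mode])
    }
    pval <- (1 + sum(r_null >= tt$r_test)) / (1 + perms)
    out[[i]] <- tibble::tibble(rep = i, r_test = tt$r_test, p = pval,
                               n_train = length(split$train),
                               n_test = length(split$test))
  }
  res <- dplyr::bind_rows(out)
  attr(res, "mean_r") <- mean(res$r_test)
  attr(res, "sd_r") <- stats::sd(res$r_test)
  attr(res, "mean_null_r") <- NULL
  class(res) <- c("pn_cv", class(res))
  res
}
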