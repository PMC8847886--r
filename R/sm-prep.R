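#' Quantitative subject-measure filter
#'
#' Applies the three sequential quantitative criteria to each SM column:
#' (1) at least `min_present` of subjects must have data; (2) fewer than
#' `max_identical` of subjects may share the same value; (3) no extreme
#' outlier, defined by `max(Y) > outlier_factor * mean(Y)` where
#' `Y = (X - median(X))^2` over non-missing values. Each dropped SM is
#' attributed to the first criterion it fails (order 1, 2, 3).
#'
#' @param sm tibble or data frame of SM columns (a `subject_id` column, if
#'   present, is carried through untouched); `NA` marks missing.
#' @param min_present minimum fraction of subjects with data (default 0.5).
#' @param max_identical maximum fraction of subjects sharing one value
#'   (default 0.95; an SM is dropped when the fraction is `>=` this value).
#' @param outlier_factor outlier ratio threshold (default 100).
#' @return list with `kept` (tibble of surviving SM columns, plus
#'   `subject_id` if supplied) and `ledger` (tibble: `sm_name`, `status`,
#'   `frac_present`, `frac_identical`, `outlier_ratio`).
#' @examples
#' sm <- tibble::tibble(a = rnorm(20), b = rep(1, 20))
#' quantitative_filter(sm)$ledger
#' @export
quantitative_filter <- function(sm, min_present = 0.5, max_identical = 0.95,
                                outlier_factor = 100) {
  id <- NULL
  if ("subject_id" %in% names(sm)) {
    id <- sm[["subject_id"]]
    sm <- sm[setdiff(names(sm), "subject_id")]
  }
  if (nrow(sm) < 1L) stop("at least one subject is required", call. = FALSE)
  stats_per_sm <- purrr::imap(sm, function(x, nm) {
    x <- as.numeric(x)
    n <- length(x)
    obs <- x[!is.na(x)]
    frac_present <- length(obs) / n
    frac_identical <- if (length(obs) == 0) 1 else max(table(obs)) / n
    outlier_ratio <- if (length(obs) == 0) NA_real_ else {
      y <- (obs - stats::median(obs))^2
      if (mean(y) == 0) 0 else max(y) / mean(y)
    }
    status <- if (frac_present < min_present) "dropped_c1"
      else if (frac_identical >= max_identical) "dropped_c2"
      else if (is.finite(outlier_ratio) && outlier_ratio > outlier_factor) "dropped_c3"
      else "kept"
    tibble::tibble(sm_name = nm, status = status, frac_present = frac_present,
                   frac_identical = frac_identical, outlier_ratio = outlier_ratio)
  })
  ledger <- dplyr::bind_rows(stats_per_sm)
  kept_names <- ledger$sm_name[ledger$status == "kept"]
  kept <- sm[kept_names]
  if (!is.null(id)) kept <- dplyr::bind_cols(tibble::tibble(subject_id = id), kept)
  list(kept = kept, ledger = ledger)
}

#' Rank-based inverse normal transformation
#'
#' Replaces each non-missing value by `qnorm((rank - 3/8) / (m + 1/4))`
#' (the Blom offset), where `m` is the number of non-missing values; ties
#' receive average ranks and missing values stay missing. The result is
#' invariant to any monotone transformation of the input.
#'
#' @param x numeric vector, possibly with `NA`.
#' @return numeric vector of the same length.
#' @examples
#' inverse_normal_transform(c(3, 1, 4, NA, 5))
#' @export
inverse_normal_transform <- function(x) {
  obs <- !is.na(x)
  v <- x[obs]
  if (length(unique(v)) < 2L) {
    stop("inverse normal transform requires at least 2 distinct non-missing values",
         call. = FALSE)
  }
  r <- rank(v, ties.method = "average")
  out <- x
  out[obs] <- stats::qnorm((r - 3 / 8) / (length(v) + 1 / 4))
  out
}

#' Gaussianize every column of an SM matrix
#'
#' Column-wise [inverse_normal_transform()].
#'
#' @param sm data frame or matrix of SM columns (`subject_id` carried
#'   through if present).
#' @return object of the same shape.
#' @export
gaussianize_sm <- function(sm) {
  if (is.data.frame(sm)) {
    dplyr::mutate(sm, dplyr::across(-dplyr::any_of("subject_id"),
                                    inverse_normal_transform))
  } else {
    apply(sm, 2, inverse_normal_transform)
  }
}

#' Build the confound regressor matrix
#'
#' From the 7 base confounds (site, scanner, mean FD, weight, BMI,
#' cube-root brain volume, cube-root intracranial volume, in that order):
#' every column is demeaned and missing entries are imputed as zero; the
#' quantitative confounds 3-7 are then squared and the squares demeaned,
#' giving 12 regressors in total. Categorical base columns (factor or
#' character) are expanded to one-of-K indicator blocks, each block counting
#' as one logical confound; squares are only added for quantitative
#' confounds 3-7.
#'
#' @param base data frame with exactly 7 base confound columns
#'   (`subject_id` carried through if present).
#' @return numeric matrix of regressors (12 columns when all base columns
#'   are numeric), every column mean-zero, no missing entries.
#' @examples
#' conf <- data.frame(site = c(0, 1, 0), scanner = c(1, 1, 0),
#'   mean_fd = c(0.1, 0.2, 0.15), weight = c(40, 50, 45), bmi = c(17, 19, 18),
#'   brainvol_cbrt = c(10, 11, 10.5), icv_cbrt = c(11, 11.5, 11.2))
#' ncol(build_confounds(conf))
#' @export
build_confounds <- function(base) {
  base <- as.data.frame(base)
  base <- base[setdiff(names(base), "subject_id")]
  if (ncol(base) != 7L) {
    stop("exactly 7 base confound columns are required", call. = FALSE)
  }
  expand <- function(x, nm) {
    if (is.factor(x) || is.character(x)) {
      f <- factor(x)
      if (nlevels(f) < 2L) return(NULL)
      m <- stats::model.matrix(~ f)[, -1, drop = FALSE]
      colnames(m) <- paste0(nm, "_", levels(f)[-1])
      m
    } else {
      m <- matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, nm))
      m
    }
  }
  blocks <- purrr::imap(base, expand)
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  demean_impute <- function(m) {
    m <- apply(m, 2, function(col) {
      col <- col - mean(col, na.rm = TRUE)
      col[is.na(col)] <- 0
      col
    })
    m
  }
  base_mat <- demean_impute(do.call(cbind, blocks))
  quant_idx <- 3:7
  sq <- base_mat[, unlist(lapply(quant_idx, function(i) {
    which(colnames(base_mat) %in% colnames(blocks[[i]]))
  })), drop = FALSE]
  sq <- sq^2
  sq <- sweep(sq, 2, colMeans(sq), "-")
  colnames(sq) <- paste0(colnames(sq), "_sq")
  out <- cbind(base_mat, sq)
  rownames(out) <- NULL
  out
}

#' Regress confounds out of a data matrix
#'
#' Per column, removes the least-squares projection onto
#' `[intercept, confounds]`, using only that column's non-missing rows;
#' missing entries stay missing. Columns of the confound design that are
#' linearly dependent are dropped with a warning.
#'
#' @param x numeric matrix (subjects x variables), possibly with `NA`.
#' @param confounds numeric confound matrix (subjects x regressors), no
#'   missing entries.
#' @return residual matrix with the same shape and missingness as `x`.
#' @export
deconfound <- function(x, confounds) {
  x <- as.matrix(x)
  confounds <- as.matrix(confounds)
  if (nrow(x) != nrow(confounds)) stop("row counts differ", call. = FALSE)
  design <- cbind(1, confounds)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    warning("confound design is rank deficient; dependent columns dropped")
    design <- design[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE]
  }
  out <- x
  if (!anyNA(x)) {
    fit <- qr.fitted(qr(design), x)
    return(x - fit)
  }
  # group columns by missingness pattern to batch the solves
  pat <- apply(is.na(x), 2, function(z) paste(which(z), collapse = ","))
  for (p in unique(pat)) {
    cols <- which(pat == p)
    miss <- if (p == "") integer(0) else as.integer(strsplit(p, ",")[[1]])
    rows <- setdiff(seq_len(nrow(x)), miss)
    if (length(rows) <= ncol(design)) {
      warning("too few observed rows to deconfound some columns; left unchanged")
      next
    }
    fit <- qr.fitted(qr(design[rows, , drop = FALSE]), x[rows, cols, drop = FALSE])
    out[rows, cols] <- x[rows, cols, drop = FALSE] - fit
  }
  out
}

#' Pairwise-complete subjects-by-subjects covariance
#'
#' For matrices with missing entries, estimates the subjects-by-subjects
#' covariance one SM at a time: entry `(a, b)` is the mean over SMs
#' observed in both subjects of the products of column-demeaned values;
#' SMs missing in either subject are ignored for that pair.
#'
#' @param x numeric matrix (subjects x SMs) with `NA` for missing.
#' @return symmetric `subjects x subjects` matrix.
#' @export
pairwise_covariance <- function(x) {
  x <- as.matrix(x)
  xc <- demean_cols(x)
  obs <- !is.na(xc)
  x0 <- xc
  x0[!obs] <- 0
  num <- tcrossprod(x0)
  cnt <- tcrossprod(obs * 1)
  if (any(cnt == 0)) {
    bad <- which(cnt == 0, arr.ind = TRUE)
    bad <- bad[bad[, 1] <= bad[, 2], , drop = FALSE]
    stop(sprintf("subject pairs share no observed SM: %s",
                 paste(apply(utils::head(bad, 5), 1, paste, collapse = "-"),
                       collapse = ", ")), call. = FALSE)
  }
  num / cnt
}

#' Project a symmetric matrix to the nearest positive-definite matrix
#'
#' Symmetrizes the input, clips eigenvalues below
#' `eps = 1e-10 * max(eigenvalue)` up to `eps`, and, if a Cholesky
#' factorization still fails numerically, doubles `eps` and re-clips until
#' it succeeds. For symmetric input the eigenvalue clipping is the
#' Frobenius-nearest positive semidefinite matrix.
#'
#' @param m square numeric matrix (symmetrized within tolerance).
#' @return symmetric positive-definite matrix of the same dimension.
#' @export
nearest_spd <- function(m) {
  m <- as.matrix(m)
  if (!all(is.finite(m))) stop("matrix has non-finite entries", call. = FALSE)
  if (nrow(m) != ncol(m)) stop("matrix must be square", call. = FALSE)
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  eps <- 1e-10 * max(abs(e$values))
  if (eps == 0) eps <- 1e-10
  repeat {
    vals <- pmax(e$values, eps)
    out <- e$vectors %*% (vals * t(e$vectors))
    out <- (out + t(out)) / 2
    ok <- !inherits(tryCatch(chol(out), error = identity), "error")
    if (ok) return(out)
    eps <- eps * 2
  }
}

#' PCA scores from a subjects-by-subjects SPD matrix
#'
#' Top-`d` eigenpairs of the (completed) subject covariance; score column
#' `k` is `u_k * sqrt(lambda_k)`, columns ordered by decreasing eigenvalue.
#'
#' @param s4 symmetric positive semidefinite `subjects x subjects` matrix.
#' @param d number of components (default 70).
#' @return `subjects x d` score matrix.
#' @export
pca_scores_from_spd <- function(s4, d = 70) {
  s4 <- as.matrix(s4)
  if (d > nrow(s4)) stop("`d` exceeds the matrix dimension", call. = FALSE)
  e <- eigen((s4 + t(s4)) / 2, symmetric = TRUE)
  lam <- pmax(e$values[seq_len(d)], 0)
  scores <- e$vectors[, seq_len(d), drop = FALSE] %*% diag(sqrt(lam), d)
  rownames(scores) <- rownames(s4)
  scores
}

#' Subject-measure selection bookkeeping
#'
#' Arithmetic of the SM selection report: from the measures matched across
#' batteries, the confounds and the "undesirable" measures are excluded to
#' give the final SM count; subjects missing more than half of the final
#' SMs are flagged for removal.
#'
#' @param n_matched measures surviving quantitative filtering and matching.
#' @param n_confounds measures reserved as confounds.
#' @param n_undesirable measures excluded as undesirable.
#' @param missing_frac_per_subject optional numeric vector of each subject's
#'   fraction of missing final SMs.
#' @param max_missing threshold above which a subject is flagged
#'   (default 0.5, strict).
#' @return list with `n_final` (final SM count) and `flagged_subjects`
#'   (integer indices, or names if the vector is named).
#' @examples
#' sm_bookkeeping(89, 7, 8)$n_final
#' @export
sm_bookkeeping <- function(n_matched, n_confounds, n_undesirable,
                           missing_frac_per_subject = NULL, max_missing = 0.5) {
  n_final <- n_matched - n_confounds - n_undesirable
  if (n_final < 0) stop("more exclusions than matched measures", call. = FALSE)
  flagged <- integer(0)
  if (!is.null(missing_frac_per_subject)) {
    idx <- which(missing_frac_per_subject > max_missing)
    flagged <- if (!is.null(names(missing_frac_per_subject))) names(missing_frac_per_subject)[idx] else idx
  }
  list(n_final = n_final, flagged_subjects = flagged)
}

#' Prepare the subject-measure view for CCA
#'
#' Runs the staged SM pipeline: `S1` (filtered raw SMs) -> `S2`
#' (rank-based inverse normal transform) -> `S3` (confounds regressed out)
#' -> `S4` (pairwise-complete subject covariance projected to the nearest
#' positive-definite matrix) -> `S5` (top-`d` PCA scores).
#'
#' @param sm tibble of SM columns with `subject_id`, `NA` for missing.
#' @param confounds confound regressor matrix from [build_confounds()].
#' @param d number of PCA components (default 70; desk scale typically 30).
#' @param filter apply [quantitative_filter()] first (default `TRUE`).
#' @return an object of class `prepared_sm`: list with matrices `S1`, `S2`,
#'   `S3`, `S4`, `S5`, the filter `ledger`, and `subject_id`.
#' @export
prepare_sm <- function(sm, confounds, d = 70, filter = TRUE) {
  subject_id <- sm[["subject_id"]]
  ledger <- NULL
  if (filter) {
    qf <- quantitative_filter(sm)
    sm <- qf$kept
    ledger <- qf$ledger
  }
  S1 <- as.matrix(sm[setdiff(names(sm), "subject_id")])
  rownames(S1) <- subject_id
  S2 <- apply(S1, 2, inverse_normal_transform)
  S3 <- deconfound(S2, confounds)
  S4 <- nearest_spd(pairwise_covariance(S3))
  if (d > ncol(S1)) d <- ncol(S1)
  S5 <- pca_scores_from_spd(S4, d = d)
  # sign convention in SM space (shared across subject subsets): flip each
  # component so its largest-magnitude SM loading is positive
  S3_0 <- S3
  S3_0[is.na(S3_0)] <- 0
  L <- crossprod(S3_0, S5)
  for (k in seq_len(ncol(S5))) {
    j <- which.max(abs(L[, k]))
    if (L[j, k] < 0) S5[, k] <- -S5[, k]
  }
  structure(list(S1 = S1, S2 = S2, S3 = S3, S4 = S4, S5 = S5,
                 ledger = ledger, subject_id = subject_id),
            class = "prepared_sm")
}
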