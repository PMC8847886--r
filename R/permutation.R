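#' Build exchangeability blocks from a family table
#'
#' Within a family, MZ co-twins may be permuted among themselves, DZ
#' co-twins among themselves, and non-twin siblings among themselves.
#' Across families, entire families with the same signature (the multiset
#' of member roles) may be swapped wholesale; singletons form one signature
#' group. An MZ or DZ member without a co-twin in its family is demoted to
#' a non-twin sibling with a warning, mirroring the handling of twins with
#' unknown zygosity.
#'
#' @param families tibble with `subject_id`, `family_id`, `member_type`
#'   (see [generate_family_structure()]).
#' @return an object of class `pn_blocks`: list with `families` (per-family
#'   member indices split by role), `signature` (per-family signature
#'   string), `signature_groups` (family indices grouped by signature), and
#'   `n` subjects.
#' @export
build_blocks <- function(families) {
  stopifnot(all(c("subject_id", "family_id", "member_type") %in% names(families)))
  if (anyDuplicated(families$subject_id)) {
    stop("duplicate subject ids in family table", call. = FALSE)
  }
  n <- nrow(families)
  role <- as.character(families$member_type)
  fam_split <- split(seq_len(n), families$family_id)

  demoted <- FALSE
  fams <- lapply(fam_split, function(idx) {
    r <- role[idx]
    for (tw in c("MZ", "DZ")) {
      k <- sum(r == tw)
      if (k == 1L) {                      # twin without a co-twin
        r[r == tw] <- "SIB"
        demoted <<- TRUE
      }
    }
    split(idx, factor(r, levels = c("MZ", "DZ", "SIB", "SINGLE")))
  })
  if (demoted) {
    warning("MZ/DZ member without a co-twin treated as a non-twin sibling")
  }
  signature <- vapply(fams, function(f) {
    paste(rep(names(f), lengths(f)), collapse = "+")
  }, character(1))
  structure(
    list(families = fams,
         signature = signature,
         signature_groups = split(seq_along(fams), signature),
         n = n),
    class = "pn_blocks"
  )
}

#' Sample one family-structure-preserving permutation
#'
#' Draws a uniform random permutation from the restricted group defined by
#' the exchangeability blocks: members are shuffled within their
#' within-family role sets, and whole families are shuffled within
#' same-signature groups with roles mapped slot-to-slot.
#'
#' @param blocks a [build_blocks()] result.
#' @return integer permutation vector `p` of length `n`; permuted data is
#'   `x[p, ]`.
#' @export
sample_permutation <- function(blocks) {
  fams <- blocks$families
  # within-family role shuffles
  shuffled <- lapply(fams, function(f) {
    lapply(f, function(idx) {
      if (length(idx) > 1L) idx[sample.int(length(idx))] else idx
    })
  })
  # across-family swaps within signature groups
  fam_target <- seq_along(fams)
  for (g in blocks$signature_groups) {
    fam_target[g] <- g[sample.int(length(g))]
  }
  # target-family slots receive the shuffled members of the source family,
  # role by role, so roles and signatures are preserved by construction
  p <- integer(blocks$n)
  for (fi in seq_along(fams)) {
    dst <- fams[[fam_target[fi]]]
    src <- shuffled[[fi]]
    for (r in names(src)) {
      if (length(src[[r]])) p[dst[[r]]] <- src[[r]]
    }
  }
  p
}

#' Permutation null distributions for the CCA
#'
#' Re-fits the CCA for each of `P` family-structure-preserving permutations
#' of the SM-side rows, recording the canonical correlations and,
#' optionally, the per-mode variance explained in the original connectome
#' and SM matrices (at matched mode index). Preprocessing is not recomputed
#' per permutation: rows of the already-prepared SM-side matrices are
#' permuted, matching the described procedure.
#'
#' @param n5 prepared connectome-side matrix.
#' @param s5 prepared SM-side matrix.
#' @param blocks a [build_blocks()] result.
#' @param P number of permutations (full cohort scale 100 000; desk default 500).
#' @param conn_ref,sm_ref original matrices (`N0`, `S2`) for
#'   variance-explained nulls; set `NULL` to skip them.
#' @param n_modes_ve number of leading modes for which variance-explained
#'   nulls are drawn (default 20).
#' @param confounds optional confound regressor matrix. When supplied, each
#'   permuted SM-side matrix is re-residualized against
#'   `[intercept, confounds]` (the Freedman-Lane scheme). Both prepared
#'   views live in the confound-orthogonal subspace; a plain row
#'   permutation moves the SM side out of it, which anticonservatively
#'   shrinks the null canonical correlations when the confound count is
#'   not negligible relative to the sample size. Re-residualizing restores
#'   the alignment and leaves the observed statistic unchanged (the
#'   prepared SM side is already confound-orthogonal).
#' @return an object of class `pn_null`: list with `perm_r` (`P x d`),
#'   `perm_ve_conn`, `perm_ve_sm` (`P x n_modes_ve` or `NULL`), and `P`.
#' @export
permutation_null <- function(n5, s5, blocks, P = 500, conn_ref = NULL,
                             sm_ref = NULL, n_modes_ve = 20,
                             confounds = NULL) {
  if (P < 1) stop("`P` must be at least 1", call. = FALSE)
  d <- min(ncol(n5), ncol(s5))
  want_ve <- !is.null(conn_ref) && !is.null(sm_ref)
  n_modes_ve <- min(n_modes_ve, d)
  qrd <- if (!is.null(confounds)) qr(cbind(1, as.matrix(confounds))) else NULL
  perm_r <- matrix(NA_real_, P, d)
  perm_ve_conn <- if (want_ve) matrix(NA_real_, P, n_modes_ve) else NULL
  perm_ve_sm <- if (want_ve) matrix(NA_real_, P, n_modes_ve) else NULL
  for (b in seq_len(P)) {
    p <- sample_permutation(blocks)
    s5_p <- s5[p, , drop = FALSE]
    if (!is.null(qrd)) s5_p <- s5_p - qr.fitted(qrd, s5_p)
    fit <- suppressWarnings(fit_cca(n5, s5_p))
    perm_r[b, seq_len(fit$d)] <- fit$r[seq_len(min(fit$d, d))]
    if (want_ve) {
      idx <- seq_len(n_modes_ve)
      perm_ve_conn[b, ] <- mode_variance_explained(fit$U[, idx, drop = FALSE], conn_ref)
      perm_ve_sm[b, ] <-
        mode_variance_explained(fit$V[, idx, drop = FALSE],
                                sm_ref[p, , drop = FALSE])
    }
  }
  structure(list(perm_r = perm_r, perm_ve_conn = perm_ve_conn,
                 perm_ve_sm = perm_ve_sm, P = P),
            class = "pn_null")
}
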