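#' Specify a synthetic family-structured cohort
#'
#' Builds the parameter object consumed by [simulate_cohort()] and the
#' individual `generate_*()` stages. The cohort emulates the structure of a
#' large developmental twin/sibling imaging study: monozygotic (MZ) and
#' dizygotic (DZ) twin pairs, non-twin sibling groups and single children,
#' with a planted low-rank mode linking subject measures (SMs) to
#' functional-connectivity edges so that downstream recovery can be verified
#' against ground truth.
#'
#' Latent subject scores are drawn with familial similarity
#' `score = sqrt(rho) * family_component + sqrt(1 - rho) * unique_component`,
#' giving within-family correlation `rho` in expectation, with
#' `rho_mz >= rho_dz >= rho_sib`. Each SM is
#' `loading * score + confound effects + Gaussian noise`; each subject's node
#' time series is drawn from a Gaussian whose precision matrix is
#' `Omega_base - score * Lambda`, where `Lambda` (`edge_loadings`) is a sparse
#' symmetric perturbation, so that ridge partial correlation is the matched
#' estimator of the planted edges.
#'
#' @param n_mz_families,n_dz_families number of MZ / DZ twin-pair families.
#' @param n_sib_families number of non-twin sibling families.
#' @param sibs_per_family siblings per sibling family.
#' @param n_singles number of single-child families.
#' @param n_nodes number of network nodes (desk scale 50; 200 mirrors a
#'   200-dimension group-ICA parcellation).
#' @param n_timepoints time points per subject after censoring/truncation
#'   (750 corresponds to 10 min at TR = 0.8 s).
#' @param n_sms number of genuine subject measures (pathological columns used
#'   to exercise the SM filters are appended on top of these).
#' @param n_modes number of planted cross-view modes (0 gives a null cohort).
#' @param sm_loadings `n_sms x n_modes` matrix of SM loadings, or `NULL` for
#'   the default (12 SMs loaded per mode, magnitudes 0.5-0.9, mixed signs).
#' @param edge_loadings list of `n_nodes x n_nodes` sparse symmetric
#'   zero-diagonal matrices (one per mode), or `NULL` for the default
#'   (25 disjoint node-pair edges of magnitude 0.12 per mode).
#' @param familial_corr list with elements `rho_mz`, `rho_dz`, `rho_sib` in
#'   `[0, 1]`, non-increasing in that order.
#' @param sm_noise_sd standard deviation of SM measurement noise.
#' @param missing_rate probability that an SM cell is missing completely at
#'   random.
#' @param confound_effects length-7 vector of per-confound effect sizes added
#'   to every SM (site, scanner, mean FD, weight, BMI, cube-root brain
#'   volume, cube-root intracranial volume).
#' @param runs_per_subject,expected_run_length motion-trace layout per
#'   subject.
#' @param fd_baseline,fd_sdlog lognormal baseline of framewise displacement
#'   (mm): `exp(N(log(fd_baseline), fd_sdlog))`.
#' @param spike_prob,spike_scale per-time-point probability and exponential
#'   scale (mm) of motion spikes exceeding the censoring threshold.
#' @param bad_run_frac fraction of runs made deliberately bad (short or
#'   high-motion).
#' @param t1_fail_prob probability a subject fails anatomical QC.
#' @param seed integer seed; the same spec (including seed) reproduces the
#'   cohort bit-identically.
#'
#' @return An object of class `cohort_spec` (a named list).
#' @seealso [simulate_cohort()], [generate_family_structure()]
#' @examples
#' spec <- cohort_spec(n_singles = 20, n_mz_families = 2, n_dz_families = 2,
#'                     n_sib_families = 2, n_nodes = 10, n_sms = 8)
#' spec$n_modes
#' @export
cohort_spec <- function(n_mz_families = 11,
                        n_dz_families = 15,
                        n_sib_families = 24,
                        sibs_per_family = 2,
                        n_singles = 200,
                        n_nodes = 50,
                        n_timepoints = 750,
                        n_sms = 74,
                        n_modes = 1,
                        sm_loadings = NULL,
                        edge_loadings = NULL,
                        familial_corr = list(rho_mz = 0.8, rho_dz = 0.5, rho_sib = 0.4),
                        sm_noise_sd = 1,
                        missing_rate = 0.02,
                        confound_effects = c(site = 0.2, scanner = 0.1, mean_fd = 0.3,
                                             weight = 0.1, bmi = 0.1,
                                             brainvol_cbrt = 0.15, icv_cbrt = 0.15),
                        runs_per_subject = 3,
                        expected_run_length = 380,
                        fd_baseline = 0.12,
                        fd_sdlog = 0.35,
                        spike_prob = 0.02,
                        spike_scale = 0.35,
                        bad_run_frac = 0.03,
                        t1_fail_prob = 0.01,
                        seed = 1L) {
  for (nm in c("n_mz_families", "n_dz_families", "n_sib_families",
               "sibs_per_family", "n_singles", "n_nodes", "n_timepoints",
               "n_sms", "n_modes", "runs_per_subject", "expected_run_length")) {
    assert_count(get(nm), nm)
  }
  assert_scalar(missing_rate, "missing_rate", 0, 1)
  assert_scalar(sm_noise_sd, "sm_noise_sd", 0)
  rho <- unlist(familial_corr[c("rho_mz", "rho_dz", "rho_sib")])
  if (length(rho) != 3L || anyNA(rho) || any(rho < 0) || any(rho > 1)) {
    stop("`familial_corr` must supply rho_mz, rho_dz, rho_sib in [0, 1]", call. = FALSE)
  }
  if (!(rho[["rho_mz"]] >= rho[["rho_dz"]] && rho[["rho_dz"]] >= rho[["rho_sib"]])) {
    stop("familial correlations must satisfy rho_mz >= rho_dz >= rho_sib", call. = FALSE)
  }
  if (length(confound_effects) != 7L) {
    stop("`confound_effects` must have length 7", call. = FALSE)
  }

  if (n_modes > 0 && is.null(sm_loadings)) {
    sm_loadings <- default_sm_loadings(n_sms, n_modes)
  }
  if (n_modes > 0 && is.null(edge_loadings)) {
    edge_loadings <- lapply(seq_len(n_modes), function(m) {
      default_edge_loadings(n_nodes, mode = m)
    })
  }
  if (n_modes > 0) {
    sm_loadings <- as.matrix(sm_loadings)
    if (nrow(sm_loadings) != n_sms || ncol(sm_loadings) != n_modes) {
      stop("`sm_loadings` must be n_sms x n_modes", call. = FALSE)
    }
    if (!is.list(edge_loadings)) edge_loadings <- list(edge_loadings)
    for (L in edge_loadings) {
      if (!isTRUE(all.equal(L, t(L))) || any(diag(L) != 0)) {
        stop("each `edge_loadings` matrix must be symmetric with zero diagonal",
             call. = FALSE)
      }
    }
  }

  structure(
    list(n_mz_families = n_mz_families, n_dz_families = n_dz_families,
         n_sib_families = n_sib_families, sibs_per_family = sibs_per_family,
         n_singles = n_singles, n_nodes = n_nodes, n_timepoints = n_timepoints,
         n_sms = n_sms, n_modes = n_modes,
         sm_loadings = sm_loadings, edge_loadings = edge_loadings,
         familial_corr = as.list(rho), sm_noise_sd = sm_noise_sd,
         missing_rate = missing_rate, confound_effects = confound_effects,
         runs_per_subject = runs_per_subject,
         expected_run_length = expected_run_length,
         fd_baseline = fd_baseline, fd_sdlog = fd_sdlog,
         spike_prob = spike_prob, spike_scale = spike_scale,
         bad_run_frac = bad_run_frac, t1_fail_prob = t1_fail_prob,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  n <- cohort_size(x)
  cat("<cohort_spec>", n, "subjects (",
      x$n_mz_families, "MZ,", x$n_dz_families, "DZ,",
      x$n_sib_families, "sib x", x$sibs_per_family, ",",
      x$n_singles, "singles );",
      x$n_nodes, "nodes x", x$n_timepoints, "timepoints;",
      x$n_sms, "SMs;", x$n_modes, "planted mode(s); seed", x$seed, "\n")
  invisible(x)
}

#' Total number of subjects implied by a cohort spec
#' @param spec a [cohort_spec()].
#' @return integer subject count.
#' @export
cohort_size <- function(spec) {
  2L * spec$n_mz_families + 2L * spec$n_dz_families +
    spec$n_sib_families * spec$sibs_per_family + spec$n_singles
}

# Default SM loadings: 12 SMs per mode (or fewer if n_sms is small) with
# magnitudes 0.5-0.9 and mixed signs, disjoint across modes.
default_sm_loadings <- function(n_sms, n_modes) {
  L <- matrix(0, n_sms, n_modes)
  per <- 12L
  mags <- rep(c(0.9, -0.8, 0.85, -0.75, 0.7, -0.7, 0.65, -0.6, 0.6, -0.55,
                0.5, -0.5), length.out = per)
  for (m in seq_len(n_modes)) {
    idx <- ((m - 1L) * per + 1L):(m * per)
    idx <- idx[idx <= n_sms]
    L[idx, m] <- mags[seq_along(idx)]
  }
  L
}

# Default edge loadings: 25 disjoint node-pair edges (i, i + n/2) of
# magnitude 0.12 with alternating signs; disjoint node pairs keep the
# spectral norm equal to the magnitude so per-subject precisions stay PD.
default_edge_loadings <- function(n_nodes, n_edges = 25L, magnitude = 0.12,
                                  mode = 1L) {
  half <- n_nodes %/% 2L
  n_edges <- min(n_edges, half)
  L <- matrix(0, n_nodes, n_nodes)
  for (k in seq_len(n_edges)) {
    i <- ((k - 1L + (mode - 1L) * n_edges) %% half) + 1L
    j <- i + half
    s <- if (k %% 2L == 0L) -1 else 1
    L[i, j] <- L[j, i] <- s * magnitude
  }
  L
}

#' Baseline precision matrix of the synthetic connectome model
#'
#' The shared precision `Omega_base` is a ring structure: unit diagonal with
#' entries of alternating sign and magnitude 0.2 between neighbouring nodes.
#' Subject `i`'s precision is `Omega_base - score_i * Lambda`. The closed-form
#' partial correlation implied by `Omega_base` is the oracle for the
#' group-mean netmat when no mode is planted.
#'
#' @param spec a [cohort_spec()].
#' @return an `n_nodes x n_nodes` positive-definite matrix.
#' @export
base_precision <- function(spec) {
  n <- spec$n_nodes
  O <- diag(n)
  for (i in seq_len(n - 1L)) {
    v <- 0.2 * if (i %% 2L == 0L) -1 else 1
    O[i, i + 1L] <- O[i + 1L, i] <- v
  }
  O
}

#' Partial correlations implied by a precision matrix
#'
#' `r_ij = -P_ij / sqrt(P_ii P_jj)` with zero diagonal; used as the
#' closed-form oracle for partial-correlation netmat estimation.
#'
#' @param P a symmetric positive-definite precision matrix.
#' @return symmetric matrix of partial correlations, zero diagonal.
#' @export
precision_to_partial <- function(P) {
  d <- sqrt(diag(P))
  R <- -P / tcrossprod(d)
  diag(R) <- 0
  R
}
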