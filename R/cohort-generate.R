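#' Generate the family structure of a synthetic cohort
#'
#' Emits one row per subject with its family id and member type. MZ and DZ
#' twins come in same-family pairs; sibling families have
#' `spec$sibs_per_family` members; single children form one-member families.
#' The layout is deterministic (no randomness is involved).
#'
#' @param spec a [cohort_spec()].
#' @return a tibble with columns `subject_id`, `family_id`, `member_type`
#'   (factor with levels `MZ`, `DZ`, `SIB`, `SINGLE`).
#' @examples
#' generate_family_structure(cohort_spec(n_mz_families = 1, n_dz_families = 0,
#'   n_sib_families = 0, n_singles = 2, n_sms = 5))
#' @export
generate_family_structure <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  fam_sizes <- c(rep(2L, spec$n_mz_families),
                 rep(2L, spec$n_dz_families),
                 rep(spec$sibs_per_family, spec$n_sib_families),
                 rep(1L, spec$n_singles))
  fam_type <- c(rep("MZ", spec$n_mz_families),
                rep("DZ", spec$n_dz_families),
                rep("SIB", spec$n_sib_families),
                rep("SINGLE", spec$n_singles))
  n_fam <- length(fam_sizes)
  if (n_fam == 0L) stop("cohort spec implies zero subjects", call. = FALSE)
  family_id <- rep(sprintf("fam%04d", seq_len(n_fam)), fam_sizes)
  member_type <- rep(fam_type, fam_sizes)
  n <- length(family_id)
  tibble::tibble(
    subject_id = sprintf("sub%04d", seq_len(n)),
    family_id = family_id,
    member_type = factor(member_type, levels = c("MZ", "DZ", "SIB", "SINGLE"))
  )
}

#' Generate latent subject scores with familial similarity
#'
#' For each planted mode, every family draws a shared standard-normal
#' component and each member an independent one; the member's score is
#' `sqrt(rho) * shared + sqrt(1 - rho) * unique` with `rho` set by member
#' type (`rho_mz`, `rho_dz`, `rho_sib`; singles have no shared part).
#' Population mean 0 and variance 1 per mode; within-family correlation
#' equals `rho` in expectation.
#'
#' @param spec a [cohort_spec()].
#' @param families output of [generate_family_structure()].
#' @return a `pn_ground_truth` list with `subject_scores`
#'   (subjects x n_modes matrix, rownames = subject ids), `true_sm_loadings`
#'   and `true_edge_loadings`.
#' @export
generate_scores <- function(spec, families) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- nrow(families)
  k <- spec$n_modes
  rho_of <- c(MZ = spec$familial_corr$rho_mz,
              DZ = spec$familial_corr$rho_dz,
              SIB = spec$familial_corr$rho_sib,
              SINGLE = 0)
  scores <- matrix(0, n, max(k, 1L))
  if (k > 0) {
    set.seed(spec$seed + 1L)
    fam_idx <- split(seq_len(n), families$family_id)
    for (m in seq_len(k)) {
      shared <- stats::rnorm(length(fam_idx))
      names(shared) <- names(fam_idx)
      unique_c <- stats::rnorm(n)
      s <- numeric(n)
      for (f in names(fam_idx)) {
        idx <- fam_idx[[f]]
        rho <- rho_of[[as.character(families$member_type[idx[1]])]]
        s[idx] <- sqrt(rho) * shared[[f]] + sqrt(1 - rho) * unique_c[idx]
      }
      scores[, m] <- s
    }
  }
  scores <- scores[, seq_len(k), drop = FALSE]
  rownames(scores) <- families$subject_id
  structure(
    list(subject_scores = scores,
         true_sm_loadings = spec$sm_loadings,
         true_edge_loadings = spec$edge_loadings),
    class = "pn_ground_truth"
  )
}

#' Generate the subject-measure table and confound table
#'
#' Each genuine SM column is `loading * score + confound effects + noise`,
#' with cells deleted completely at random at `spec$missing_rate`. Four
#' deliberately pathological columns are always appended in fixed trailing
#' positions to exercise the quantitative SM filters: a constant column, a
#' column in which more than 95% of subjects share one value, a column with
#' an extreme outlier, and a column missing in more than half of subjects.
#' Their roles are recorded in the `sm_meta` attribute.
#'
#' @param truth output of [generate_scores()].
#' @param spec a [cohort_spec()].
#' @param families output of [generate_family_structure()].
#' @return a list with `sm` (tibble: `subject_id` + SM columns, `sm_meta`
#'   attribute) and `confounds` (tibble: `subject_id` + the 7 base confound
#'   columns).
#' @export
generate_sm_matrix <- function(truth, spec, families) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- nrow(families)
  set.seed(spec$seed + 2L)

  confounds <- tibble::tibble(
    subject_id = families$subject_id,
    site = stats::rbinom(n, 1, 0.5),
    scanner = stats::rbinom(n, 1, 0.5),
    mean_fd = stats::rlnorm(n, log(spec$fd_baseline), spec$fd_sdlog),
    weight = stats::rnorm(n, 45, 8),
    bmi = stats::rnorm(n, 18, 3),
    brainvol_cbrt = stats::rnorm(n, 10.5, 0.3),
    icv_cbrt = stats::rnorm(n, 11, 0.3)
  )
  conf_num <- scale(as.matrix(confounds[, -1]))
  conf_part <- as.vector(conf_num %*% spec$confound_effects)

  p <- spec$n_sms
  signal <- if (spec$n_modes > 0) {
    truth$subject_scores %*% t(spec$sm_loadings)
  } else {
    matrix(0, n, p)
  }
  noise <- matrix(stats::rnorm(n * p, sd = spec$sm_noise_sd), n, p)
  values <- signal + conf_part + noise
  if (spec$missing_rate > 0) {
    values[matrix(stats::runif(n * p) < spec$missing_rate, n, p)] <- NA_real_
  }
  colnames(values) <- sprintf("sm_%03d", seq_len(p))

  # pathological columns, fixed trailing positions; counts are exact so the
  # filter outcomes are deterministic at any cohort size
  low_var <- rep(0, n)
  low_var[sample.int(n, max(1L, floor(0.03 * n)))] <- 1
  outlier <- stats::rnorm(n, 10, 1)
  outlier[sample.int(n, 1L)] <- 1e4
  half_missing <- stats::rnorm(n)
  half_missing[sample.int(n, ceiling(0.6 * n))] <- NA_real_
  patho <- cbind(sm_constant = rep(5, n),
                 sm_low_variance = low_var,
                 sm_outlier = outlier,
                 sm_missing = half_missing)

  sm <- tibble::as_tibble(cbind(as.data.frame(values), as.data.frame(patho)))
  sm <- dplyr::bind_cols(tibble::tibble(subject_id = families$subject_id), sm)
  attr(sm, "sm_meta") <- tibble::tibble(
    sm_name = c(colnames(values), colnames(patho)),
    pathology = c(rep(NA_character_, p),
                  c("constant", "low_variance", "extreme_outlier", "over_half_missing"))
  )
  list(sm = sm, confounds = confounds)
}

#' Generate per-subject node time series from subject-varying precisions
#'
#' Subject `i` is sampled from a zero-mean Gaussian with precision
#' `Omega_i = Omega_base - sum_m score_im * Lambda_m`, where `Omega_base`
#' comes from [base_precision()] and `Lambda_m` are the planted edge
#' loadings. If a subject's precision would dip below a minimum eigenvalue
#' of 0.05, its loading contribution is scaled down until the bound holds
#' (positive definiteness is always maintained).
#'
#' @param truth output of [generate_scores()].
#' @param spec a [cohort_spec()].
#' @param families output of [generate_family_structure()].
#' @return named list of `n_timepoints x n_nodes` matrices, one per subject.
#' @export
generate_node_timeseries <- function(truth, spec, families) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- nrow(families)
  O_base <- base_precision(spec)
  set.seed(spec$seed + 3L)
  out <- vector("list", n)
  names(out) <- families$subject_id
  min_eig <- 0.05
  for (i in seq_len(n)) {
    M <- matrix(0, spec$n_nodes, spec$n_nodes)
    if (spec$n_modes > 0) {
      for (m in seq_len(spec$n_modes)) {
        M <- M + truth$subject_scores[i, m] * spec$edge_loadings[[m]]
      }
    }
    Omega <- O_base - M
    ev <- min(eigen(Omega, symmetric = TRUE, only.values = TRUE)$values)
    scale_c <- 1
    while (ev < min_eig && scale_c > 1e-4) {
      scale_c <- scale_c * 0.9
      Omega <- O_base - scale_c * M
      ev <- min(eigen(Omega, symmetric = TRUE, only.values = TRUE)$values)
    }
    if (ev <= 0) {
      stop(sprintf("precision matrix for subject %s is not positive definite after clipping",
                   families$subject_id[i]), call. = FALSE)
    }
    Sigma <- chol2inv(chol(Omega))
    Z <- matrix(stats::rnorm(spec$n_timepoints * spec$n_nodes),
                spec$n_timepoints, spec$n_nodes)
    out[[i]] <- Z %*% chol(Sigma)
  }
  out
}

#' Generate per-run framewise-displacement traces and QC flags
#'
#' Runs have a lognormal FD baseline with exponential motion spikes at a
#' Bernoulli per-time-point rate; a configurable fraction of runs is made
#' deliberately bad (truncated short or with a high-motion baseline), and a
#' small fraction of subjects fails anatomical (T1) quality control.
#'
#' @param spec a [cohort_spec()].
#' @param families output of [generate_family_structure()].
#' @return a list with `runs` (tibble: `subject_id`, `run_index`,
#'   `expected_length`, list-column `fd`) and `qc` (tibble: `subject_id`,
#'   `t1_pass`).
#' @export
generate_motion_table <- function(spec, families) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- nrow(families)
  set.seed(spec$seed + 4L)
  rows <- vector("list", n * spec$runs_per_subject)
  k <- 0L
  for (i in seq_len(n)) {
    for (r in seq_len(spec$runs_per_subject)) {
      bad <- stats::runif(1) < spec$bad_run_frac
      len <- spec$expected_run_length
      baseline <- spec$fd_baseline
      if (bad) {
        if (stats::runif(1) < 0.5) len <- 150L else baseline <- 0.5
      }
      fd <- stats::rlnorm(len, log(baseline), spec$fd_sdlog)
      spikes <- stats::runif(len) < spec$spike_prob
      fd[spikes] <- fd[spikes] + 0.31 + stats::rexp(sum(spikes), rate = 1 / spec$spike_scale)
      k <- k + 1L
      rows[[k]] <- tibble::tibble(subject_id = families$subject_id[i],
                                  run_index = r,
                                  expected_length = spec$expected_run_length,
                                  fd = list(fd))
    }
  }
  runs <- dplyr::bind_rows(rows)
  qc <- tibble::tibble(subject_id = families$subject_id,
                       t1_pass = stats::runif(n) >= spec$t1_fail_prob)
  list(runs = runs, qc = qc)
}

#' Simulate a complete synthetic cohort
#'
#' Runs all generator stages under the spec's seed and returns the assembled
#' cohort: family structure, ground-truth scores, SM and confound tables,
#' per-subject node time series, and per-run motion traces with QC flags.
#' Identical specs (including seed) produce bit-identical cohorts.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `pn_cohort`: a list with elements `spec`,
#'   `families`, `truth`, `sm`, `confounds`, `timeseries`, `motion`, `qc`.
#' @examples
#' co <- simulate_cohort(cohort_spec(n_mz_families = 2, n_dz_families = 2,
#'   n_sib_families = 2, n_singles = 10, n_nodes = 12, n_timepoints = 80,
#'   n_sms = 10))
#' nrow(co$families)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  families <- generate_family_structure(spec)
  truth <- generate_scores(spec, families)
  smc <- generate_sm_matrix(truth, spec, families)
  ts <- generate_node_timeseries(truth, spec, families)
  motion <- generate_motion_table(spec, families)
  structure(
    list(spec = spec, families = families, truth = truth,
         sm = smc$sm, confounds = smc$confounds,
         timeseries = ts, motion = motion$runs, qc = motion$qc),
    class = "pn_cohort"
  )
}

#' @export
print.pn_cohort <- function(x, ...) {
  cat("<pn_cohort>", nrow(x$families), "subjects,",
      x$spec$n_nodes, "nodes,", ncol(x$sm) - 1L, "SM columns,",
      x$spec$n_modes, "planted mode(s)\n")
  invisible(x)
}
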