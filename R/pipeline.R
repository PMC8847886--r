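#' Run the full connectome-SM CCA pipeline
#'
#' Orchestrates every stage on a cohort (real or synthetic): motion-based
#' subject selection, per-subject ridge partial-correlation and
#' full-correlation netmats, the subjects-by-edges matrix, SM and
#' connectome preparation, the CCA, the family-restricted permutation null
#' with variance-explained statistics, the replication-criteria report, the
#' positive-negative axis, edge-level mapping and Ward clustering, and
#' (optionally) repeated family-respecting cross-validation. All
#' randomness is governed by `seed`; identical inputs and seed reproduce
#' identical results.
#'
#' @param cohort a `pn_cohort` from [simulate_cohort()], or a
#'   [cohort_spec()] (which is simulated first).
#' @param d PCA/CCA dimensionality (desk-scale default 30; 70 mirrors the
#'   reference analysis).
#' @param rho ridge penalty for partial netmats (default 0.01).
#' @param permutations CCA permutation-null size (default 500 at desk
#'   scale; 100 000 at full cohort scale).
#' @param n_modes_ve leading modes for variance-explained statistics
#'   (default 10).
#' @param axis_permutations permutations for per-SM axis z-scores.
#' @param top_k number of top edges reported (default 30).
#' @param ward_k number of node clusters (default 4).
#' @param held_out_sms names of SM columns kept out of the CCA but included
#'   in the positive-negative axis.
#' @param apply_qc run motion/QC subject selection first (default `TRUE`).
#' @param run_cv run repeated cross-validation (default `TRUE`).
#' @param cv_reps,cv_perms,train_frac cross-validation settings.
#' @param seed integer seed for permutations and splits.
#' @return an object of class `pn_result`: a list with elements `qc`,
#'   `edges`, `group_partial`, `group_full`, `prep_sm`, `prep_conn`,
#'   `blocks`, `fit`, `null`, `variance`, `criteria`, `primary_mode`,
#'   `axis`, `edge_map`, `clusters`, `cv`, and the effective `params`.
#' @export
run_pipeline <- function(cohort, d = 30, rho = 0.01, permutations = 500,
                         n_modes_ve = 10, axis_permutations = 500,
                         top_k = 30, ward_k = 4, held_out_sms = character(),
                         apply_qc = TRUE, run_cv = TRUE, cv_reps = 10,
                         cv_perms = 1000, train_frac = 0.8, seed = 1L) {
  if (inherits(cohort, "cohort_spec")) cohort <- simulate_cohort(cohort)
  stopifnot(inherits(cohort, "pn_cohort"))

  qc <- NULL
  keep_ids <- cohort$families$subject_id
  if (apply_qc) {
    qc <- select_subjects(cohort$motion, cohort$qc)
    keep_ids <- intersect(keep_ids, qc$included)
  }
  families <- cohort$families[cohort$families$subject_id %in% keep_ids, ]
  rows <- match(families$subject_id, cohort$sm$subject_id)
  sm <- cohort$sm[rows, , drop = FALSE]
  conf_base <- cohort$confounds[rows, , drop = FALSE]
  ts <- cohort$timeseries[families$subject_id]

  netmats_partial <- lapply(ts, partial_netmat_ridge, rho = rho)
  netmats_full <- lapply(ts, full_netmat)
  edges <- assemble_edges(netmats_partial)
  group_partial <- group_average(netmats_partial)
  group_full <- group_average(netmats_full)

  conf <- build_confounds(conf_base)
  cca_sm <- sm[setdiff(names(sm), held_out_sms)]
  prep_sm <- prepare_sm(cca_sm, conf, d = d)
  # subjects missing more than half of the final SMs would be flagged here
  miss_frac <- rowMeans(is.na(prep_sm$S1))
  flagged <- sm_bookkeeping(ncol(prep_sm$S1), 0, 0,
                            missing_frac_per_subject =
                              stats::setNames(miss_frac, families$subject_id))$flagged_subjects
  if (length(flagged)) {
    keep <- !(families$subject_id %in% flagged)
    families <- families[keep, ]
    sm <- sm[keep, , drop = FALSE]
    conf_base <- conf_base[keep, , drop = FALSE]
    edges$values <- edges$values[keep, , drop = FALSE]
    conf <- build_confounds(conf_base)
    prep_sm <- prepare_sm(sm[setdiff(names(sm), held_out_sms)], conf, d = d)
  }
  prep_conn <- prepare_connectome(edges$values, conf, d = d)

  blocks <- suppressWarnings(build_blocks(families))
  set.seed(seed)
  fit <- suppressWarnings(fit_cca(prep_conn$N5, prep_sm$S5))
  null <- permutation_null(prep_conn$N5, prep_sm$S5, blocks, P = permutations,
                           conn_ref = prep_conn$N0, sm_ref = prep_sm$S2,
                           n_modes_ve = n_modes_ve, confounds = conf)
  vp <- variance_profile(fit, prep_conn$N0, prep_sm$S2, null)
  criteria <- evaluate_replication_criteria(vp)
  primary <- criteria$primary_mode
  if (is.na(primary)) primary <- which.max(vp$z_sm)

  # positive-negative axis on raw (non-Gaussianized) deconfounded SMs,
  # including any held-out SMs
  kept_sm <- colnames(prep_sm$S1)
  axis_cols <- c(kept_sm, intersect(held_out_sms, names(sm)))
  S7 <- as.matrix(sm[axis_cols])
  S8 <- deconfound(S7, conf)
  axis <- positive_negative_axis(S8, fit$V[, primary],
                                 included = axis_cols %in% kept_sm,
                                 blocks = blocks, P = axis_permutations)

  a_f1 <- edge_weights(fit$U[, primary], prep_conn$N0)
  edge_map <- list(
    a_f1 = a_f1,
    r_with_mean = correlate_with_mean(a_f1, group_partial),
    top = top_edges(a_f1, edges$edge_index, k = min(top_k, length(a_f1)))
  )
  clusters <- ward_clusters(group_full, k = ward_k)

  cv <- NULL
  if (run_cv) {
    cv <- repeated_cv(cca_sm, conf_base, edges$values, families, d = d,
                      reps = cv_reps, perms = cv_perms,
                      train_frac = train_frac, mode = 1, seed = seed)
  }

  structure(
    list(qc = qc, families = families, edges = edges,
         group_partial = group_partial, group_full = group_full,
         prep_sm = prep_sm, prep_conn = prep_conn, blocks = blocks,
         fit = fit, null = null, variance = vp, criteria = criteria,
         primary_mode = primary, axis = axis, edge_map = edge_map,
         clusters = clusters, cv = cv,
         params = list(d = d, rho = rho, permutations = permutations,
                       n_modes_ve = n_modes_ve, top_k = top_k,
                       ward_k = ward_k, seed = seed)),
    class = "pn_result"
  )
}

#' @export
print.pn_result <- function(x, ...) {
  cat("<pn_result>", nrow(x$fit$U), "subjects,", x$fit$d, "modes\n")
  cat("  primary mode:", x$primary_mode,
      " r =", signif(x$variance$r[x$primary_mode], 3),
      " FWE p =", signif(x$variance$p_fwe[x$primary_mode], 3), "\n")
  if (!is.null(x$cv)) {
    cat("  CV mean test r =", signif(attr(x$cv, "mean_r"), 3),
        "+/-", signif(attr(x$cv, "sd_r"), 2), "\n")
  }
  invisible(x)
}

#' Write pipeline outputs to disk
#'
#' Writes the tabular artifacts of a [run_pipeline()] result as plain-text
#' CSV/TSV files: the per-mode summary, the positive-negative axis, the top
#' edges, the node clusters, the family table, and (if present) the QC
#' exclusion ledger and cross-validation report.
#'
#' @param result a `pn_result`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- character(0)
  w <- function(x, name, tsv = FALSE) {
    path <- file.path(dir, name)
    if (tsv) readr::write_tsv(x, path) else readr::write_csv(x, path)
    f <<- c(f, path)
  }
  w(result$variance, "modes_summary.csv")
  w(result$axis, "positive_negative_axis.csv")
  w(result$edge_map$top, "top_edges.csv")
  w(result$clusters$labels, "node_clusters.tsv", tsv = TRUE)
  w(result$families, "families.tsv", tsv = TRUE)
  if (!is.null(result$qc)) w(result$qc$ledger, "qc_exclusions.csv")
  if (!is.null(result$cv)) w(tibble::as_tibble(result$cv), "crossval.csv")
  invisible(f)
}
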