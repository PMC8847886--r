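test_that("family structure matches the spec counts and taxonomy", {
  # degenerate: singles only
  sp <- cohort_spec(n_mz_families = 0, n_dz_families = 0, n_sib_families = 0,
                    n_singles = 5, n_sms = 4, n_modes = 0)
  fam <- generate_family_structure(sp)
  expect_equal(nrow(fam), 5L)
  expect_equal(length(unique(fam$family_id)), 5L)
  expect_true(all(fam$member_type == "SINGLE"))

  # count arithmetic: 2 MZ fams + 1 DZ fam + 1 sib fam x3 + 2 singles
  sp2 <- cohort_spec(n_mz_families = 2, n_dz_families = 1, n_sib_families = 1,
                     sibs_per_family = 3, n_singles = 2, n_sms = 4, n_modes = 0)
  fam2 <- generate_family_structure(sp2)
  expect_equal(nrow(fam2), 2 * 2 + 1 * 2 + 3 + 2)
  expect_equal(length(unique(fam2$family_id)), 6L)
  counts <- table(fam2$member_type)
  expect_equal(as.integer(counts[c("MZ", "DZ", "SIB", "SINGLE")]), c(4L, 2L, 3L, 2L))
  expect_setequal(levels(fam2$member_type), c("MZ", "DZ", "SIB", "SINGLE"))
})

test_that("cohorts are bit-identical under the same seed", {
  a <- simulate_cohort(tiny_spec(seed = 5))
  b <- simulate_cohort(tiny_spec(seed = 5))
  expect_identical(a$families, b$families)
  expect_identical(a$sm, b$sm)
  expect_identical(a$timeseries, b$timeseries)
  expect_identical(a$motion, b$motion)
  c2 <- simulate_cohort(tiny_spec(seed = 6))
  expect_false(identical(a$sm, c2$sm))
})

test_that("latent scores hit their familial correlation targets", {
  # perfect sharing: MZ co-twins identical
  sp <- cohort_spec(n_mz_families = 20, n_dz_families = 0, n_sib_families = 0,
                    n_singles = 0, n_sms = 4,
                    familial_corr = list(rho_mz = 1, rho_dz = 0.5, rho_sib = 0.2))
  fam <- generate_family_structure(sp)
  tr <- generate_scores(sp, fam)
  s <- tr$subject_scores[, 1]
  expect_equal(s[seq(1, 39, 2)], s[seq(2, 40, 2)], ignore_attr = TRUE)

  # independence: rho = 0 everywhere
  sp0 <- cohort_spec(n_mz_families = 500, n_dz_families = 0, n_sib_families = 0,
                     n_singles = 0, n_sms = 4, seed = 2,
                     familial_corr = list(rho_mz = 0, rho_dz = 0, rho_sib = 0))
  tr0 <- generate_scores(sp0, generate_family_structure(sp0))
  s0 <- tr0$subject_scores[, 1]
  expect_lt(abs(cor(s0[seq(1, 999, 2)], s0[seq(2, 1000, 2)])), 0.1)

  # Monte-Carlo check of the shared-component construction at rho_mz = 0.8
  sp8 <- cohort_spec(n_mz_families = 1000, n_dz_families = 0, n_sib_families = 0,
                     n_singles = 0, n_sms = 4, seed = 3,
                     familial_corr = list(rho_mz = 0.8, rho_dz = 0.5, rho_sib = 0.2))
  tr8 <- generate_scores(sp8, generate_family_structure(sp8))
  s8 <- tr8$subject_scores[, 1]
  r_mz <- cor(s8[seq(1, 1999, 2)], s8[seq(2, 2000, 2)])
  expect_lt(abs(r_mz - 0.8), 0.05)
  # population moments
  expect_lt(abs(mean(s8)), 0.05)
  expect_lt(abs(sd(s8) - 1), 0.05)

  # validation error
  expect_error(cohort_spec(familial_corr = list(rho_mz = 1.2, rho_dz = 0.5,
                                                rho_sib = 0.2)),
               "rho")
})

test_that("SM generation follows the attenuation model and missingness spec", {
  sp <- cohort_spec(n_mz_families = 0, n_dz_families = 0, n_sib_families = 0,
                    n_singles = 2000, n_sms = 3, seed = 4,
                    sm_loadings = matrix(c(1, 0.5, 0), 3, 1),
                    sm_noise_sd = 1, missing_rate = 0,
                    confound_effects = rep(0, 7))
  fam <- generate_family_structure(sp)
  tr <- generate_scores(sp, fam)
  out <- generate_sm_matrix(tr, sp, fam)
  X <- as.matrix(out$sm[sprintf("sm_%03d", 1:3)])
  expect_false(anyNA(X))
  # attenuation: corr = loading / sqrt(loading^2 + sd^2)
  expect_lt(abs(cor(X[, 1], tr$subject_scores[, 1]) - 1 / sqrt(2)), 0.03)
  expect_lt(abs(cor(X[, 2], tr$subject_scores[, 1]) - 0.5 / sqrt(1.25)), 0.03)
  expect_lt(abs(cor(X[, 3], tr$subject_scores[, 1])), 0.05)

  # noiseless: perfect correlation with the latent score
  sp0 <- cohort_spec(n_mz_families = 0, n_dz_families = 0, n_sib_families = 0,
                     n_singles = 50, n_sms = 2, seed = 4,
                     sm_loadings = matrix(c(1, -1), 2, 1),
                     sm_noise_sd = 0, missing_rate = 0,
                     confound_effects = rep(0, 7))
  fam0 <- generate_family_structure(sp0)
  tr0 <- generate_scores(sp0, fam0)
  X0 <- as.matrix(generate_sm_matrix(tr0, sp0, fam0)$sm[sprintf("sm_%03d", 1:2)])
  expect_equal(cor(X0[, 1], tr0$subject_scores[, 1]), 1)
  expect_equal(cor(X0[, 2], tr0$subject_scores[, 1]), -1)

  # pathological columns sit in fixed trailing positions with metadata
  meta <- attr(out$sm, "sm_meta")
  expect_equal(utils::tail(meta$pathology, 4),
               c("constant", "low_variance", "extreme_outlier", "over_half_missing"))
  expect_true(all(out$sm$sm_constant == 5))
  expect_gt(mean(is.na(out$sm$sm_missing)), 0.5)
})

test_that("node time series realize the subject-varying precision model", {
  # null scores: group-mean partial netmat matches the closed form of the
  # base precision
  sp <- cohort_spec(n_mz_families = 0, n_dz_families = 0, n_sib_families = 0,
                    n_singles = 200, n_nodes = 50, n_timepoints = 750,
                    n_sms = 4, n_modes = 0, seed = 8)
  fam <- generate_family_structure(sp)
  tr <- generate_scores(sp, fam)
  ts <- generate_node_timeseries(tr, sp, fam)
  expect_equal(dim(ts[[1]]), c(750L, 50L))
  nm <- lapply(ts, partial_netmat_ridge, rho = 1e-4)
  avg <- tanh(group_average(nm))          # back to r units
  oracle <- precision_to_partial(base_precision(sp))
  expect_lt(max(abs(avg - oracle)), 0.05)
})

test_that("motion traces obey the run-quality and spike model", {
  # no spikes, low baseline: every run passes
  sp <- cohort_spec(n_mz_families = 0, n_dz_families = 0, n_sib_families = 0,
                    n_singles = 30, n_sms = 4, n_modes = 0, spike_prob = 0,
                    fd_baseline = 0.1, bad_run_frac = 0, seed = 9)
  fam <- generate_family_structure(sp)
  mo <- generate_motion_table(sp, fam)
  expect_true(all(purrr::map2_lgl(mo$runs$fd, mo$runs$expected_length, run_is_good)))

  # a forced short run fails the length criterion
  expect_false(run_is_good(rep(0.1, 150), expected_length = 380))

  # censored fraction matches the binomial expectation of the spike process
  sp2 <- cohort_spec(n_mz_families = 0, n_dz_families = 0, n_sib_families = 0,
                     n_singles = 50, n_sms = 4, n_modes = 0, spike_prob = 0.05,
                     fd_baseline = 0.05, bad_run_frac = 0, seed = 10)
  mo2 <- generate_motion_table(sp2, generate_family_structure(sp2))
  fd_all <- unlist(mo2$runs$fd)
  p_hat <- mean(fd_all > 0.3)
  se <- sqrt(0.05 * 0.95 / length(fd_all))
  expect_lt(abs(p_hat - 0.05), 2 * se + 1e-6)
})
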