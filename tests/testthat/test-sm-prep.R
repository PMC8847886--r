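test_that("quantitative filter attributes drops to the first failing criterion", {
  set.seed(1)
  n <- 200
  present45 <- rnorm(n); present45[sample(n, ceiling(0.55 * n))] <- NA
  low_var <- c(rep(1, 191), rnorm(9))
  outlier <- rnorm(n); outlier[1] <- 1000    # max(Y)/mean(Y) >> 100 here
  ok <- rnorm(n)
  sm <- tibble::tibble(a = present45, b = low_var, c = outlier, d = ok,
                       e = rep(2, n))
  res <- quantitative_filter(sm)
  st <- setNames(res$ledger$status, res$ledger$sm_name)
  expect_equal(st[["a"]], "dropped_c1")
  expect_equal(st[["b"]], "dropped_c2")
  expect_equal(st[["c"]], "dropped_c3")
  expect_equal(st[["d"]], "kept")
  expect_equal(st[["e"]], "dropped_c2")      # constant: criterion 2 fires first
  # direct-formula oracle for the outlier statistic
  y <- (outlier - median(outlier))^2
  expect_equal(res$ledger$outlier_ratio[res$ledger$sm_name == "c"],
               max(y) / mean(y))
  expect_gt(max(y) / mean(y), 100)
  # statuses partition the SMs; re-filtering kept SMs drops nothing
  expect_equal(nrow(res$ledger), 5L)
  res2 <- quantitative_filter(res$kept)
  expect_true(all(res2$ledger$status == "kept"))
})

test_that("inverse normal transform follows the Blom formula with tie handling", {
  got <- inverse_normal_transform(c(10, 20, 30, 40, 50))
  expect_equal(got, c(-1.1797611176, -0.4972005707, 0, 0.4972005707,
                      1.1797611176), tolerance = 1e-9)
  # middle rank of odd n maps exactly to 0; missing stays missing
  x <- c(5, NA, 1, 9)
  gt <- inverse_normal_transform(x)
  expect_true(is.na(gt[2]))
  expect_equal(gt[1], 0)
  # rank invariance under monotone transforms
  z <- rnorm(50)
  expect_equal(inverse_normal_transform(exp(z)), inverse_normal_transform(z))
  # ties share the average-rank value
  tt <- inverse_normal_transform(c(1, 1, 2))
  expect_equal(tt[1], tt[2])
  expect_error(inverse_normal_transform(c(3, 3, 3)), "distinct")
})

test_that("gaussianized columns are near-symmetric for moderate n", {
  set.seed(2)
  for (i in 1:5) {
    x <- rexp(300)    # heavily skewed input, no ties
    g <- inverse_normal_transform(x)
    expect_lt(abs(mean(g)), 0.02)
    skew <- mean((g - mean(g))^3) / sd(g)^3
    expect_lt(abs(skew), 0.1)
  }
})

test_that("confound construction yields 12 demeaned regressors from 7 base", {
  set.seed(3)
  base <- tibble::tibble(site = rbinom(20, 1, 0.5), scanner = rbinom(20, 1, 0.5),
                         mean_fd = rlnorm(20, -2, 0.3), weight = rnorm(20, 45, 5),
                         bmi = rnorm(20, 18, 2), brainvol_cbrt = rnorm(20, 10.5, 0.2),
                         icv_cbrt = rnorm(20, 11, 0.2))
  cm <- build_confounds(base)
  expect_equal(ncol(cm), 12L)
  expect_true(all(abs(colMeans(cm)) < 1e-10))
  expect_false(anyNA(cm))
  # imputation is a no-op for a complete column
  base2 <- base; base2$weight[3] <- NA
  cm2 <- build_confounds(base2)
  expect_equal(cm2[, "bmi"], cm[, "bmi"])
  expect_equal(unname(cm2[3, "weight"]), 0)  # demeaned then imputed as zero
  # hand arithmetic on [1, 2, 3]
  toy <- tibble::as_tibble(setNames(as.data.frame(matrix(rnorm(21), 3, 7)),
                                    names(base)))
  toy$mean_fd <- c(1, 2, 3)
  cmt <- build_confounds(toy)
  expect_equal(cmt[, "mean_fd"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(cmt[, "mean_fd_sq"], c(1 / 3, -2 / 3, 1 / 3), ignore_attr = TRUE)
  expect_error(build_confounds(base[, 1:5]), "7")
})

test_that("deconfounding removes confound projections per observed rows", {
  set.seed(4)
  n <- 40
  conf <- cbind(rnorm(n), rnorm(n))
  # a data column equal to a confound leaves ~zero residual
  res <- deconfound(cbind(conf[, 1]), conf)
  expect_lt(max(abs(res)), 1e-10)
  # closed-form OLS oracle on a 5 x 2 toy
  x5 <- matrix(rnorm(10), 5, 2)
  c5 <- cbind(rnorm(5))
  d5 <- cbind(1, c5)
  oracle <- x5 - d5 %*% solve(crossprod(d5), crossprod(d5, x5))
  expect_equal(deconfound(x5, c5), oracle, tolerance = 1e-12)
  # orthogonal confounds: output = demeaned input
  xo <- matrix(rep(c(1, -1), 10), 20, 1)
  co <- matrix(rep(c(1, 1, -1, -1), 5), 20, 1)
  expect_equal(deconfound(xo, co), xo - mean(xo), tolerance = 1e-12)
  # missing entries stay missing; observed-row residuals orthogonal to confounds
  xm <- matrix(rnorm(n * 3), n, 3)
  xm[sample(length(xm), 15)] <- NA
  rm_ <- deconfound(xm, conf)
  expect_equal(is.na(rm_), is.na(xm))
  for (j in 1:3) {
    obs <- !is.na(rm_[, j])
    expect_lt(max(abs(crossprod(conf[obs, ], rm_[obs, j]))), 1e-8)
  }
})

test_that("pairwise covariance handles missing data and matches exact covariance", {
  set.seed(5)
  x <- matrix(rnorm(12 * 6), 12, 6)
  # no missingness: equals the demeaned cross-product divided by #SMs
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(pairwise_covariance(x), tcrossprod(xc) / ncol(x), tolerance = 1e-12)
  # 3 x 4 toy with one missing cell, per-pair hand arithmetic
  t3 <- matrix(c(1, 2, 3, 4,
                 2, 1, 0, 1,
                 0, NA, 1, 2), 3, 4, byrow = TRUE)
  tc <- sweep(t3, 2, colMeans(t3, na.rm = TRUE))
  pc <- pairwise_covariance(t3)
  expect_equal(pc[1, 2], mean(tc[1, ] * tc[2, ]))
  shared <- c(1, 3, 4)
  expect_equal(pc[1, 3], mean(tc[1, shared] * tc[3, shared]))
  expect_equal(pc, t(pc))
  # an isolated subject errors
  iso <- rbind(c(1, NA, 2), c(NA, 3, NA))
  expect_error(pairwise_covariance(iso), "share no observed")
})

test_that("nearest SPD projection equals the eigen-clipping oracle", {
  # idempotence on an SPD input
  set.seed(6)
  a <- crossprod(matrix(rnorm(36), 6, 6)) + diag(6)
  expect_equal(nearest_spd(a), a, tolerance = 1e-12)
  # [[0,1],[1,0]]: eigenvalues +-1 clip to the rank-1 half matrix (+ eps)
  got <- nearest_spd(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(got, matrix(0.5, 2, 2), tolerance = 1e-8)
  expect_false(inherits(tryCatch(chol(got), error = identity), "error"))
  # random indefinite inputs: Cholesky always succeeds, clipping matches oracle
  for (i in 1:10) {
    m <- matrix(rnorm(25), 5, 5); m <- (m + t(m)) / 2
    out <- nearest_spd(m)
    expect_false(inherits(tryCatch(chol(out), error = identity), "error"))
    e <- eigen(m, symmetric = TRUE)
    eps <- 1e-10 * max(abs(e$values))
    oracle <- e$vectors %*% (pmax(e$values, eps) * t(e$vectors))
    expect_equal(out, (oracle + t(oracle)) / 2, tolerance = 1e-8)
  }
  expect_error(nearest_spd(matrix(c(1, NA, NA, 1), 2, 2)), "finite")
})

test_that("subject-space PCA scores reproduce the eigendecomposition", {
  # rank-1 matrix: a single non-zero component proportional to v
  v <- c(3, -1, 2, 0.5)
  s4 <- tcrossprod(v)
  sc <- pca_scores_from_spd(s4, d = 2)
  expect_equal(abs(cor(sc[, 1], v)), 1)
  expect_lt(max(abs(sc[, 2])), 1e-6)
  # 6 x 6 toy vs dense eigendecomposition oracle (up to column sign)
  set.seed(7)
  s6 <- crossprod(matrix(rnorm(36), 6, 6))
  sc6 <- pca_scores_from_spd(s6, d = 4)
  e <- eigen(s6, symmetric = TRUE)
  for (k in 1:4) {
    oracle <- e$vectors[, k] * sqrt(e$values[k])
    expect_equal(min(max(abs(sc6[, k] - oracle)), max(abs(sc6[, k] + oracle))),
                 0, tolerance = 1e-8)
  }
  expect_error(pca_scores_from_spd(s6, d = 7), "exceeds")
})

test_that("SM selection bookkeeping reproduces the published arithmetic", {
  bk <- sm_bookkeeping(89, 7, 8)
  expect_equal(bk$n_final, 74)
  expect_equal(sm_bookkeeping(10, 0, 0)$n_final, 10)
  # a subject missing 38 of 74 final SMs (> 50%) is flagged
  frac <- c(s1 = 10 / 74, s2 = 38 / 74)
  expect_equal(sm_bookkeeping(89, 7, 8, frac)$flagged_subjects, "s2")
  expect_error(sm_bookkeeping(5, 4, 4), "exclusions")
})

test_that("prepared SM stages satisfy their contracts end to end", {
  co <- simulate_cohort(tiny_spec(seed = 21))
  conf <- build_confounds(co$confounds)
  prep <- prepare_sm(co$sm, conf, d = 6)
  # pathological columns filtered out (the outlier criterion needs n > 100
  # by construction of the max/mean ratio, so it is exercised elsewhere)
  expect_false(any(c("sm_constant", "sm_low_variance", "sm_missing") %in%
                     colnames(prep$S1)))
  # S4 SPD within tolerance, S5 ordered by decreasing variance
  ev <- eigen(prep$S4, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  expect_true(all(diff(apply(prep$S5, 2, var)) < 1e-8))
  # deconfounded columns orthogonal to every confound on observed rows
  for (j in seq_len(ncol(prep$S3))) {
    obs <- !is.na(prep$S3[, j])
    expect_lt(max(abs(crossprod(conf[obs, , drop = FALSE], prep$S3[obs, j]))), 1e-6)
  }
})

test_that("SPD projection barely perturbs the pairwise covariance at 5% missingness", {
  set.seed(8)
  n <- 200; p <- 74
  full <- matrix(rnorm(n * p), n, p)
  miss <- full
  miss[matrix(runif(n * p) < 0.05, n, p)] <- NA
  before <- pairwise_covariance(miss)
  after <- nearest_spd(before)
  # before/after projection correlation stays essentially perfect
  expect_gt(cor(as.vector(before), as.vector(after)), 0.999)
  # and the completed matrix still tracks the full-data covariance closely
  expect_gt(cor(as.vector(after), as.vector(pairwise_covariance(full))), 0.95)
})
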