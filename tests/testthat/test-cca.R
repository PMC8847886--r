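test_that("identical views give perfect canonical correlations", {
  set.seed(1)
  x <- matrix(rnorm(40 * 4), 40, 4)
  fit <- fit_cca(x, x)
  expect_equal(fit$r, rep(1, 4), tolerance = 1e-10)
})

test_that("canonical correlations match the whitened cross-covariance oracle", {
  set.seed(2)
  whiten_oracle <- function(X, Y) {
    X <- scale(X, scale = FALSE); Y <- scale(Y, scale = FALSE)
    isqrt <- function(S) { e <- eigen(S, symmetric = TRUE)
      e$vectors %*% (1 / sqrt(e$values) * t(e$vectors)) }
    K <- isqrt(crossprod(X)) %*% crossprod(X, Y) %*% isqrt(crossprod(Y))
    sort(svd(K)$d, decreasing = TRUE)
  }
  for (i in 1:10) {
    X <- matrix(rnorm(50 * 3), 50, 3)
    Y <- matrix(rnorm(50 * 3), 50, 3)
    fit <- fit_cca(X, Y)
    expect_equal(fit$r, whiten_oracle(X, Y), tolerance = 1e-8)
  }
})

test_that("canonical structure satisfies its invariants", {
  set.seed(3)
  X <- matrix(rnorm(60 * 5), 60, 5)
  Y <- matrix(rnorm(60 * 4), 60, 4)
  fit <- fit_cca(X, Y)
  # r non-increasing in [0, 1]; corr(U_k, V_k) = r_k
  expect_true(all(diff(fit$r) <= 1e-12))
  expect_true(all(fit$r >= 0 & fit$r <= 1))
  expect_equal(diag(cor(fit$U, fit$V)), fit$r, tolerance = 1e-10)
  # variates unit variance and mutually uncorrelated
  expect_equal(apply(fit$U, 2, var), rep(1, 4), tolerance = 1e-10)
  cu <- cor(fit$U); cv <- cor(fit$V)
  expect_lt(max(abs(cu[upper.tri(cu)])), 1e-8)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  # invertible recombination of either view leaves r unchanged
  A3 <- matrix(rnorm(25), 5, 5); B3 <- matrix(rnorm(16), 4, 4)
  fit2 <- fit_cca(X %*% A3, Y %*% B3)
  expect_equal(fit2$r, fit$r, tolerance = 1e-8)
  # identical row permutation of both views leaves r unchanged
  p <- sample(60)
  fit3 <- fit_cca(X[p, ], Y[p, ])
  expect_equal(fit3$r, fit$r, tolerance = 1e-10)
})

test_that("canonical correlations agree with the generalized eigenproblem", {
  set.seed(4)
  X <- matrix(rnorm(30 * 4), 30, 4)
  Y <- matrix(rnorm(30 * 5), 30, 5)
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  Sxx <- crossprod(Xc); Syy <- crossprod(Yc); Sxy <- crossprod(Xc, Yc)
  M <- solve(Sxx, Sxy) %*% solve(Syy, t(Sxy))
  r_oracle <- sqrt(sort(Re(eigen(M)$values), decreasing = TRUE))[1:4]
  expect_equal(fit_cca(X, Y)$r, r_oracle, tolerance = 1e-8)
})

test_that("rank deficiency reduces the mode count with a warning", {
  set.seed(5)
  X <- matrix(rnorm(20 * 3), 20, 3)
  Xdef <- cbind(X, X[, 1] + X[, 2])
  Y <- matrix(rnorm(20 * 4), 20, 4)
  expect_warning(fit <- fit_cca(Xdef, Y), "rank")
  expect_equal(fit$d, 3L)
})

test_that("variance explained follows the weighted squared-correlation formula", {
  set.seed(6)
  w <- matrix(rnorm(30), 30, 1)
  # single column equal to the weight: ve = 1; orthogonal: ve = 0
  expect_equal(mode_variance_explained(w, w), 1, tolerance = 1e-12)
  o <- rep(c(1, -1), 16)
  w0 <- matrix(rep(c(1, 1, -1, -1), 8), 32, 1)
  expect_equal(mode_variance_explained(w0, cbind(o)), 0, tolerance = 1e-12)
  # 3-column toy vs per-column R^2 arithmetic
  X <- matrix(rnorm(90), 30, 3)
  ve <- mode_variance_explained(w, X)
  oracle <- sum(sapply(1:3, function(j) cor(w, X[, j])^2 * var(X[, j]))) /
    sum(apply(X, 2, var))
  expect_equal(ve, oracle, tolerance = 1e-12)
  # missing entries: pairwise-complete rows per column
  Xm <- X; Xm[1:5, 2] <- NA
  vem <- mode_variance_explained(w, Xm)
  r2 <- c(cor(w, X[, 1])^2,
          cor(w[-(1:5)], X[-(1:5), 2])^2,
          cor(w, X[, 3])^2)
  vj <- c(var(X[, 1]), var(X[-(1:5), 2]), var(X[, 3]))
  expect_equal(vem, sum(r2 * vj) / sum(vj), tolerance = 1e-12)
  # total over all modes bounded by 1 for uncorrelated scores
  fit <- fit_cca(matrix(rnorm(200), 50, 4), matrix(rnorm(200), 50, 4))
  expect_lte(sum(mode_variance_explained(fit$U, matrix(rnorm(50 * 6), 50, 6))),
             1 + 1e-6)
})

test_that("replication criteria are evaluated as pre-registered", {
  vp <- tibble::tibble(
    mode = 1:3,
    r = c(0.5, 0.4, 0.3), p_fwe = c(0.0005, 0.2, 0.5),
    ve_conn = c(0.02, 0.005, 0.004), z_conn = c(8, 3, 0.4),
    p5_conn = rep(0.001, 3), p95_conn = rep(0.01, 3),
    ve_sm = c(0.06, 0.01, 0.02), z_sm = c(8.56, 3.64, 1),
    p5_sm = rep(0.005, 3), p95_sm = rep(0.03, 3)
  )
  rep1 <- evaluate_replication_criteria(vp)
  expect_equal(rep1$primary_mode, 1L)
  expect_true(rep1$criterion1)
  # SM z-ratio 8.56 / 3.64 = 2.35 < factor 3: criterion 2 fails
  expect_equal(rep1$z_ratio_sm, 8.56 / 3.64, tolerance = 1e-12)
  expect_false(rep1$criterion2)
  expect_true(rep1$criterion3)                 # p = 0.0005 < 0.001
  # criterion 3 threshold is strict at 0.001
  vp2 <- vp; vp2$p_fwe[1] <- 0.002
  expect_false(evaluate_replication_criteria(vp2)$criterion3)
  # a clean single-mode profile passes everything
  vp3 <- vp; vp3$z_sm <- c(9, 0.5, 0.2); vp3$z_conn <- c(9, 0.5, 0.2)
  vp3$ve_conn <- c(0.02, 0.001, 0.001); vp3$ve_sm <- c(0.06, 0.001, 0.001)
  rep3 <- evaluate_replication_criteria(vp3)
  expect_true(rep3$criterion1 && rep3$criterion2 && rep3$criterion3)
  # no mode significant in both views: no primary mode
  vp4 <- vp; vp4$ve_conn <- rep(0.0001, 3)
  expect_equal(evaluate_replication_criteria(vp4)$note, "no primary mode")
})

test_that("tidy and glance summarize a fit", {
  set.seed(7)
  fit <- fit_cca(matrix(rnorm(120), 40, 3), matrix(rnorm(120), 40, 3))
  td <- tidy(fit)
  expect_equal(td$mode, 1:3)
  expect_equal(td$r, fit$r)
  gl <- glance(fit)
  expect_equal(gl$n, 40L)
  expect_equal(gl$r_first, fit$r[1])
})
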