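# Helpers building small functional samples in code.

dense_sample <- function(n, grid, curve_fun, noise = 0, seed = 1) {
  set.seed(seed)
  ids <- sprintf("D%03d", seq_len(n))
  long <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(id = ids[i], s = grid,
               y = curve_fun(i, grid) + rnorm(length(grid), 0, noise))
  }))
  sparse_curves(long$id, long$s, long$y)
}

test_that("mean estimation reproduces constants and smooth truths", {
  g <- seq(0, 1, length.out = 21)
  sc <- dense_sample(5, g, function(i, s) rep(3.5, length(s)))
  mf <- estimate_mean(sc, bandwidth = 0.2)
  expect_equal(mf$mu, rep(3.5, length(mf$grid)), tolerance = 1e-10)

  # known truth + iid noise, pooled over many subjects
  truth <- function(s) 1 + sin(2 * pi * s) / 2
  sc2 <- dense_sample(200, g, function(i, s) truth(s), noise = 0.2, seed = 2)
  mf2 <- estimate_mean(sc2, bandwidth = 0.1)
  expect_lt(max(abs(mf2$mu - truth(mf2$grid))), 0.05)
  expect_error(estimate_mean(sparse_curves(c("a", "a"), c(0, 1), c(1, 2))),
               "at least 10")
})

test_that("covariance smoothing recovers rank-1 structure and noise level", {
  g <- seq(0, 1, length.out = 26)
  phi <- sqrt(2) * sin(pi * g)
  lam <- 0.6
  set.seed(3)
  xi <- as.numeric(scale(rnorm(150))) * sqrt(lam)  # exact score variance
  sc <- dense_sample(150, g, function(i, s) {
    2 + xi[i] * sqrt(2) * sin(pi * s)
  }, seed = 3)
  mf <- estimate_mean(sc, grid = g, bandwidth = 0.1)
  cf <- estimate_covariance(sc, mf, bandwidth = 0.1)
  expect_identical(cf$G, t(cf$G))                     # symmetric exactly
  expect_lt(cf$sigma2, 0.03)                          # no noise injected
  G_true <- lam * outer(phi, phi)
  # only the O(h^2) kernel attenuation of the surface peak remains
  expect_lt(max(abs(cf$G - G_true)), 0.05)

  # pure iid noise around a flat mean
  sc_n <- dense_sample(150, g, function(i, s) rep(0, length(s)),
                       noise = 0.3, seed = 4)
  mf_n <- estimate_mean(sc_n, grid = g, bandwidth = 0.2)
  cf_n <- estimate_covariance(sc_n, mf_n, bandwidth = 0.2)
  expect_lt(max(abs(cf_n$G)), 0.03)
  expect_equal(cf_n$sigma2, 0.09, tolerance = 0.3)    # sigma^2 = 0.3^2

  # all subjects singly observed: covariance inestimable
  one <- sparse_curves(letters[1:12], runif(12), rnorm(12))
  mf1 <- estimate_mean(one, bandwidth = 0.5)
  expect_error(estimate_covariance(one, mf1), "inestimable")
})

test_that("eigendecomposition recovers constructed eigenpairs", {
  g <- seq(0, 1, length.out = 41)
  w <- funspi:::quad_weights(g)
  phi1 <- rep(1, 41)
  phi2 <- sqrt(3) * (2 * g - 1)
  G <- 0.7 * outer(phi1, phi1) + 0.2 * outer(phi2, phi2)
  eg <- eigendecompose(G, g)
  # quadrature-level agreement (trapezoid error on the quadratic phi2)
  expect_equal(eg$lambda[1:2], c(0.7, 0.2), tolerance = 5e-3)
  expect_length(eg$lambda, 2L)                        # rank 2 after truncation
  # orthonormality in the quadrature metric
  M <- t(eg$phi[, 1:2]) %*% (eg$phi[, 1:2] * w)
  expect_lt(max(abs(M - diag(2))), 1e-6)
  # sign convention: positive integral, or positive leading coordinate
  # when the integral vanishes (phi2 is antisymmetric)
  expect_gt(sum(eg$phi[, 1] * w), 0)
  expect_gt(eg$phi[1, 2], 0)
  expect_error(eigendecompose(matrix(NA_real_, 2, 2), c(0, 1)), "non-finite")
})

test_that("FVE rule selects the smallest sufficient component count", {
  expect_equal(select_n_components(c(0.9, 0.1)), 2L)
  expect_equal(select_n_components(c(0.95, 0.05)), 1L)
  expect_equal(select_n_components(c(0.80, 0.13, 0.07)), 2L)
  expect_equal(select_n_components(c(1, 0), threshold = 1), 1L)
  expect_error(select_n_components(c(0, 0)), "zero")
  expect_error(select_n_components(c(0.1, 0.9)), "non-increasing")
})

test_that("conditional-expectation scores are linear, centered and shrinking", {
  co <- simulate_fpca_cohort(150, seed = 10)
  fp <- suppressWarnings(fit_fpca(co$sample, bandwidth_mean = 0.1,
                                  bandwidth_cov = 0.15))

  # a subject lying exactly on the mean gets zero scores
  on_mean <- sparse_curves(rep("m", 21), seq(0.1, 0.9, length.out = 21),
                           approx(fp$grid, fp$mu,
                                  seq(0.1, 0.9, length.out = 21))$y)
  expect_equal(unname(estimate_scores_conditional(on_mean, fp)[1, ]),
               rep(0, ncol(fp$scores)), tolerance = 1e-10)

  # linearity in the observation vector (superposition)
  s0 <- seq(0.05, 0.95, length.out = 15)
  mu0 <- approx(fp$grid, fp$mu, s0)$y
  r1 <- rnorm(15); r2 <- rnorm(15)
  sc_of <- function(r) estimate_scores_conditional(
    sparse_curves(rep("x", 15), s0, mu0 + r), fp)[1, ]
  expect_equal(sc_of(2 * r1 + 3 * r2), 2 * sc_of(r1) + 3 * sc_of(r2),
               tolerance = 1e-8)

  # scores vanish as the noise variance grows
  fp_noisy <- fp
  fp_noisy$sigma2 <- 1e6
  big <- estimate_scores_conditional(sparse_curves(rep("x", 15), s0, mu0 + r1),
                                     fp_noisy)
  expect_lt(max(abs(big)), 1e-3)
})

test_that("sparse FPCA recovers a known two-component model", {
  co <- simulate_fpca_cohort(200, lambda = c(0.8, 0.15), seed = 6)
  fp <- suppressWarnings(fit_fpca(co$sample, bandwidth_mean = 0.1,
                                  bandwidth_cov = 0.15))
  expect_equal(fp$L, 2L)
  expect_lt(abs(fp$lambda[1] - 0.8) / 0.8, 0.15)
  expect_lt(abs(fp$lambda[2] - 0.15) / 0.15, 0.15)
  w <- funspi:::quad_weights(fp$grid)
  a1 <- abs(sum(fp$phi[, 1] * co$phi_funs[[1]](fp$grid) * w))
  a2 <- abs(sum(fp$phi[, 2] * co$phi_funs[[2]](fp$grid) * w))
  expect_gt(a1, 0.95)
  expect_gt(a2, 0.95)
  # estimated scores track the generating scores
  expect_gt(abs(cor(fp$scores[, 1], co$scores[, 1])), 0.95)
  expect_gt(abs(cor(fp$scores[, 2], co$scores[, 2])), 0.8)
})

test_that("dense regular grids reduce to weighted matrix PCA", {
  set.seed(3)
  n <- 300; M <- 51
  g <- seq(0, 1, length.out = M)
  phi1 <- rep(1, M); phi2 <- sqrt(3) * (2 * g - 1)
  mu <- 1 + sin(2 * pi * g) / 3
  xi <- matrix(rnorm(2 * n), n, 2)
  xi <- scale(xi); xi <- qr.Q(qr(xi)) * sqrt(n - 1)
  xi <- sweep(xi, 2, sqrt(c(0.8, 0.15)), "*")
  Y <- matrix(mu, n, M, byrow = TRUE) + xi[, 1] %o% phi1 + xi[, 2] %o% phi2
  sc <- sparse_curves(rep(sprintf("S%03d", 1:n), each = M), rep(g, n),
                      as.vector(t(Y)))
  h <- 1.2 * (g[2] - g[1])
  fp <- suppressWarnings(fit_fpca(sc, grid = g, bandwidth_mean = h,
                                  bandwidth_cov = h))
  # oracle: eigenpairs of the empirical covariance with quadrature weights
  C <- stats::cov(Y) * (n - 1) / n
  w <- funspi:::quad_weights(g); sw <- sqrt(w)
  A <- t(C * sw) * sw
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  lam_or <- e$values[1:2]
  phi_or <- e$vectors[, 1:2] / sw
  expect_lt(max(abs(fp$lambda[1:2] - lam_or) / lam_or), 0.01)
  al <- abs(c(sum(fp$phi[, 1] * phi_or[, 1] * w),
              sum(fp$phi[, 2] * phi_or[, 2] * w)))
  expect_gt(min(al), 0.99)
})

test_that("reconstruction error is non-increasing in L (projection limit)", {
  # In the dense noiseless limit the conditional-expectation scores reduce
  # to least-squares projections, where truncation error is monotone.
  set.seed(8)
  n <- 80; g <- seq(0, 1, length.out = 31)
  xi <- cbind(rnorm(n, 0, 0.9), rnorm(n, 0, 0.4), rnorm(n, 0, 0.2))
  B <- cbind(rep(1, 31), sqrt(3) * (2 * g - 1), sqrt(2) * sin(2 * pi * g))
  Y <- xi %*% t(B) + 2
  sc <- sparse_curves(rep(sprintf("D%02d", 1:n), each = 31), rep(g, n),
                      as.vector(t(Y)))
  h <- 1.2 * (g[2] - g[1])
  fp <- suppressWarnings(fit_fpca(sc, grid = g, bandwidth_mean = h,
                                  bandwidth_cov = h))
  errs <- vapply(seq_len(min(4, ncol(fp$scores))), function(L) {
    rc <- reconstruct_curves(fp, sc, L = L)
    sum((rc$y - rc$fitted)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("the fitted model is invariant to subject order", {
  co <- simulate_fpca_cohort(60, seed = 13)
  sc <- co$sample
  set.seed(1)
  perm <- sample(unique(sc$id))
  idx <- order(match(sc$id, perm))
  sc2 <- sparse_curves(sc$id[idx], sc$s[idx], sc$y[idx])
  fp1 <- suppressWarnings(fit_fpca(sc, bandwidth_mean = 0.1, bandwidth_cov = 0.15))
  fp2 <- suppressWarnings(fit_fpca(sc2, bandwidth_mean = 0.1, bandwidth_cov = 0.15))
  expect_equal(fp1$mu, fp2$mu, tolerance = 1e-10)
  expect_equal(fp1$lambda, fp2$lambda, tolerance = 1e-8)
  expect_equal(fp1$scores[rownames(fp1$scores), ],
               fp2$scores[rownames(fp1$scores), ], tolerance = 1e-8)
})
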