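#' Sparse functional sample
#'
#' Long-format container for irregularly observed curves: per subject `i`,
#' observation abscissae \eqn{S_{ik}} (here, distance-bin midpoints in
#' microns) and values \eqn{SPI_{ik}}.  Missing bins are simply absent —
#' never zero-filled — which is what makes the sample "sparse".
#'
#' @param id subject identifiers (coercible to character).
#' @param s numeric abscissae.
#' @param y numeric observed values.
#' @return An object of class `sparse_curves`: data frame with columns
#'   `id`, `s`, `y`, ordered by subject then abscissa.
#' @export
sparse_curves <- function(id, s, y) {
  id <- as.character(id)
  s <- as.numeric(s)
  y <- as.numeric(y)
  stopifnot(length(id) == length(s), length(s) == length(y))
  keep <- is.finite(s) & is.finite(y)
  df <- data.frame(id = id[keep], s = s[keep], y = y[keep])
  if (nrow(df) == 0L) stop("no finite observations")
  df <- df[order(match(df$id, unique(df$id)), df$s), ]
  rownames(df) <- NULL
  structure(df, class = c("sparse_curves", "data.frame"))
}

#' Convert a list of SPI curves to a sparse functional sample
#'
#' Takes per-subject [spi_curve()] objects and pools their defined
#' (non-missing) per-bin SPI values at the bin midpoints.
#'
#' @param curves list of `spi_curve` objects, or a long data frame with
#'   columns `subject_id`, `midpoint`, `spi`.
#' @return A [sparse_curves()] object.
#' @export
curves_to_sample <- function(curves) {
  if (is.data.frame(curves))
    return(sparse_curves(curves$subject_id, curves$midpoint, curves$spi))
  ids <- vapply(curves, function(cv) attr(cv, "subject_id"), character(1))
  sparse_curves(
    id = rep(ids, vapply(curves, nrow, integer(1))),
    s = unlist(lapply(curves, `[[`, "midpoint"), use.names = FALSE),
    y = unlist(lapply(curves, `[[`, "spi"), use.names = FALSE))
}

default_grid <- function(sample, n_grid = 51L) {
  seq(min(sample$s), max(sample$s), length.out = n_grid)
}

#' Mean function of a sparse functional sample
#'
#' Local-linear (Epanechnikov) smoother of the pooled observations
#' \eqn{(S_{ik}, SPI_{ik})} over all subjects, evaluated on a working grid.
#'
#' @param sample a [sparse_curves()] object.
#' @param grid numeric evaluation grid (defaults to 51 equally spaced points
#'   on the pooled abscissa range).
#' @param bandwidth positive numeric, or `"auto"` for generalized
#'   cross-validation over a geometric candidate grid.
#' @return List with `grid`, `mu` (mean values on the grid) and `bandwidth`.
#' @export
estimate_mean <- function(sample, grid = NULL, bandwidth = "auto") {
  stopifnot(inherits(sample, "sparse_curves"))
  if (nrow(sample) < 10L) stop("need at least 10 pooled observations")
  if (is.null(grid)) grid <- default_grid(sample)
  # subject-uniform weighting: each curve contributes equal total weight
  w <- 1 / ave(sample$s, sample$id, FUN = length)
  h <- if (identical(bandwidth, "auto"))
    gcv_bandwidth_1d(sample$s, sample$y, grid, w = w) else as.numeric(bandwidth)
  mu <- lwls1d(sample$s, sample$y, grid, h, w = w)
  list(grid = grid, mu = mu, bandwidth = h)
}

# Raw covariance cross-products (j != l) pooled over subjects.  Each
# subject receives equal total weight (1/{K_i(K_i-1)} per cross-product,
# 1/K_i per diagonal point): with observation-count weighting a subject
# observed at 50 bins would carry ~100x the weight of one observed at 5,
# and the covariance would estimate a count-weighted score variance.
raw_covariances <- function(sample, grid, mu) {
  resid <- sample$y - stats::approx(grid, mu, xout = sample$s, rule = 2)$y
  parts <- split(data.frame(s = sample$s, e = resid), sample$id)
  s1 <- s2 <- v <- w <- vector("list", length(parts))
  ds <- de <- dw <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    si <- parts[[i]]$s; ei <- parts[[i]]$e
    k <- length(si)
    ds[[i]] <- si
    de[[i]] <- ei^2
    dw[[i]] <- rep(1 / k, k)
    if (k >= 2L) {
      off <- which(row(diag(k)) != col(diag(k)))
      s1[[i]] <- rep(si, each = k)[off]
      s2[[i]] <- rep(si, times = k)[off]
      v[[i]] <- as.vector(outer(ei, ei))[off]
      w[[i]] <- rep(1 / (k * (k - 1)), k * (k - 1))
    }
  }
  list(s1 = unlist(s1), s2 = unlist(s2), v = unlist(v), w = unlist(w),
       diag_s = unlist(ds), diag_v = unlist(de), diag_w = unlist(dw))
}

#' Covariance surface and noise variance of a sparse functional sample
#'
#' Smooths the pooled raw covariances
#' \eqn{(SPI_{ij} - \hat\mu(S_{ij}))(SPI_{il} - \hat\mu(S_{il}))}, `j != l`,
#' with a 2D local-linear smoother onto `grid x grid`.  Same-point products
#' (`j == l`) are excluded because they carry the measurement-error variance
#' \eqn{\sigma^2}; that variance is then recovered as the average positive
#' gap, over the central 80% of the grid, between the smoothed diagonal of
#' raw second moments and the diagonal of the smoothed covariance surface
#' (floored at 0).
#'
#' @inheritParams estimate_mean
#' @param mean_fit result of [estimate_mean()] (supplies `grid` and `mu`).
#' @return List with `G` (symmetric covariance matrix on the grid),
#'   `sigma2`, `bandwidth`.
#' @export
estimate_covariance <- function(sample, mean_fit, bandwidth = "auto") {
  stopifnot(inherits(sample, "sparse_curves"))
  grid <- mean_fit$grid
  raw <- raw_covariances(sample, grid, mean_fit$mu)
  if (length(raw$v) == 0L)
    stop("covariance inestimable: every subject has a single observation")
  cells <- bin_raw_cov(raw$s1, raw$s2, raw$v, grid, w = raw$w)
  h <- if (identical(bandwidth, "auto"))
    gcv_bandwidth_2d(cells, grid) else as.numeric(bandwidth)
  G <- lwls2d(cells, grid, h)
  G <- (G + t(G)) / 2
  # noise variance from the diagonal gap
  hd <- max(h, mean_fit$bandwidth)
  V <- suppressWarnings(lwls1d(raw$diag_s, raw$diag_v, grid, hd, w = raw$diag_w))
  M <- length(grid)
  core <- seq(from = ceiling(M * 0.1), to = floor(M * 0.9))
  sigma2 <- max(0, mean((V - diag(G))[core]))
  list(G = G, sigma2 = sigma2, bandwidth = h, diag_raw = V)
}

#' Eigendecomposition of a covariance surface
#'
#' Solves the discretized eigenproblem with trapezoid quadrature weights,
#' truncates negative eigenvalues, normalizes eigenfunctions to unit L2 norm
#' on the grid, and fixes signs so that each eigenfunction has positive
#' integral (first non-negligible coordinate positive when the integral is
#' zero).
#'
#' @param G symmetric covariance matrix evaluated on `grid`.
#' @param grid numeric grid.
#' @return List with `lambda` (positive, non-increasing), `phi`
#'   (`length(grid) x L` matrix, orthonormal in the quadrature metric) and
#'   `fve` (fraction of variance explained per component).
#' @export
eigendecompose <- function(G, grid) {
  if (any(!is.finite(G))) stop("covariance surface contains non-finite entries")
  M <- length(grid)
  stopifnot(nrow(G) == M, ncol(G) == M)
  w <- quad_weights(grid)
  sw <- sqrt(w)
  A <- t(G * sw) * sw          # diag(sw) %*% G %*% diag(sw)
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-12 & e$values > 0
  lambda <- e$values[keep]
  phi <- e$vectors[, keep, drop = FALSE] / sw
  for (l in seq_along(lambda)) {
    s <- sum(phi[, l] * w)
    if (abs(s) < 1e-10) {
      nz <- which(abs(phi[, l]) > 1e-8)[1L]
      s <- phi[nz, l]
    }
    if (s < 0) phi[, l] <- -phi[, l]
  }
  list(lambda = lambda, phi = phi, fve = lambda / sum(lambda))
}

quad_weights <- function(grid) {
  M <- length(grid)
  if (M == 1L) return(1)
  d <- diff(grid)
  c(d[1L] / 2, (d[-(M - 1L)] + d[-1L]) / 2, d[M - 1L] / 2)
}

#' Number of components for a target fraction of variance explained
#'
#' Smallest `L` such that the leading `L` eigenvalues account for at least
#' `threshold` of the total (default 92%).
#'
#' @param lambda non-increasing, non-negative eigenvalues.
#' @param threshold FVE threshold in (0, 1].
#' @return Integer `L`.
#' @examples
#' select_n_components(c(0.80, 0.13, 0.07))  # 2
#' @export
select_n_components <- function(lambda, threshold = 0.92) {
  lambda <- as.numeric(lambda)
  if (length(lambda) == 0L || sum(lambda) <= 0) stop("all eigenvalues are zero")
  if (is.unsorted(rev(lambda))) stop("eigenvalues must be non-increasing")
  cum <- cumsum(lambda) / sum(lambda)
  as.integer(which(cum >= threshold - 1e-12)[1L])
}

#' Conditional-expectation (PACE) scores
#'
#' Best linear prediction of the component scores given a subject's sparse
#' observations:
#' \deqn{\hat\xi_{il} = \hat\lambda_l \hat\phi_{il}^T \hat\Sigma_i^{-1}
#'       (SPI_i - \hat\mu_i)},
#' with \eqn{\hat\Sigma_i = \hat G(S_{ij}, S_{il}) + \hat\sigma^2
#' \delta_{jl}} evaluated at the subject's abscissae.  Solved as a linear
#' system; a tiny ridge (1e-8 of the trace) is added with a warning if the
#' system is numerically singular.  Scores shrink toward 0 as
#' \eqn{\hat\sigma^2} grows.
#'
#' @param sample a [sparse_curves()] object.
#' @param model an `fpca_model` from [fit_fpca()] (or a list with `grid`,
#'   `mu`, `G`, `sigma2`, `lambda`, `phi`).
#' @param L number of leading components to score (default: all retained in
#'   the model).
#' @return Numeric matrix, one row per subject (named), one column per
#'   component.
#' @export
estimate_scores_conditional <- function(sample, model, L = NULL) {
  stopifnot(inherits(sample, "sparse_curves"))
  if (is.null(L)) L <- ncol(model$phi)
  L <- min(L, ncol(model$phi))
  grid <- model$grid
  ids <- unique(sample$id)
  out <- matrix(0, length(ids), L, dimnames = list(ids, paste0("xi", seq_len(L))))
  parts <- split(data.frame(s = sample$s, y = sample$y), sample$id)[ids]
  warned <- FALSE
  for (i in seq_along(ids)) {
    si <- parts[[i]]$s
    ri <- parts[[i]]$y - stats::approx(grid, model$mu, xout = si, rule = 2)$y
    k <- length(si)
    Gi <- matrix(interp_bilinear(grid, model$G,
                                 rep(si, each = k), rep(si, times = k)), k, k)
    Gi <- (Gi + t(Gi)) / 2
    Sigma <- Gi + diag(model$sigma2, k)
    phii <- vapply(seq_len(L),
                   function(l) stats::approx(grid, model$phi[, l], xout = si,
                                             rule = 2)$y,
                   numeric(k))
    phii <- matrix(phii, nrow = k)
    z <- tryCatch(solve(Sigma, ri), error = function(e) NULL)
    if (is.null(z)) {
      Sigma <- Sigma + diag(1e-8 * sum(diag(Sigma)), k)
      z <- solve(Sigma, ri)
      warned <- TRUE
    }
    out[i, ] <- model$lambda[seq_len(L)] * as.numeric(crossprod(phii, z))
  }
  if (warned) warning("near-singular within-subject covariance; ridge applied")
  out
}

#' Sparse functional principal component analysis
#'
#' PACE-style FPCA for irregularly observed curves: local-linear mean and
#' covariance smoothing on a working grid, eigendecomposition with
#' quadrature weights, component count by the fraction-of-variance-explained
#' rule, and conditional-expectation scores.  Deterministic given inputs
#' and settings.
#'
#' @param sample a [sparse_curves()] object.
#' @param n_grid size of the working grid (51 by default, matching the cap
#'   of 50 distance ranges).
#' @param grid explicit working grid (overrides `n_grid`).
#' @param fve fraction-of-variance-explained threshold selecting the number
#'   of components `L` (default 0.92).
#' @param bandwidth_mean,bandwidth_cov positive numerics or `"auto"` (GCV).
#' @param max_components cap on retained components (default 20).
#' @return An object of class `fpca_model`: list with `grid`, `mu`, `G`,
#'   `sigma2`, `lambda`, `phi`, `fve`, `cum_fve`, `L`, `scores` (all
#'   retained components; the first `L` are the selected ones),
#'   `bandwidths`, `n_subjects`.
#' @export
fit_fpca <- function(sample, n_grid = 51L, grid = NULL, fve = 0.92,
                     bandwidth_mean = "auto", bandwidth_cov = "auto",
                     max_components = 20L) {
  stopifnot(inherits(sample, "sparse_curves"))
  if (is.null(grid)) grid <- default_grid(sample, n_grid)
  mf <- estimate_mean(sample, grid = grid, bandwidth = bandwidth_mean)
  cf <- estimate_covariance(sample, mf, bandwidth = bandwidth_cov)
  eg <- eigendecompose(cf$G, grid)
  n_keep <- min(length(eg$lambda), max_components)
  lambda <- eg$lambda[seq_len(n_keep)]
  phi <- eg$phi[, seq_len(n_keep), drop = FALSE]
  L <- select_n_components(eg$lambda, threshold = fve)
  L <- min(L, n_keep)
  model <- structure(
    list(grid = grid, mu = mf$mu, G = cf$G, sigma2 = cf$sigma2,
         lambda = lambda, phi = phi,
         fve = eg$fve[seq_len(n_keep)],
         cum_fve = cumsum(eg$fve)[seq_len(n_keep)],
         L = L,
         bandwidths = c(mean = mf$bandwidth, cov = cf$bandwidth),
         n_subjects = length(unique(sample$id))),
    class = "fpca_model")
  model$scores <- estimate_scores_conditional(sample, model)
  model
}

#' @export
print.fpca_model <- function(x, ...) {
  cat("<fpca_model>", x$n_subjects, "subjects, grid of", length(x$grid),
      "points\n  sigma^2 =", format(x$sigma2, digits = 4),
      "; L =", x$L, "components at",
      paste0(format(100 * x$cum_fve[x$L], digits = 3), "% FVE"), "\n")
  cat("  eigenvalues:", paste(format(x$lambda[seq_len(min(5, length(x$lambda)))],
                                     digits = 3), collapse = ", "),
      if (length(x$lambda) > 5) "...", "\n")
  invisible(x)
}

#' Reconstruct fitted curves at observed abscissae
#'
#' \eqn{\hat X_i(s) = \hat\mu(s) + \sum_{l \le L} \hat\xi_{il}
#' \hat\phi_l(s)} evaluated at each subject's own abscissae.
#'
#' @param model an `fpca_model`.
#' @param sample the [sparse_curves()] the model was fitted to.
#' @param L number of components used in the truncation.
#' @return Data frame `id`, `s`, `y`, `fitted`.
#' @export
reconstruct_curves <- function(model, sample, L = model$L) {
  L <- min(L, ncol(model$scores))
  mu_i <- stats::approx(model$grid, model$mu, xout = sample$s, rule = 2)$y
  fit <- mu_i
  for (l in seq_len(L)) {
    phil <- stats::approx(model$grid, model$phi[, l], xout = sample$s, rule = 2)$y
    fit <- fit + model$scores[sample$id, l] * phil
  }
  data.frame(id = sample$id, s = sample$s, y = sample$y, fitted = fit)
}
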