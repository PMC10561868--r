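# Local-linear kernel smoothers (Epanechnikov) used by the sparse-FPCA
# machinery: 1D for the mean and the diagonal of raw second moments, 2D for
# the covariance surface.  The 2D smoother operates on bin-aggregated raw
# covariances (cell means with counts as weights), which is exact when
# observations share a grid and a standard fast approximation otherwise.

epan <- function(u) ifelse(abs(u) < 1, 0.75 * (1 - u^2), 0)

# Local linear fit of y on x at each point of xout.  w are per-point
# weights (e.g. bin counts).  If a target point has insufficient support the
# bandwidth is widened locally (x1.5, up to 10 times) with a warning; an
# error is raised if support is still empty.
lwls1d <- function(x, y, xout, h, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  stopifnot(length(x) == length(y), length(x) == length(w), h > 0)
  fit_at <- function(x0, h0) {
    for (it in 1:10) {
      u <- (x - x0) / h0
      kw <- epan(u) * w
      use <- kw > 0
      if (sum(use) >= 2L && length(unique(x[use])) >= 2L) {
        dx <- x[use] - x0
        kw <- kw[use]
        S0 <- sum(kw); S1 <- sum(kw * dx); S2 <- sum(kw * dx^2)
        den <- S0 * S2 - S1^2
        if (den > 1e-12 * S0 * max(S2, .Machine$double.eps)) {
          T0 <- sum(kw * y[use]); T1 <- sum(kw * dx * y[use])
          return(list(v = (S2 * T0 - S1 * T1) / den, h = h0))
        }
      }
      h0 <- h0 * 1.5
    }
    if (!any(epan((x - x0) / h0) * w > 0))
      stop("no data within bandwidth at x = ", format(x0), " even after widening")
    # fall back to local constant
    kw <- epan((x - x0) / h0) * w
    list(v = sum(kw * y) / sum(kw), h = h0)
  }
  widened <- FALSE
  out <- numeric(length(xout))
  for (g in seq_along(xout)) {
    f <- fit_at(xout[g], h)
    if (f$h > h) widened <- TRUE
    out[g] <- f$v
  }
  if (widened)
    warning("bandwidth widened locally to cover sparse regions")
  out
}

# GCV bandwidth selection for lwls1d over a geometric candidate grid.
# Fitted values at data points are obtained by linear interpolation of the
# fit on a working grid (binned evaluation).
gcv_bandwidth_1d <- function(x, y, grid, w = NULL, n_cand = 10L) {
  if (is.null(w)) w <- rep(1, length(x))
  r <- diff(range(x))
  if (r <= 0) stop("degenerate abscissa range")
  # minimal bandwidth: every grid point must see >= 2 distinct x
  xs <- sort(unique(x))
  gaps <- max(diff(xs))
  h_min <- max(gaps, r / 50, 1e-8 * r)
  h_max <- r / 2
  if (h_min >= h_max) return(h_max)
  hs <- exp(seq(log(h_min), log(h_max), length.out = n_cand))
  k0 <- 0.75  # Epanechnikov at 0
  n <- sum(w)
  best_h <- hs[length(hs)]
  best <- Inf
  for (h in hs) {
    mu <- try(suppressWarnings(lwls1d(x, y, grid, h, w)), silent = TRUE)
    if (inherits(mu, "try-error") || any(!is.finite(mu))) next
    yhat <- stats::approx(grid, mu, xout = x, rule = 2)$y
    rss <- sum(w * (y - yhat)^2)
    shrink <- 1 - r * k0 / (n * h)
    if (shrink <= 0) next
    gcv <- rss / shrink^2
    if (is.finite(gcv) && gcv < best) { best <- gcv; best_h <- h }
  }
  best_h
}

# Aggregate raw covariance points (s1, s2, v) into cells of grid x grid:
# returns cell centers, mean value and count for non-empty cells.
bin_raw_cov <- function(s1, s2, v, grid, w = NULL) {
  if (is.null(w)) w <- rep(1, length(v))
  i1 <- nearest_index(s1, grid)
  i2 <- nearest_index(s2, grid)
  id <- (i1 - 1L) * length(grid) + i2
  sums <- rowsum(v * w, id)
  cnts <- rowsum(w, id)
  ids <- as.integer(rownames(sums))
  g1 <- grid[(ids - 1L) %/% length(grid) + 1L]
  g2 <- grid[(ids - 1L) %% length(grid) + 1L]
  list(s1 = g1, s2 = g2, m = as.numeric(sums / cnts), w = as.numeric(cnts))
}

nearest_index <- function(x, grid) {
  i <- findInterval(x, grid, all.inside = TRUE)
  ifelse(x - grid[i] > grid[i + 1L] - x, i + 1L, i)
}

# Local-linear (plane) smoother of binned raw covariances onto grid x grid.
# Only the upper triangle is computed; the result is symmetric by
# construction.
lwls2d <- function(cells, grid, h) {
  M <- length(grid)
  G <- matrix(NA_real_, M, M)
  s1 <- cells$s1; s2 <- cells$s2; m <- cells$m; w <- cells$w
  for (a in seq_len(M)) {
    ga <- grid[a]
    u1 <- (s1 - ga) / h
    k1 <- epan(u1)
    sel1 <- k1 > 0
    for (b in a:M) {
      gb <- grid[b]
      h2 <- h
      for (it in 1:10) {
        if (it == 1L && h2 == h) {
          kw <- k1
          sel <- sel1
        } else {
          kw <- epan((s1 - ga) / h2)
          sel <- kw > 0
        }
        kk <- kw * epan((s2 - gb) / h2) * w
        use <- kk > 0
        if (sum(use) >= 4L) {
          # local bilinear basis (1, ds, dt, ds*dt): the cross term removes
          # the boundary attenuation a plane fit inflicts on product-form
          # covariance components
          ds <- s1[use] - ga; dt <- s2[use] - gb; kk <- kk[use]
          X <- cbind(1, ds, dt, ds * dt)
          A <- crossprod(X, X * kk)
          bvec <- crossprod(X, kk * m[use])
          fit <- tryCatch(solve(A, bvec), error = function(e) NULL)
          if (!is.null(fit) && is.finite(fit[1L])) {
            G[a, b] <- fit[1L]
            G[b, a] <- fit[1L]
            break
          }
        }
        h2 <- h2 * 1.5
      }
      if (is.na(G[a, b])) {
        # local-constant fallback over the widened window
        kk <- epan((s1 - ga) / h2) * epan((s2 - gb) / h2) * w
        if (!any(kk > 0))
          stop("no covariance data near grid point (", format(ga), ", ",
               format(gb), ")")
        G[a, b] <- sum(kk * m) / sum(kk)
        G[b, a] <- G[a, b]
      }
    }
  }
  G
}

# GCV over a small geometric candidate grid for the 2D smoother.
gcv_bandwidth_2d <- function(cells, grid, n_cand = 5L) {
  r <- diff(range(grid))
  dg <- r / (length(grid) - 1L)
  h_min <- 1.5 * dg
  h_max <- r / 3
  if (h_min >= h_max) return(h_max)
  hs <- exp(seq(log(h_min), log(h_max), length.out = n_cand))
  k0 <- 0.75
  # penalize by the number of distinct design cells: they, not the raw
  # points piled onto them, limit how fine a surface feature is resolvable
  Mw <- length(cells$m)
  best_h <- hs[length(hs)]
  best <- Inf
  for (h in hs) {
    G <- try(lwls2d(cells, grid, h), silent = TRUE)
    if (inherits(G, "try-error")) next
    vhat <- interp_bilinear(grid, G, cells$s1, cells$s2)
    rss <- sum(cells$w * (cells$m - vhat)^2)
    shrink <- 1 - (r * k0 / h)^2 / Mw
    if (shrink <= 0) next
    gcv <- rss / shrink^2
    if (is.finite(gcv) && gcv < best) { best <- gcv; best_h <- h }
  }
  best_h
}

# Bilinear interpolation of a grid surface at arbitrary points (clamped to
# the grid range).
interp_bilinear <- function(grid, G, x1, x2) {
  M <- length(grid)
  x1 <- pmin(pmax(x1, grid[1L]), grid[M])
  x2 <- pmin(pmax(x2, grid[1L]), grid[M])
  i <- pmin(findInterval(x1, grid), M - 1L)
  j <- pmin(findInterval(x2, grid), M - 1L)
  tx <- (x1 - grid[i]) / (grid[i + 1L] - grid[i])
  ty <- (x2 - grid[j]) / (grid[j + 1L] - grid[j])
  G[cbind(i, j)] * (1 - tx) * (1 - ty) +
    G[cbind(i + 1L, j)] * tx * (1 - ty) +
    G[cbind(i, j + 1L)] * (1 - tx) * ty +
    G[cbind(i + 1L, j + 1L)] * tx * ty
}
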