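#' Per-range residual entropy
#'
#' For each distance range \eqn{w_k}, the Shannon entropy of the conditional
#' co-occurrence distribution,
#' \eqn{H_k^W = \sum_r p(z_r | w_k) \log(1/p(z_r|w_k))}: the cell-type
#' heterogeneity remaining at that range once spatial position has been
#' accounted for.  Ranges with no pairs are `NA`.
#'
#' @param hist a [pair_histogram()].
#' @return Numeric vector of length `K` (nats), `NA` for empty ranges.
#' @export
residual_entropy_curve <- function(hist) {
  stopifnot(inherits(hist, "pair_histogram"))
  apply(hist$p_cond, 2L, function(p) {
    if (anyNA(p)) return(NA_real_)
    p <- p[p > 0]
    -sum(p * log(p))
  })
}

#' SPI curve: spatial-information decomposition of co-occurrence entropy
#'
#' Decomposes the global co-occurrence entropy \eqn{H(Z)} into spatial
#' mutual information and residual entropy, per distance range and in total:
#' \deqn{SPI_k = \sum_r p(z_r|w_k) \log\{p(z_r|w_k)/p(z_r)\}, \quad
#'       H_k^W = \sum_r p(z_r|w_k) \log\{1/p(z_r|w_k)\},}
#' \deqn{SPI(Z) = \sum_k p(w_k) SPI_k, \quad H^W(Z) = \sum_k p(w_k) H_k^W,
#'       \quad H(Z) = SPI(Z) + H^W(Z).}
#' \eqn{SPI_k} is a Kullback–Leibler divergence, hence non-negative; it is
#' near 0 when the mix of type pairs at range \eqn{w_k} matches the overall
#' mix (complete spatial randomness) and grows when short- or long-range
#' structure (e.g. same-type clustering) makes the local mix deviate.
#'
#' @param hist a [pair_histogram()], or a [cell_pattern()] (then `K`
#'   is used to build breaks and the histogram internally).
#' @param K number of distance ranges when `hist` is a pattern.
#' @param ... passed on to [compute_distance_breaks()] when `hist` is a
#'   pattern.
#' @return An object of class `spi_curve`: a data frame with columns
#'   `k, d_lo, d_hi, midpoint, n_pairs, spi, residual` and attributes
#'   `totals` (named vector `H`, `SPI`, `HW`), `J`, `R`, `K`,
#'   `subject_id`, `empty_bins`.
#' @examples
#' p <- cell_pattern(runif(200, 0, 100), runif(200, 0, 100),
#'                   sample(c("A", "B"), 200, TRUE))
#' sc <- spi_curve(p, K = 10)
#' attr(sc, "totals")
#' @export
spi_curve <- function(hist, K = 50L, ...) {
  subject_id <- NA_character_
  J <- NA_integer_
  if (inherits(hist, "cell_pattern")) {
    pattern <- hist
    subject_id <- pattern$subject_id
    J <- nlevels(pattern$type)
    binning <- compute_distance_breaks(pattern, K = K, ...)
    hist <- bin_pairs(pattern, binning)
  }
  stopifnot(inherits(hist, "pair_histogram"))
  if (is.na(J) && !is.null(attr(hist$categories, "J")))
    J <- attr(hist$categories, "J")
  p_z <- hist$p_z
  spi_k <- apply(hist$p_cond, 2L, function(pc) {
    if (anyNA(pc)) return(NA_real_)
    nz <- pc > 0
    if (any(nz & p_z == 0))
      stop("internal inconsistency: p(z_r) = 0 but p(z_r|w_k) > 0")
    sum(pc[nz] * log(pc[nz] / p_z[nz]))
  })
  res_k <- residual_entropy_curve(hist)
  p_w <- hist$p_w
  totals <- c(
    H = shannon_entropy(p_z),
    SPI = sum((p_w * spi_k)[p_w > 0]),
    HW = sum((p_w * res_k)[p_w > 0]))
  b <- hist$binning
  out <- data.frame(
    k = seq_len(b$K),
    d_lo = b$breaks[-(b$K + 1L)],
    d_hi = b$breaks[-1L],
    midpoint = b$midpoints,
    n_pairs = colSums(hist$counts),
    spi = spi_k,
    residual = res_k)
  structure(out,
            totals = totals, J = J, R = hist$R, K = b$K,
            subject_id = subject_id,
            empty_bins = which(p_w == 0),
            class = c("spi_curve", "data.frame"))
}

#' @export
print.spi_curve <- function(x, ...) {
  t <- attr(x, "totals")
  cat("<spi_curve>", attr(x, "K"), "distance ranges, R =", attr(x, "R"),
      "pair categories\n  H(Z) =", format(t["H"], digits = 4),
      " SPI(Z) =", format(t["SPI"], digits = 4),
      " H^W(Z) =", format(t["HW"], digits = 4), "\n")
  invisible(x)
}

#' @param x an `spi_curve`.
#' @param ... further arguments to [graphics::plot()].
#' @rdname spi_curve
#' @export
plot.spi_curve <- function(x, ...) {
  graphics::plot(x$midpoint, x$spi, type = "b", pch = 16,
                 xlab = "inter-cell distance (midpoint)", ylab = expression(SPI[k]),
                 ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Label-permutation null envelope for an SPI curve
#'
#' Holds cell coordinates fixed, randomly permutes the type labels
#' `n_perm` times, and recomputes the SPI curve for each permutation on the
#' observed pattern's distance ranges.  Under label exchangeability
#' (complete spatial randomness of types given locations) the observed
#' curve should sit inside the permutation envelope; observed short-range
#' SPI above the envelope indicates genuine spatial organisation of types.
#' The permuted-mean curve can also replace the observed one as a
#' noise-robustified input to downstream functional analysis.
#'
#' @param pattern a [cell_pattern()].
#' @param K number of distance ranges.
#' @param n_perm number of label permutations (>= 1).
#' @param seed integer seed; permutations are reproducible given it.
#' @param probs two quantile levels for the pointwise envelope.
#' @param ... passed to [compute_distance_breaks()].
#' @return List with `observed` (the observed `spi_curve`), `mean`,
#'   `lower`, `upper` (numeric length-`K` pointwise summaries over
#'   permutations) and `perms` (`n_perm x K` matrix of permuted curves).
#' @export
permutation_null_spi <- function(pattern, K = 50L, n_perm = 99L, seed = 1L,
                                 probs = c(0.025, 0.975), ...) {
  stopifnot(inherits(pattern, "cell_pattern"), n_perm >= 1L)
  binning <- compute_distance_breaks(pattern, K = K, ...)
  observed <- spi_curve(bin_pairs(pattern, binning))
  set.seed(as.integer(seed))
  perms <- matrix(NA_real_, n_perm, binning$K)
  pp <- pattern
  for (b in seq_len(n_perm)) {
    pp$type <- pattern$type[sample.int(pattern$n)]
    perms[b, ] <- spi_curve(bin_pairs(pp, binning))$spi
  }
  qs <- apply(perms, 2L, stats::quantile, probs = probs, na.rm = TRUE)
  list(observed = observed,
       mean = colMeans(perms, na.rm = TRUE),
       lower = qs[1L, ], upper = qs[2L, ],
       perms = perms)
}
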