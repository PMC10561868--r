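#' Shannon entropy of a probability mass function
#'
#' \eqn{H = \sum_r p_r \log(1/p_r)} in natural log units (nats), with the
#' convention \eqn{0 \log(1/0) \equiv 0}.  For a pmf over `R` categories the
#' value lies in `[0, log R]`, the maximum attained at the uniform
#' distribution.
#'
#' @param pmf numeric vector of probabilities; must be non-negative and sum
#'   to 1 within `tol`.
#' @param tol tolerance on the sum-to-one check.
#' @return Non-negative entropy in nats.
#' @examples
#' shannon_entropy(rep(0.2, 5))      # log(5)
#' shannon_entropy(c(1, 0, 0))       # 0
#' @export
shannon_entropy <- function(pmf, tol = 1e-8) {
  pmf <- as.numeric(pmf)
  if (any(!is.finite(pmf)) || any(pmf < 0))
    stop("pmf entries must be finite and non-negative")
  if (abs(sum(pmf) - 1) > tol)
    stop("pmf must sum to 1 (got ", format(sum(pmf)), ")")
  p <- pmf[pmf > 0]
  -sum(p * log(p))
}

#' Unordered cell-type pair categories
#'
#' The co-occurrence variable for a label set of size `J` takes
#' \eqn{R = J(J+1)/2} values: one per unordered pair of types (order within
#' a pair carries no meaning for undirected spatial co-occurrence).
#' Categories are ordered canonically: for sorted labels
#' \eqn{a_1 < \dots < a_J}, pairs are listed
#' \eqn{(a_1,a_1), (a_1,a_2), \dots, (a_1,a_J), (a_2,a_2), \dots}.
#'
#' @param labels character vector of type labels, or a single positive
#'   integer `J` (labels then default to `T1..TJ`).
#' @param sep separator used in the category names.
#' @return Character vector of length `R` naming the pair categories, with
#'   attributes `J` and a `J x J` index matrix `index` mapping a type pair to
#'   its category.
#' @examples
#' enumerate_pair_categories(c("A", "B"))   # "A:A" "A:B" "B:B"
#' length(enumerate_pair_categories(5))     # 15
#' @export
enumerate_pair_categories <- function(labels, sep = ":") {
  if (is.numeric(labels) && length(labels) == 1L) {
    if (labels < 1 || labels != round(labels)) stop("J must be a positive integer")
    labels <- paste0("T", seq_len(labels))
  }
  labels <- as.character(labels)
  if (length(labels) < 1L) stop("J must be >= 1")
  labels <- sort(labels)
  J <- length(labels)
  idx <- matrix(0L, J, J)
  nm <- character(J * (J + 1L) / 2L)
  r <- 0L
  for (a in seq_len(J)) {
    for (b in a:J) {
      r <- r + 1L
      idx[a, b] <- r
      idx[b, a] <- r
      nm[r] <- paste(labels[a], labels[b], sep = sep)
    }
  }
  structure(nm, J = J, labels = labels, index = idx)
}

# All pairwise inter-cell distances of a pattern, as a plain vector in the
# column-major lower-triangle order of stats::dist.
pattern_distances <- function(pattern) {
  as.vector(stats::dist(cbind(pattern$x, pattern$y)))
}

# Lower-triangle (i > j) row/col cell indices matching pattern_distances order.
pair_indices <- function(n) {
  list(i = sequence((n - 1L):1L, from = 2:n),
       j = rep.int(seq_len(n - 1L), (n - 1L):1L))
}

#' Distance breaks for co-occurrence binning
#'
#' Builds the `K` distance ranges \eqn{w_k = (d_{k-1}, d_k]} over which
#' cell-pair co-occurrences are tabulated.  Following the focus on local
#' cell-to-cell interaction, \eqn{d_0 = 0} and \eqn{d_K} is the median of
#' the inter-cell distance distribution; interior breaks decrease linearly
#' from \eqn{d_K} on a log scale (geometric spacing), anchored below at
#' `d_floor`.
#'
#' By default `d_floor` is the `q_floor` quantile (0.1%) of the inter-cell
#' distance distribution, floored at the smallest positive distance.  The
#' anchor matters: anchoring at the nearest pair itself would leave the
#' shortest ranges with a handful of pairs, whose plug-in entropy is
#' dominated by upward small-sample bias of order \eqn{(R-1)/2m} for `m`
#' pairs.  The quantile anchor keeps every range populated, in the same
#' spirit as the `K <= 50` cap.
#'
#' @param pattern a [cell_pattern()].
#' @param K number of distance ranges, `1 <= K <= 50`.
#' @param q_floor quantile of the inter-cell distance distribution anchoring
#'   the first break.
#' @param breaks optional explicit break vector `c(0, d_1, ..., d_K)`
#'   (strictly increasing, starting at 0); overrides the automatic rule, for
#'   use with externally chosen ranges.
#' @return An object of class `distance_binning`: list with `breaks`
#'   (length `K + 1`, first element 0), `K`, `d_max`, `midpoints`.
#' @examples
#' p <- cell_pattern(c(0, 1, 2), c(0, 0, 0), c("A", "B", "A"))
#' compute_distance_breaks(p, K = 1)$breaks  # c(0, 1): median of {1,1,2}
#' @export
compute_distance_breaks <- function(pattern, K = 50L, q_floor = 0.001,
                                    breaks = NULL) {
  if (!is.null(breaks)) {
    breaks <- as.numeric(breaks)
    if (breaks[1L] != 0 || any(diff(breaks) <= 0))
      stop("explicit breaks must start at 0 and be strictly increasing")
    return(new_distance_binning(breaks))
  }
  stopifnot(inherits(pattern, "cell_pattern"))
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (K > 50L)
    stop("K must be <= 50: larger K leaves short distance ranges empty, ",
         "making the entropy there undefined")
  d <- pattern_distances(pattern)
  d_max <- stats::median(d)
  if (d_max <= 0)
    stop("degenerate pattern: all cells coincident (median inter-cell distance is 0)")
  if (K == 1L) return(new_distance_binning(c(0, d_max)))
  pos <- d[d > 0]
  d_floor <- max(min(pos), stats::quantile(d, q_floor, names = FALSE))
  if (d_floor >= d_max) {
    # distance distribution too concentrated for log spacing; fall back to linear
    warning("log-scale spacing degenerate (d_floor >= median); using linear breaks")
    return(new_distance_binning(seq(0, d_max, length.out = K + 1L)))
  }
  # log-equally-spaced: d_k = d_max * (d_floor/d_max)^((K-k)/(K-1)), k = 1..K
  dk <- d_max * (d_floor / d_max)^((K - seq_len(K)) / (K - 1))
  breaks <- c(0, dk)
  if (any(diff(breaks) <= 0)) stop("breaks failed to be strictly increasing")
  new_distance_binning(breaks)
}

new_distance_binning <- function(breaks) {
  K <- length(breaks) - 1L
  structure(
    list(breaks = breaks, K = K, d_max = breaks[K + 1L],
         midpoints = (breaks[-1L] + breaks[-(K + 1L)]) / 2),
    class = "distance_binning")
}

#' @export
print.distance_binning <- function(x, ...) {
  cat("<distance_binning>", x$K, "ranges, d_K =", format(x$d_max), "\n")
  invisible(x)
}

#' Tabulate type-pair co-occurrences by distance range
#'
#' Every unordered cell pair with inter-cell distance in \eqn{(0, d_K]}
#' increments exactly one cell of the `R x K` count matrix: row = unordered
#' type pair, column = distance range.  Pairs beyond \eqn{d_K} are excluded;
#' coincident cells (distance exactly 0) are excluded with a warning.  The
#' derived pmfs (joint, range marginal, pair marginal, conditionals) all
#' refer to this restricted support, so the pair marginal is exactly the
#' row sum of the joint — the condition under which the entropy
#' decomposition is additive.
#'
#' @param pattern a [cell_pattern()].
#' @param binning a `distance_binning`, typically from
#'   [compute_distance_breaks()] on the same pattern.
#' @return An object of class `pair_histogram`: list with `counts`
#'   (`R x K` integer matrix), `categories`, `binning`, `n_pairs`, and pmfs
#'   `p_joint`, `p_w`, `p_z`, `p_cond` (columns of `p_cond` for empty ranges
#'   are `NA`).
#' @export
bin_pairs <- function(pattern, binning) {
  stopifnot(inherits(pattern, "cell_pattern"), inherits(binning, "distance_binning"))
  cats <- enumerate_pair_categories(levels(pattern$type))
  cidx <- attr(cats, "index")
  R <- length(cats)
  K <- binning$K
  d <- pattern_distances(pattern)
  if (any(d == 0))
    warning("coincident cells found; pairs at distance 0 are excluded")
  pr <- pair_indices(pattern$n)
  t1 <- as.integer(pattern$type)[pr$i]
  t2 <- as.integer(pattern$type)[pr$j]
  k <- findInterval(d, binning$breaks, left.open = TRUE)  # (b[k], b[k+1]]
  keep <- d > 0 & k >= 1L & k <= K
  if (!any(keep)) stop("degenerate input: no cell pairs within (0, d_K]")
  r <- cidx[cbind(t1[keep], t2[keep])]
  counts <- matrix(tabulate((k[keep] - 1L) * R + r, nbins = R * K), R, K,
                   dimnames = list(pair = as.character(cats), range = NULL))
  new_pair_histogram(counts, cats, binning)
}

# Construct a pair_histogram (and its pmfs) from a count matrix.  Exported
# indirectly through bin_pairs(); also used to build toy histograms in
# analyses of the decomposition itself.
#' Build a pair histogram from an explicit count matrix
#'
#' @param counts non-negative `R x K` matrix of pair counts.
#' @param categories optional category names (length `R`).
#' @param binning optional `distance_binning` with `K` ranges.
#' @return A `pair_histogram` (see [bin_pairs()]).
#' @export
pair_histogram <- function(counts, categories = NULL, binning = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("histogram has no pairs")
  if (is.null(categories)) categories <- paste0("z", seq_len(nrow(counts)))
  if (is.null(binning))
    binning <- new_distance_binning(seq(0, ncol(counts), by = 1))
  if (binning$K != ncol(counts)) stop("binning K does not match counts columns")
  new_pair_histogram(counts, categories, binning)
}

new_pair_histogram <- function(counts, categories, binning) {
  n_pairs <- sum(counts)
  p_joint <- counts / n_pairs
  p_w <- colSums(p_joint)
  p_z <- rowSums(p_joint)
  p_cond <- sweep(p_joint, 2L, p_w, "/")  # NaN for empty ranges
  p_cond[, p_w == 0] <- NA_real_
  structure(
    list(counts = counts, categories = categories, binning = binning,
         n_pairs = n_pairs, R = nrow(counts),
         p_joint = p_joint, p_w = p_w, p_z = p_z, p_cond = p_cond),
    class = "pair_histogram")
}

#' @export
print.pair_histogram <- function(x, ...) {
  cat("<pair_histogram>", x$R, "pair categories x", x$binning$K,
      "distance ranges,", x$n_pairs, "pairs\n")
  invisible(x)
}
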