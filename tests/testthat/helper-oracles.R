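# Independent oracles and small fixture generators, deliberately written
# as plain, slow, loop-based code so they share nothing with the package's
# vectorized implementations.

# Brute-force spatial-entropy decomposition: enumerate all unordered cell
# pairs with two loops, tabulate type pairs per distance interval, and
# evaluate every pmf and entropy term directly from its definition.
brute_spi <- function(x, y, type, breaks) {
  type <- as.character(type)
  labs <- sort(unique(type))
  J <- length(labs)
  cats <- c()
  for (a in 1:J) for (b in a:J) cats <- c(cats, paste(labs[a], labs[b], sep = ":"))
  R <- length(cats)
  K <- length(breaks) - 1
  N <- matrix(0, R, K, dimnames = list(cats, NULL))
  n <- length(x)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (d <= 0 || d > breaks[K + 1]) next
      k <- NA
      for (kk in 1:K) if (d > breaks[kk] && d <= breaks[kk + 1]) { k <- kk; break }
      if (is.na(k)) next
      pr <- sort(c(type[i], type[j]))
      cat_name <- paste(pr[1], pr[2], sep = ":")
      N[cat_name, k] <- N[cat_name, k] + 1
    }
  }
  tot <- sum(N)
  p_joint <- N / tot
  p_w <- colSums(p_joint)
  p_z <- rowSums(p_joint)
  spi_k <- rep(NA_real_, K)
  res_k <- rep(NA_real_, K)
  for (k in 1:K) {
    if (p_w[k] == 0) next
    s <- 0; h <- 0
    for (r in 1:R) {
      pc <- p_joint[r, k] / p_w[k]
      if (pc > 0) {
        s <- s + pc * log(pc / p_z[r])
        h <- h - pc * log(pc)
      }
    }
    spi_k[k] <- s
    res_k[k] <- h
  }
  H <- 0
  for (r in 1:R) if (p_z[r] > 0) H <- H - unname(p_z[r]) * log(unname(p_z[r]))
  SPI <- 0; HW <- 0
  for (k in 1:K) if (p_w[k] > 0) {
    SPI <- SPI + p_w[k] * spi_k[k]
    HW <- HW + p_w[k] * res_k[k]
  }
  list(counts = N, spi = spi_k, residual = res_k,
       totals = c(H = H, SPI = SPI, HW = HW))
}

# Brute-force median of all pairwise distances (two loops).
brute_median_distance <- function(x, y) {
  n <- length(x)
  d <- c()
  for (i in 1:(n - 1))
    for (j in (i + 1):n)
      d <- c(d, sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2))
  stats::median(d)
}

# Breslow partial log-likelihood written from the explicit product formula.
brute_cox_loglik <- function(beta, time, event, X) {
  X <- as.matrix(X)
  eta <- as.numeric(X %*% beta)
  ll <- 0
  for (tt in sort(unique(time[event == 1]))) {
    dead <- which(time == tt & event == 1)
    risk <- which(time >= tt)
    ll <- ll + sum(eta[dead]) - length(dead) * log(sum(exp(eta[risk])))
  }
  ll
}

# Maximize the brute-force partial likelihood numerically.
brute_cox_fit <- function(time, event, X) {
  X <- as.matrix(X)
  opt <- stats::optim(rep(0, ncol(X)),
                      function(b) -brute_cox_loglik(b, time, event, X),
                      method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  list(coef = opt$par, loglik = -opt$value)
}

# Random multitype pattern for property tests.
random_pattern <- function(n, J, seed, side = 100, clustered = FALSE) {
  set.seed(seed)
  labs <- LETTERS[1:J]
  if (clustered) {
    # two patches per type so mid/long ranges mix types
    centers <- matrix(runif(4 * J, 0, side), 2 * J, 2)
    i <- sample(seq_len(2 * J), n, replace = TRUE)
    x <- rnorm(n, centers[i, 1], side / 15)
    y <- rnorm(n, centers[i, 2], side / 15)
    type <- labs[(i - 1) %% J + 1]
  } else {
    x <- runif(n, 0, side)
    y <- runif(n, 0, side)
    type <- sample(labs, n, replace = TRUE)
  }
  cell_pattern(x, y, type, subject_id = paste0("P", seed), levels = labs)
}

# Random pair-count matrix (some zero cells, occasional empty columns).
random_histogram <- function(seed, R_max = 10, K_max = 12) {
  set.seed(seed)
  R <- sample(2:R_max, 1)
  K <- sample(2:K_max, 1)
  counts <- matrix(rpois(R * K, lambda = runif(1, 0.5, 8)), R, K)
  if (sum(counts) == 0) counts[1, 1] <- 1
  pair_histogram(counts)
}
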