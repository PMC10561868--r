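test_that("shannon entropy matches hand-computed values and validates input", {
  expect_equal(shannon_entropy(rep(0.2, 5)), log(5))
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  # 0.5*log(2) + 2*0.25*log(4) = 1.5*log(2)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5 * log(2))
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
  expect_error(shannon_entropy(c(1.2, -0.2)), "non-negative")
})

test_that("pair categories enumerate J(J+1)/2 unordered pairs canonically", {
  expect_length(enumerate_pair_categories(5), 15)
  expect_equal(as.character(enumerate_pair_categories(1)), "T1:T1")
  expect_equal(as.character(enumerate_pair_categories(c("A", "B"))),
               c("A:A", "A:B", "B:B"))
  # input order irrelevant
  expect_equal(as.character(enumerate_pair_categories(c("B", "A"))),
               c("A:A", "A:B", "B:B"))
  expect_error(enumerate_pair_categories(0), "positive")
  idx <- attr(enumerate_pair_categories(c("A", "B", "C")), "index")
  expect_equal(idx[2, 3], idx[3, 2])  # unordered
})

test_that("distance breaks start at 0, end at the median, increase strictly", {
  p3 <- cell_pattern(c(0, 1, 2), c(0, 0, 0), c("A", "B", "A"))
  b1 <- compute_distance_breaks(p3, K = 1)
  expect_equal(b1$breaks, c(0, 1))  # median of {1, 1, 2}

  p <- random_pattern(300, 3, seed = 11)
  b <- compute_distance_breaks(p, K = 50)
  expect_length(b$breaks, 51)
  expect_true(all(diff(b$breaks) > 0))
  expect_equal(b$breaks[1], 0)
  expect_equal(b$d_max, brute_median_distance(p$x, p$y))

  expect_error(compute_distance_breaks(p, K = 51), "<= 50")
  pc <- cell_pattern(c(1, 1, 1), c(2, 2, 2), c("A", "A", "B"))
  expect_error(compute_distance_breaks(pc, K = 5), "coincident")
})

test_that("explicit breaks are accepted and validated", {
  b <- compute_distance_breaks(breaks = c(0, 0.25, 1))
  expect_equal(b$K, 2)
  expect_error(compute_distance_breaks(breaks = c(0.1, 0.5)), "start at 0")
  expect_error(compute_distance_breaks(breaks = c(0, 2, 1)), "increasing")
})

test_that("bin_pairs assigns every in-range pair to exactly one cell", {
  p2 <- cell_pattern(c(0, 3), c(0, 0), c("A", "B"))
  h2 <- bin_pairs(p2, compute_distance_breaks(p2, K = 1))
  expect_equal(sum(h2$counts), 1)
  expect_equal(unname(h2$counts["A:B", 1]), 1L)  # distance = median: included

  for (sd_ in 1:5) {
    p <- random_pattern(80, 4, seed = 100 + sd_)
    b <- compute_distance_breaks(p, K = 12)
    h <- bin_pairs(p, b)
    d <- dist(cbind(p$x, p$y))
    expect_equal(sum(h$counts), sum(d > 0 & d <= b$d_max))
    expect_equal(sum(h$p_joint), 1)
    expect_equal(rowSums(h$p_joint), h$p_z)
    nonempty <- h$p_w > 0
    expect_equal(colSums(h$p_cond[, nonempty, drop = FALSE]),
                 rep(1, sum(nonempty)), ignore_attr = TRUE)
  }
})

test_that("first-range co-occurrence counts match brute-force enumeration", {
  # 30 cells, 10 per type, co-occurrences within radius 0.25
  set.seed(42)
  x <- runif(30, 0, 2); y <- runif(30, 0, 2)
  type <- rep(c("A", "B", "C"), each = 10)
  p <- cell_pattern(x, y, type)
  breaks <- c(0, 0.25, compute_distance_breaks(p, K = 1)$d_max)
  h <- bin_pairs(p, compute_distance_breaks(breaks = breaks))
  oracle <- brute_spi(x, y, type, breaks)
  expect_equal(unname(h$counts), unname(oracle$counts), ignore_attr = TRUE)
})

test_that("residual entropy per range follows the conditional pmf", {
  counts <- cbind(c(5, 0, 0), c(2, 2, 2), c(2, 1, 1))
  h <- pair_histogram(counts)
  res <- residual_entropy_curve(h)
  expect_equal(res[1], 0)            # single observed category
  expect_equal(res[2], log(3))       # uniform over categories
  expect_equal(res[3], 1.5 * log(2)) # (0.5, 0.25, 0.25)
  # empty ranges are missing, not zero
  h0 <- pair_histogram(cbind(c(1, 2), c(0, 0)))
  expect_true(is.na(residual_entropy_curve(h0)[2]))
})

test_that("SPI vanishes when conditional equals marginal and for one type", {
  # proportional columns: p(z|w_k) identical across ranges
  counts <- cbind(c(8, 4, 2), c(16, 8, 4), c(4, 2, 1))
  cv <- spi_curve(pair_histogram(counts))
  expect_equal(cv$spi, rep(0, 3), tolerance = 1e-12)
  expect_equal(attr(cv, "totals")[["SPI"]], 0, tolerance = 1e-12)

  p1 <- random_pattern(60, 1, seed = 9)
  cv1 <- spi_curve(p1, K = 8)
  expect_equal(cv1$spi[!is.na(cv1$spi)],
               rep(0, sum(!is.na(cv1$spi))), tolerance = 1e-12)
})

test_that("SPI curve matches the brute-force oracle on a clustered pattern", {
  p <- random_pattern(200, 2, seed = 5, clustered = TRUE)
  b <- compute_distance_breaks(p, K = 15)
  cv <- spi_curve(bin_pairs(p, b))
  oracle <- brute_spi(p$x, p$y, as.character(p$type), b$breaks)
  expect_equal(cv$spi, unname(oracle$spi), tolerance = 1e-12)
  expect_equal(cv$residual, unname(oracle$residual), tolerance = 1e-12)
  expect_equal(attr(cv, "totals"), oracle$totals, tolerance = 1e-12)
})

test_that("decomposition identity and bounds hold on random histograms", {
  for (sd_ in 1:100) {
    h <- random_histogram(sd_)
    cv <- spi_curve(h)
    t <- attr(cv, "totals")
    expect_lt(abs(t[["H"]] - t[["SPI"]] - t[["HW"]]), 1e-10)
    expect_true(all(cv$spi[!is.na(cv$spi)] >= -1e-12))
    expect_gte(t[["SPI"]], -1e-12)
    expect_gte(t[["HW"]], 0)
    expect_lte(t[["HW"]], t[["H"]] + 1e-12)
    expect_lte(t[["H"]], log(h$R) + 1e-12)
  }
})

test_that("SPI curves are invariant under rigid motions", {
  p <- random_pattern(150, 3, seed = 21, clustered = TRUE)
  cv <- spi_curve(p, K = 20)
  set.seed(77)
  for (rep_ in 1:5) {
    th <- runif(1, 0, 2 * pi)
    dx <- runif(2, -500, 500)
    refl <- sample(c(1, -1), 1)
    xr <- cos(th) * p$x - sin(th) * p$y + dx[1]
    yr <- refl * (sin(th) * p$x + cos(th) * p$y) + dx[2]
    cvr <- spi_curve(cell_pattern(xr, yr, p$type), K = 20)
    expect_equal(cvr$spi, cv$spi, tolerance = 1e-9)
    expect_equal(attr(cvr, "totals"), attr(cv, "totals"), tolerance = 1e-9)
  }
})

test_that("label-permutation null brackets CSR but not clustering", {
  csr <- random_pattern(250, 2, seed = 31)
  pn <- permutation_null_spi(csr, K = 8, n_perm = 39, seed = 4)
  # labels already exchangeable: observed close to the permuted mean
  expect_lt(max(abs(pn$observed$spi - pn$mean), na.rm = TRUE), 0.05)

  cl <- random_pattern(250, 2, seed = 32, clustered = TRUE)
  pc <- permutation_null_spi(cl, K = 8, n_perm = 99, seed = 4)
  expect_gt(pc$observed$spi[1], pc$upper[1])  # short-range SPI exceeds envelope

  # reproducible given the seed
  pc2 <- permutation_null_spi(cl, K = 8, n_perm = 99, seed = 4)
  expect_identical(pc$perms, pc2$perms)
})

test_that("diversity baselines are space-blind summaries of type frequencies", {
  p <- cell_pattern(runif(50), runif(50), rep(LETTERS[1:5], each = 10))
  d <- diversity_baselines(p)
  expect_equal(d[["shannon"]], log(5))
  expect_equal(d[["simpson"]], 0.8)

  p1 <- cell_pattern(runif(10), runif(10), rep("A", 10))
  expect_equal(unname(diversity_baselines(p1)), c(0, 0))

  # any spatial rearrangement leaves both indices unchanged
  p_shuf <- cell_pattern(p$y * 3 + 1, rev(p$x), p$type)
  expect_equal(diversity_baselines(p_shuf), d)
})

test_that("degenerate inputs raise informative errors", {
  expect_error(cell_pattern(1, 1, "A"), "at least 2")
  expect_error(cell_pattern(c(0, Inf), c(0, 1), c("A", "B")), "finite")
  expect_error(cell_pattern(c(0, 1), c(0, 1), c("A", "Z"), levels = c("A", "B")),
               "label set")
  p <- cell_pattern(c(0, 0, 1), c(0, 0, 0), c("A", "A", "B"))
  expect_warning(bin_pairs(p, compute_distance_breaks(breaks = c(0, 2))),
                 "coincident")
})
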