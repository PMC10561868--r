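# Cohort simulator: multitype point patterns (clustered vs completely
# random), reference SPI curves, noise-perturbed subject curves, and
# proportional-hazards survival times linked to FPC scores.

NOISE_SD <- c(small = 0.01, medium = 0.05, large = 0.15)

noise_sd <- function(noise) {
  if (is.numeric(noise)) return(as.numeric(noise))
  if (!noise %in% names(NOISE_SD)) stop("unknown noise level: ", noise)
  NOISE_SD[[noise]]
}

#' Simulate a multitype cell pattern
#'
#' Two spatial configurations of `J` cell types with a fixed count per
#' type in a rectangular window:
#' * `"random"` — complete spatial randomness: every cell placed
#'   independently and uniformly;
#' * `"clustered"` — a Thomas-style cluster process per type: `n_parents`
#'   parent locations uniform in the window, each cell assigned to a
#'   parent and displaced by isotropic Gaussian noise (`cluster_sd`),
#'   wrapped toroidally so counts stay exact.  Different types get
#'   different parents, producing type-segregated patches.
#'
#' @param config `"random"` or `"clustered"`.
#' @param J number of cell types.
#' @param n_per_type cells per type (default 600).
#' @param window `c(xmin, xmax, ymin, ymax)` in microns.
#' @param n_parents,cluster_sd Thomas-process geometry (clustered config).
#' @param type_labels optional labels (default `T1..TJ`).
#' @param subject_id subject identifier.
#' @param seed optional integer seed for exact reproducibility.
#' @return A [cell_pattern()].
#' @export
simulate_pattern <- function(config = c("random", "clustered"), J = 5L,
                             n_per_type = 600L,
                             window = c(0, 1000, 0, 1000),
                             n_parents = 5L, cluster_sd = 40,
                             type_labels = NULL, subject_id = "sim",
                             seed = NULL) {
  config <- match.arg(config)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (n_per_type < 1L || J < 1L) stop("counts must be positive")
  wx <- window[2L] - window[1L]
  wy <- window[4L] - window[3L]
  if (wx <= 0 || wy <= 0) stop("degenerate window")
  if (is.null(type_labels)) type_labels <- paste0("T", seq_len(J))
  n <- J * n_per_type
  type <- rep(type_labels, each = n_per_type)
  if (config == "random") {
    x <- stats::runif(n, window[1L], window[2L])
    y <- stats::runif(n, window[3L], window[4L])
  } else {
    x <- numeric(n); y <- numeric(n)
    for (j in seq_len(J)) {
      px <- stats::runif(n_parents, window[1L], window[2L])
      py <- stats::runif(n_parents, window[3L], window[4L])
      par <- sample.int(n_parents, n_per_type, replace = TRUE)
      ix <- (j - 1L) * n_per_type + seq_len(n_per_type)
      # toroidal wrap keeps all offspring in-window without altering counts
      x[ix] <- window[1L] + (px[par] + stats::rnorm(n_per_type, 0, cluster_sd) -
                               window[1L]) %% wx
      y[ix] <- window[3L] + (py[par] + stats::rnorm(n_per_type, 0, cluster_sd) -
                               window[3L]) %% wy
    }
  }
  cell_pattern(x, y, type, subject_id = subject_id, levels = sort(type_labels))
}

#' Reference SPI curves per spatial configuration
#'
#' Averages the SPI curve over `n_reps` independent replicate patterns of
#' each configuration, bin index by bin index (replicate binnings are
#' near-identical because the configurations are homogeneous).  The random
#' configuration's reference is approximately zero at all ranges; the
#' clustered configuration's sits above zero, most strongly at short range.
#'
#' @param configs configurations to simulate.
#' @param n_reps replicates per configuration.
#' @param K number of distance ranges.
#' @param seed integer seed.
#' @param ... passed to [simulate_pattern()].
#' @return Named list (one per configuration) of data frames with columns
#'   `k`, `midpoint`, `spi` (replicate means; bins empty in any replicate
#'   are dropped).
#' @export
reference_spi_curves <- function(configs = c("clustered", "random"),
                                 n_reps = 10L, K = 50L, seed = 1L, ...) {
  stopifnot(n_reps >= 1L)
  set.seed(as.integer(seed))
  out <- list()
  for (cfg in configs) {
    spi_mat <- matrix(NA_real_, n_reps, K)
    mid_mat <- matrix(NA_real_, n_reps, K)
    for (b in seq_len(n_reps)) {
      p <- simulate_pattern(cfg, ...)
      cv <- spi_curve(p, K = K)
      spi_mat[b, ] <- cv$spi
      mid_mat[b, ] <- cv$midpoint
    }
    keep <- colSums(is.na(spi_mat)) == 0L
    out[[cfg]] <- data.frame(
      k = which(keep),
      midpoint = colMeans(mid_mat)[keep],
      spi = colMeans(spi_mat)[keep])
  }
  out
}

#' Simulate noisy subject-level SPI curves
#'
#' Each subject is assigned to the clustered or random configuration
#' (group sizes `~ Binomial(N, p_clustered)`) and observed as its group's
#' reference curve plus additive noise at the chosen level
#' (`small/medium/large` = bin-level SD 0.01/0.05/0.15 on the SPI scale,
#' or a numeric SD).  The noise has two parts: a subject-level baseline
#' offset (a smooth, curve-wide shift with SD `shift_factor` times the
#' bin-level SD, emulating subject-wide differences in overall
#' co-occurrence diversity) and iid bin-level jitter.  The offset gives
#' the cohort a genuine second mode of functional variation on top of the
#' clustered-versus-random contrast.
#'
#' @param n_subjects cohort size `N`.
#' @param refs reference curves from [reference_spi_curves()].
#' @param noise `"small"`, `"medium"`, `"large"` or a numeric SD.
#' @param p_clustered probability of the clustered configuration.
#' @param shift_factor ratio of the subject-level offset SD to the
#'   bin-level SD (default 1.5; 0 disables the offset).
#' @param seed integer seed.
#' @return List with `sample` (a [sparse_curves()]), `group` (factor per
#'   subject), `noise_sd`, `shift_sd`.
#' @export
simulate_cohort_curves <- function(n_subjects, refs, noise = "medium",
                                   p_clustered = 0.5, shift_factor = 1.5,
                                   seed = 1L) {
  set.seed(as.integer(seed))
  sd0 <- noise_sd(noise)
  sd_shift <- shift_factor * sd0
  cfgs <- names(refs)
  stopifnot(length(cfgs) == 2L)
  grp <- cfgs[1L + stats::rbinom(n_subjects, 1L, 1 - p_clustered)]
  ids <- sprintf("S%04d", seq_len(n_subjects))
  shifts <- stats::rnorm(n_subjects, 0, sd_shift)
  parts <- lapply(seq_len(n_subjects), function(i) {
    ref <- refs[[grp[i]]]
    data.frame(id = ids[i], s = ref$midpoint,
               y = ref$spi + shifts[i] + stats::rnorm(nrow(ref), 0, sd0))
  })
  long <- do.call(rbind, parts)
  list(sample = sparse_curves(long$id, long$s, long$y),
       group = factor(grp, levels = cfgs),
       ids = ids,
       noise_sd = sd0, shift_sd = sd_shift)
}

#' Synthetic sparse functional cohort with known eigenstructure
#'
#' Generates irregularly observed curves
#' \eqn{y_{ik} = \mu(s_{ik}) + \xi_{i1}\phi_1(s_{ik}) +
#' \xi_{i2}\phi_2(s_{ik}) + \epsilon_{ik}} on `[0, 1]` with two known
#' orthonormal components (\eqn{\phi_1 \equiv 1},
#' \eqn{\phi_2(s) = \sqrt{3}(2s - 1)}) for validating the FPCA estimators.
#' Per-subject observation counts are uniform on `k_range`; abscissae are
#' stratified (one uniform draw per 1/K cell), mimicking the structured
#' spacing of distance-bin midpoints.  Scores are drawn Gaussian and then
#' exactly standardized (centered, unit-scaled, decorrelated) before
#' scaling by \eqn{\sqrt{\lambda_l}}, so the empirical score covariance
#' equals the target and estimator error is not confounded with score
#' sampling noise.
#'
#' @param n_subjects number of curves.
#' @param lambda length-2 positive eigenvalues (default `c(0.8, 0.15)`).
#' @param sigma measurement-error SD.
#' @param k_range integer range of per-subject observation counts.
#' @param seed integer seed.
#' @return List with `sample` (a [sparse_curves()]), `scores` (true
#'   \eqn{n \times 2} score matrix), `lambda`, `mu_fun`, `phi_funs`
#'   (list of the two eigenfunctions as functions).
#' @export
simulate_fpca_cohort <- function(n_subjects = 300L, lambda = c(0.8, 0.15),
                                 sigma = 0.05, k_range = c(5L, 50L),
                                 seed = 1L) {
  set.seed(as.integer(seed))
  stopifnot(length(lambda) == 2L, all(lambda > 0))
  mu_fun <- function(s) 1 + sin(2 * pi * s) / 3
  phi_funs <- list(function(s) rep(1, length(s)),
                   function(s) sqrt(3) * (2 * s - 1))
  xi <- matrix(stats::rnorm(2L * n_subjects), n_subjects, 2L)
  xi <- scale(xi)
  xi <- qr.Q(qr(xi)) * sqrt(n_subjects - 1)   # exactly orthonormal columns
  xi <- sweep(xi, 2L, sqrt(lambda), "*")
  ids <- sprintf("S%04d", seq_len(n_subjects))
  parts <- lapply(seq_len(n_subjects), function(i) {
    k <- sample(seq(k_range[1L], k_range[2L]), 1L)
    s <- (seq_len(k) - stats::runif(k)) / k
    data.frame(id = ids[i], s = s,
               y = mu_fun(s) + xi[i, 1L] * phi_funs[[1L]](s) +
                 xi[i, 2L] * phi_funs[[2L]](s) + stats::rnorm(k, 0, sigma))
  })
  long <- do.call(rbind, parts)
  rownames(xi) <- ids
  list(sample = sparse_curves(long$id, long$s, long$y),
       scores = xi, lambda = lambda, mu_fun = mu_fun, phi_funs = phi_funs)
}

#' Standardized linear predictor from clinical covariate and scores
#'
#' \eqn{\eta^*_i = Z^*_i + \sum_{l \le L} \xi^*_{il}} with the clinical
#' covariate and each score column mean-centered and unit-scaled first.
#'
#' @param z numeric clinical covariate.
#' @param scores score matrix.
#' @param L number of leading score columns entering the sum.
#' @return Numeric vector of linear predictors.
#' @export
build_linear_predictor <- function(z, scores, L = ncol(scores)) {
  scores <- as.matrix(scores)[, seq_len(L), drop = FALSE]
  as.numeric(scale(z)) + rowSums(apply(scores, 2L, function(v) as.numeric(scale(v))))
}

#' Simulate right-censored survival times from a linear predictor
#'
#' Inverse-transform sampling from
#' \eqn{S_i(t) = \exp\{-e^{\eta_i} \Lambda_0(t)\}} with a parametric
#' cumulative baseline hazard (default Weibull, shape 1.2, scale 60 time
#' units), and independent exponential censoring (default rate 0.008,
#' giving roughly 40% censoring under the default cohort conditions).
#'
#' @param eta numeric linear predictors \eqn{\eta^*_i}.
#' @param baseline list: `type = "weibull"` with `shape`, `scale`, or
#'   `type = "exponential"` with `rate`.
#' @param censoring list: `type = "exponential"` with `rate`, or
#'   `type = "none"`.
#' @param seed integer seed.
#' @return Data frame with `time` (\eqn{Y_i = \min(T_i, C_i)}), `event`
#'   (\eqn{\delta_i}), and the latent `t_true`, `t_cens`.
#' @export
simulate_survival <- function(eta,
                              baseline = list(type = "weibull",
                                              shape = 1.2, scale = 60),
                              censoring = list(type = "exponential",
                                               rate = 0.008),
                              seed = 1L) {
  set.seed(as.integer(seed))
  n <- length(eta)
  u <- stats::runif(n)
  # Lambda0(T) = -log(u) * exp(-eta); invert the cumulative baseline
  lam <- -log(u) * exp(-eta)
  t_true <- switch(baseline$type,
    weibull = baseline$scale * lam^(1 / baseline$shape),
    exponential = lam / baseline$rate,
    stop("unknown baseline type: ", baseline$type))
  if (any(!is.finite(t_true)) || baseline_scale_bad(baseline))
    stop("invalid baseline specification")
  t_cens <- switch(censoring$type,
    exponential = stats::rexp(n, censoring$rate),
    none = rep(Inf, n),
    stop("unknown censoring type: ", censoring$type))
  data.frame(time = pmin(t_true, t_cens),
             event = as.integer(t_true <= t_cens),
             t_true = t_true, t_cens = t_cens)
}

baseline_scale_bad <- function(baseline) {
  (baseline$type == "weibull" && (baseline$shape <= 0 || baseline$scale <= 0)) ||
    (baseline$type == "exponential" && baseline$rate <= 0)
}

#' Normalized root mean squared error of predicted linear predictors
#'
#' `sqrt(mean((eta_hat - eta_star)^2)) / mean(abs(eta_star))`.  The
#' normalization makes the error scale-free: rescaling both vectors by a
#' common positive factor leaves it unchanged.  `type = "mse"` gives the
#' unrooted variant `mean((eta_hat - eta_star)^2) / mean(abs(eta_star))`.
#'
#' @param eta_hat,eta_star equal-length numeric vectors (predicted, true).
#' @param type `"rmse"` (default) or `"mse"`.
#' @return Non-negative scalar.
#' @examples
#' nrmse(c(2, 0), c(1, 1))  # 1
#' @export
nrmse <- function(eta_hat, eta_star, type = c("rmse", "mse")) {
  type <- match.arg(type)
  stopifnot(length(eta_hat) == length(eta_star), length(eta_star) >= 1L)
  denom <- mean(abs(eta_star))
  if (denom == 0) stop("true linear predictor is identically zero")
  err <- mean((eta_hat - eta_star)^2)
  if (type == "rmse") sqrt(err) / denom else err / denom
}

#' Simulate one full cohort: curves, scores, clinical covariate, survival
#'
#' Chains the curve simulator, FPCA (component count by the FVE rule),
#' the standardized linear predictor and the survival generator into one
#' analysis-ready cohort.
#'
#' @param n_subjects cohort size.
#' @param refs reference curves ([reference_spi_curves()]).
#' @param noise noise level (see [simulate_cohort_curves()]).
#' @param fve FVE threshold for the number of scores entering \eqn{\eta^*}.
#' @param max_L cap on that number.
#' @param clinical_mean,clinical_sd distribution of the age-like covariate.
#' @param baseline,censoring see [simulate_survival()].
#' @param bandwidth_mean,bandwidth_cov FPCA bandwidths; the defaults are
#'   fixed fractions (0.07 / 0.15) of the distance-domain range, the
#'   simulator's reproducibility-oriented policy.
#' @param seed integer seed.
#' @return List with `records` (data frame `subject_id`, `time`, `event`,
#'   `z`, `xi1..xiL`), `eta_star`, `L`, `group`, `fpca` (the fitted
#'   `fpca_model`), `sample`.
#' @export
simulate_cohort <- function(n_subjects, refs, noise = "medium", fve = 0.92,
                            max_L = 5L,
                            clinical_mean = 64, clinical_sd = 10,
                            baseline = list(type = "weibull",
                                            shape = 1.2, scale = 60),
                            censoring = list(type = "exponential",
                                             rate = 0.008),
                            bandwidth_mean = NULL, bandwidth_cov = NULL,
                            seed = 1L) {
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max, 3L)
  cc <- simulate_cohort_curves(n_subjects, refs, noise, seed = seeds[1L])
  rng <- diff(range(cc$sample$s))
  if (is.null(bandwidth_mean)) bandwidth_mean <- 0.07 * rng
  if (is.null(bandwidth_cov)) bandwidth_cov <- 0.15 * rng
  fp <- fit_fpca(cc$sample, fve = fve,
                 bandwidth_mean = bandwidth_mean, bandwidth_cov = bandwidth_cov)
  L <- min(fp$L, max_L, ncol(fp$scores))
  scores <- fp$scores[cc$ids, seq_len(L), drop = FALSE]
  set.seed(seeds[2L])
  z <- stats::rnorm(n_subjects, clinical_mean, clinical_sd)
  eta <- build_linear_predictor(z, scores, L)
  surv <- simulate_survival(eta, baseline, censoring, seed = seeds[3L])
  records <- data.frame(subject_id = cc$ids,
                        time = surv$time, event = surv$event, z = z)
  colnames(scores) <- paste0("xi", seq_len(L))
  records <- cbind(records, scores)
  rownames(records) <- NULL
  list(records = records, eta_star = eta, L = L, group = cc$group,
       fpca = fp, sample = cc$sample)
}

#' NRMSE comparison of clinical/spatial/combined predictive models
#'
#' For each cohort size and noise level, repeats `n_iter` times: simulate a
#' cohort, split 75/25 into training and test, fit three Cox models on the
#' training set — (1) clinical covariate + FPC scores, (2) scores only,
#' (3) clinical only — and score each model's predicted linear predictor
#' against the true \eqn{\eta^*} on the test set by [nrmse()].
#'
#' @param sizes integer vector of cohort sizes.
#' @param noise_levels character/numeric vector of noise levels.
#' @param n_iter iterations per grid cell.
#' @param refs reference curves; generated at the default study conditions
#'   if `NULL`.
#' @param train_frac training fraction (default 0.75).
#' @param seed master seed; all randomness derives from it via per-run
#'   substreams.
#' @param ... passed to [simulate_cohort()].
#' @return An object of class `nrmse_experiment`: data frame with columns
#'   `size`, `noise`, `iter`, `model`, `nrmse`.
#' @export
run_experiment <- function(sizes = c(100L), noise_levels = c("medium", "large"),
                           n_iter = 100L, refs = NULL, train_frac = 0.75,
                           seed = 1L, ...) {
  set.seed(as.integer(seed))
  if (is.null(refs)) refs <- reference_spi_curves(seed = sample.int(1e9, 1L))
  grid <- expand.grid(size = sizes, noise = noise_levels,
                      iter = seq_len(n_iter), stringsAsFactors = FALSE)
  run_seeds <- sample.int(.Machine$integer.max, nrow(grid))
  res <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    set.seed(run_seeds[g])
    sub <- sample.int(.Machine$integer.max, 2L)
    coh <- simulate_cohort(grid$size[g], refs, noise = grid$noise[g],
                           seed = sub[1L], ...)
    set.seed(sub[2L])
    n <- nrow(coh$records)
    idx_train <- sort(sample.int(n, round(train_frac * n)))
    idx_test <- setdiff(seq_len(n), idx_train)
    train <- coh$records[idx_train, ]
    test <- coh$records[idx_test, ]
    score_cols <- grep("^xi", names(coh$records), value = TRUE)
    covs <- list(c("z", score_cols), score_cols, "z")
    vals <- vapply(covs, function(cv) {
      fit <- fit_cox(train, cv)
      nrmse(linear_predictor(fit, test), coh$eta_star[idx_test])
    }, numeric(1))
    res[[g]] <- data.frame(size = grid$size[g], noise = grid$noise[g],
                           iter = grid$iter[g], model = c("1", "2", "3"),
                           nrmse = vals)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("nrmse_experiment", "data.frame"))
}

#' Summarise an NRMSE experiment as mean (SD) per cell
#'
#' @param object an `nrmse_experiment` from [run_experiment()].
#' @param ... unused.
#' @return Data frame with `size`, `noise`, `model`, `mean`, `sd`, `n`.
#' @export
summary.nrmse_experiment <- function(object, ...) {
  agg <- stats::aggregate(nrmse ~ size + noise + model, data = object,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  out <- cbind(agg[c("size", "noise", "model")], as.data.frame(agg$nrmse))
  out[order(out$noise, out$size, out$model), ]
}
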