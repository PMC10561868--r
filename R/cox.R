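#' Assemble survival records
#'
#' Joins a clinical table (subject id, observed time, event indicator,
#' scalar covariates) with a matrix/data frame of functional principal
#' component scores by subject id.  Subjects missing on either side, or
#' with missing covariate values, are dropped with a message.
#'
#' @param clinical data frame with columns `subject_id`, `time`, `event`
#'   plus any clinical covariates.
#' @param scores matrix or data frame of scores with row names (or a
#'   `subject_id` column) identifying subjects.
#' @param covariates character vector of clinical covariate columns to
#'   carry (default: all extra columns).
#' @return Data frame with `subject_id`, `time`, `event`, the clinical
#'   covariates and score columns `xi1..xiL`.
#' @export
assemble_records <- function(clinical, scores, covariates = NULL) {
  stopifnot(all(c("subject_id", "time", "event") %in% names(clinical)))
  if (is.null(covariates))
    covariates <- setdiff(names(clinical), c("subject_id", "time", "event"))
  if (is.data.frame(scores) && "subject_id" %in% names(scores)) {
    rn <- as.character(scores$subject_id)
    scores <- as.matrix(scores[setdiff(names(scores), "subject_id")])
    rownames(scores) <- rn
  } else {
    scores <- as.matrix(scores)
  }
  if (is.null(rownames(scores))) stop("scores must identify subjects")
  colnames(scores) <- paste0("xi", seq_len(ncol(scores)))
  ids <- intersect(as.character(clinical$subject_id), rownames(scores))
  dropped <- setdiff(union(as.character(clinical$subject_id), rownames(scores)), ids)
  df <- clinical[match(ids, as.character(clinical$subject_id)),
                 c("subject_id", "time", "event", covariates), drop = FALSE]
  df <- cbind(df, scores[ids, , drop = FALSE])
  cc <- stats::complete.cases(df)
  dropped <- c(dropped, df$subject_id[!cc])
  if (length(dropped))
    message(length(dropped), " subject(s) dropped (unmatched or missing data)")
  df <- df[cc, , drop = FALSE]
  if (any(df$time <= 0)) stop("survival times must be positive")
  if (!all(df$event %in% c(0, 1))) stop("event indicator must be 0/1")
  rownames(df) <- NULL
  df
}

#' Cox proportional-hazards fit with standardized covariates
#'
#' Fits the partial likelihood of the model
#' \eqn{\log h_i(t) = \log h_0(t) + U_i^T\gamma + \xi_i^T\beta}
#' with Breslow tie handling (Efron selectable), after mean-centering and
#' unit-scaling every covariate.  The standardization is stored so linear
#' predictors for new data are reproducible.  Constant covariates are
#' dropped with a warning (their coefficient is undefined); collinear
#' designs raise an error naming the offending columns.
#'
#' @param records data frame with `time`, `event` and covariate columns
#'   (see [assemble_records()]).
#' @param covariates character vector of covariate columns to include.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param standardize mean-center and unit-scale covariates (default TRUE).
#' @return An object of class `cox_fit`: list with `coefficients`,
#'   `loglik` (of the fitted model), `loglik_null`, `basehaz` (Breslow
#'   cumulative baseline hazard at covariates equal to their means),
#'   `center`, `scale`, `covariates`, `dropped`, `n`, `n_events`, and the
#'   underlying `survival::coxph` fit.
#' @export
fit_cox <- function(records, covariates, ties = c("breslow", "efron"),
                    standardize = TRUE) {
  ties <- match.arg(ties)
  stopifnot(all(c("time", "event") %in% names(records)))
  if (sum(records$event) < 1) stop("no events in the data")
  missing_cov <- setdiff(covariates, names(records))
  if (length(missing_cov))
    stop("missing covariate column(s): ", paste(missing_cov, collapse = ", "))
  X <- as.matrix(records[covariates])
  if (!is.numeric(X)) stop("covariates must be numeric")
  sds <- apply(X, 2L, stats::sd)
  dropped <- covariates[sds == 0]
  if (length(dropped)) {
    warning("constant covariate(s) dropped (coefficient undefined): ",
            paste(dropped, collapse = ", "))
    covariates <- setdiff(covariates, dropped)
    X <- X[, covariates, drop = FALSE]
  }
  if (ncol(X) == 0L) stop("no usable covariates")
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("rank-deficient design; collinear column(s): ",
         paste(covariates[qx$pivot[-seq_len(qx$rank)]], collapse = ", "))
  center <- if (standardize) colMeans(X) else rep(0, ncol(X))
  scl <- if (standardize) apply(X, 2L, stats::sd) else rep(1, ncol(X))
  Xs <- scale(X, center = center, scale = scl)
  dat <- data.frame(time = records$time, event = records$event, Xs)
  names(dat) <- c("time", "event", covariates)
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste0("`", covariates, "`", collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties,
                         control = survival::coxph.control(iter.max = 50))
  if (!is.null(fit$info) && grepl("did not converge", paste(fit$info, collapse = "")))
    stop("Cox fit did not converge")
  if (any(is.na(stats::coef(fit))))
    stop("Cox fit produced undefined coefficients")
  bh <- survival::basehaz(fit, centered = TRUE)  # covariates are centered at 0
  structure(
    list(coefficients = stats::coef(fit),
         loglik = fit$loglik[2L],
         loglik_null = fit$loglik[1L],
         basehaz = bh,
         center = center, scale = scl,
         covariates = covariates, dropped = dropped,
         ties = ties, standardize = standardize,
         n = nrow(dat), n_events = sum(dat$event),
         coxph = fit),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit>", x$n, "subjects,", x$n_events, "events; ties =", x$ties, "\n")
  print(round(x$coefficients, 4))
  cat("  partial log-likelihood:", format(x$loglik, digits = 6), "\n")
  invisible(x)
}

#' Linear predictor of a Cox fit
#'
#' \eqn{\eta_i = U_i^T\hat\gamma + \xi_i^T\hat\beta} on the fit's
#' standardized covariate scale.
#'
#' @param fit a [fit_cox()] result.
#' @param records data frame carrying the fit's covariate columns.
#' @return Numeric vector of linear predictors.
#' @export
linear_predictor <- function(fit, records) {
  stopifnot(inherits(fit, "cox_fit"))
  missing_cov <- setdiff(fit$covariates, names(records))
  if (length(missing_cov))
    stop("missing covariate column(s): ", paste(missing_cov, collapse = ", "))
  X <- as.matrix(records[fit$covariates])
  Xs <- scale(X, center = fit$center, scale = fit$scale)
  as.numeric(Xs %*% fit$coefficients)
}

#' Likelihood-ratio test for a joint spatial-heterogeneity effect
#'
#' Tests \eqn{H_0: \beta_1 = \dots = \beta_L = 0} (all score coefficients
#' zero) by comparing the full Cox model (clinical covariates + `L` scores)
#' with the restricted model (clinical covariates only) fitted to the same
#' records: statistic \eqn{2(\ell_{full} - \ell_{restricted})}, referred to
#' the upper tail of \eqn{\chi^2_L}.  When there are no clinical
#' covariates the restricted model is the null (empty) model.
#'
#' @param records data frame from [assemble_records()].
#' @param clinical_covariates character vector (possibly empty) of clinical
#'   covariate columns.
#' @param score_columns character vector of score columns (default: all
#'   `xi*` columns).
#' @param ... passed to [fit_cox()].
#' @return An object of class `spatial_lrt`: list with `statistic`, `df`,
#'   `p_value`, `fit_full`, `fit_restricted`.
#' @export
lrt_spatial_effect <- function(records, clinical_covariates = character(),
                               score_columns = NULL, ...) {
  if (is.null(score_columns))
    score_columns <- grep("^xi[0-9]+$", names(records), value = TRUE)
  if (length(score_columns) == 0L) stop("no score columns found")
  # scores that are identically zero contribute nothing: full == restricted
  full <- suppressWarnings(
    fit_cox(records, c(clinical_covariates, score_columns), ...))
  restricted <- if (length(clinical_covariates)) {
    fit_cox(records, clinical_covariates, ...)
  } else {
    # null model: partial log-likelihood with all coefficients 0
    list(loglik = full$loglik_null)
  }
  stat <- max(0, 2 * (full$loglik - restricted$loglik))
  df <- length(score_columns)
  structure(
    list(statistic = stat, df = df,
         p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
         fit_full = full, fit_restricted = restricted),
    class = "spatial_lrt")
}

#' @export
print.spatial_lrt <- function(x, ...) {
  cat("<spatial_lrt> LRT of all score coefficients jointly zero\n",
      " statistic =", format(x$statistic, digits = 5),
      " df =", x$df,
      " p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}
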