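# Delimited-table input, tidy outputs, configuration and pipeline
# orchestration.

#' Read a delimited cell table into cell patterns
#'
#' Expects one row per cell with x/y coordinates (microns), a cell-type
#' label and a subject identifier; column names are given explicitly in
#' `mapping` (no header-dialect guessing).  If an image-id column is
#' mapped and a subject has several images, the image with the maximum
#' number of cells is kept for that subject.  Subjects with fewer than two
#' cells are skipped with a warning.
#'
#' @param path CSV (`.csv`) or TSV (`.tsv`/`.txt`) file.
#' @param mapping named list with entries `x`, `y`, `type`, `subject` and
#'   optionally `image`, naming the corresponding columns.
#' @param levels optional cohort-wide label set passed to [cell_pattern()].
#' @return Named list of [cell_pattern()] objects, one per retained
#'   subject.
#' @export
read_cell_table <- function(path,
                            mapping = list(x = "x", y = "y",
                                           type = "cell_type",
                                           subject = "subject_id"),
                            levels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- unlist(mapping[c("x", "y", "type", "subject")])
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "),
         "; available: ", paste(names(df), collapse = ", "))
  for (cc in c("x", "y")) {
    v <- df[[mapping[[cc]]]]
    vn <- suppressWarnings(as.numeric(v))
    if (anyNA(vn)) {
      bad <- which(is.na(vn))[1L]
      stop("malformed numeric value in column '", mapping[[cc]],
           "', row ", bad, ": '", v[bad], "'")
    }
    df[[mapping[[cc]]]] <- vn
  }
  if (is.null(levels)) levels <- sort(unique(as.character(df[[mapping$type]])))
  patterns <- list()
  for (sid in unique(as.character(df[[mapping$subject]]))) {
    sub <- df[as.character(df[[mapping$subject]]) == sid, , drop = FALSE]
    if (!is.null(mapping$image) && mapping$image %in% names(df)) {
      tab <- table(sub[[mapping$image]])
      best <- names(tab)[which.max(tab)]  # image with the maximum cell count
      sub <- sub[sub[[mapping$image]] == best, , drop = FALSE]
    }
    if (nrow(sub) < 2L) {
      warning("subject ", sid, " has fewer than 2 cells; skipped")
      next
    }
    patterns[[sid]] <- cell_pattern(sub[[mapping$x]], sub[[mapping$y]],
                                    sub[[mapping$type]], subject_id = sid,
                                    levels = levels)
  }
  if (!length(patterns)) stop("no usable subjects in ", path)
  patterns
}

#' Compute SPI curves for a collection of patterns, tidily
#'
#' @param patterns list of [cell_pattern()]s.
#' @param K number of distance ranges.
#' @param ... passed to [spi_curve()].
#' @return List with `curves` (long data frame: `subject_id`, `k`, `d_lo`,
#'   `d_hi`, `midpoint`, `n_pairs`, `spi`, `residual`) and `totals` (one
#'   row per subject: `subject_id`, `H`, `SPI`, `HW`, `J`, `R`, `K`).
#' @export
spi_curves_table <- function(patterns, K = 50L, ...) {
  rows <- list(); tot <- list()
  for (p in patterns) {
    cv <- spi_curve(p, K = K, ...)
    rows[[p$subject_id]] <- cbind(subject_id = p$subject_id,
                                  as.data.frame(cv))
    t <- attr(cv, "totals")
    tot[[p$subject_id]] <- data.frame(
      subject_id = p$subject_id, H = t[["H"]], SPI = t[["SPI"]],
      HW = t[["HW"]], J = attr(cv, "J"), R = attr(cv, "R"), K = attr(cv, "K"))
  }
  list(curves = do.call(rbind, c(rows, make.row.names = FALSE)),
       totals = do.call(rbind, c(tot, make.row.names = FALSE)))
}

#' Validate a pipeline configuration
#'
#' Checks a configuration list (or YAML file) against the known schema
#' before any computation; unknown keys are rejected.
#'
#' @param config named list or path to a YAML file.
#' @return The validated configuration with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  defaults <- list(
    cells = NULL, clinical = NULL, out_dir = "funspi_out",
    columns = list(x = "x", y = "y", type = "cell_type",
                   subject = "subject_id", image = NULL),
    clinical_columns = list(subject = "subject_id", time = "time",
                            event = "event", covariates = list()),
    K = 50L, q_floor = 0.001, fve = 0.92,
    bandwidth_mean = "auto", bandwidth_cov = "auto",
    seed = 1L)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (cfg$K < 1 || cfg$K > 50) stop("K must be in 1..50")
  if (cfg$fve <= 0 || cfg$fve > 1) stop("fve must be in (0, 1]")
  cfg
}

#' Run the full pipeline: entropy curves, FPCA, survival LRT
#'
#' Executes the three analysis stages on delimited inputs and writes tidy
#' CSV/JSON artifacts plus a run manifest (config snapshot, package
#' version, seeds, input digests, timestamp) sufficient to reproduce the
#' run.
#'
#' @param config configuration list or YAML path (see [validate_config()]);
#'   `cells` and `clinical` must point to existing files.
#' @return Invisibly, a list with `curves`, `totals`, `fpca`, `lrt`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  if (is.null(cfg$cells) || is.null(cfg$clinical))
    stop("config must provide 'cells' and 'clinical' input paths")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  patterns <- read_cell_table(cfg$cells, mapping = cfg$columns)
  tab <- spi_curves_table(patterns, K = cfg$K, q_floor = cfg$q_floor)
  utils::write.csv(tab$curves, file.path(cfg$out_dir, "curves.csv"),
                   row.names = FALSE)
  jsonlite::write_json(tab$totals, file.path(cfg$out_dir, "totals.json"),
                       dataframe = "rows", digits = NA)

  sample <- curves_to_sample(tab$curves)
  fp <- fit_fpca(sample, fve = cfg$fve,
                 bandwidth_mean = cfg$bandwidth_mean,
                 bandwidth_cov = cfg$bandwidth_cov)
  scores_df <- data.frame(subject_id = rownames(fp$scores),
                          fp$scores[, seq_len(fp$L), drop = FALSE])
  utils::write.csv(scores_df, file.path(cfg$out_dir, "scores.csv"),
                   row.names = FALSE)

  ccol <- cfg$clinical_columns
  clin_raw <- utils::read.csv(cfg$clinical, stringsAsFactors = FALSE)
  covars <- unlist(ccol$covariates)
  clin <- data.frame(subject_id = clin_raw[[ccol$subject]],
                     time = clin_raw[[ccol$time]],
                     event = clin_raw[[ccol$event]])
  for (cv in covars) clin[[cv]] <- clin_raw[[cv]]
  records <- assemble_records(clin, fp$scores[, seq_len(fp$L), drop = FALSE],
                              covariates = covars)
  lrt <- lrt_spatial_effect(records, clinical_covariates = covars)
  report <- list(
    coefficients = as.list(lrt$fit_full$coefficients),
    loglik_full = lrt$fit_full$loglik,
    loglik_restricted = lrt$fit_restricted$loglik,
    lrt_statistic = lrt$statistic, df = lrt$df, p_value = lrt$p_value,
    n = lrt$fit_full$n, n_events = lrt$fit_full$n_events,
    fve = as.numeric(fp$cum_fve[fp$L]), L = fp$L)
  jsonlite::write_json(report, file.path(cfg$out_dir, "survtest.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package = "funspi",
    version = as.character(utils::packageVersion("funspi")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = cfg,
    inputs = list(cells = unname(tools::md5sum(cfg$cells)),
                  clinical = unname(tools::md5sum(cfg$clinical))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(curves = tab$curves, totals = tab$totals, fpca = fp,
                 lrt = lrt, manifest = manifest))
}
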