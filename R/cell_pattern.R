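#' Multitype cell point pattern
#'
#' Container for one subject's cells: planar coordinates (microns) plus a
#' categorical cell-type label per cell.  This is the raw input to the
#' spatial-entropy decomposition: the label set of size `J` defines the
#' cell-type variable whose pairwise co-occurrences are analysed over
#' distance.
#'
#' @param x,y numeric vectors of cell coordinates in microns.
#' @param type character or factor vector of cell-type labels, one per cell.
#' @param subject_id single string identifying the subject/image.
#' @param levels optional character vector declaring the full label set
#'   (size `J`).  Defaults to the sorted unique labels present.  Declaring
#'   levels explicitly matters when some types are absent from an image but
#'   present in the cohort.
#'
#' @return An object of class `cell_pattern`: a list with elements
#'   `subject_id`, `x`, `y`, `type` (factor with `J` levels) and `n`.
#' @examples
#' p <- cell_pattern(c(0, 1, 2), c(0, 0, 0), c("A", "B", "A"))
#' p$n
#' nlevels(p$type)
#' @export
cell_pattern <- function(x, y, type, subject_id = "subject", levels = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y) || length(x) != length(type))
    stop("x, y and type must have equal length")
  if (length(x) < 2L)
    stop("a cell pattern needs at least 2 cells")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("all coordinates must be finite")
  if (is.null(levels)) {
    levels <- if (is.factor(type)) base::levels(type) else sort(unique(as.character(type)))
  }
  type <- as.character(type)
  if (!all(type %in% levels))
    stop("cell-type labels outside the declared label set: ",
         paste(setdiff(unique(type), levels), collapse = ", "))
  if (length(levels) < 1L) stop("label set must contain at least one type")
  structure(
    list(subject_id = as.character(subject_id)[1L],
         x = x, y = y,
         type = factor(type, levels = levels),
         n = length(x)),
    class = "cell_pattern")
}

#' @export
print.cell_pattern <- function(x, ...) {
  cat("<cell_pattern> subject", x$subject_id, "-", x$n, "cells,",
      nlevels(x$type), "types\n")
  print(table(x$type))
  invisible(x)
}

#' Aspatial diversity indices of a cell pattern
#'
#' Shannon and Simpson diversity of the cell-type frequency distribution.
#' Both depend only on type proportions, not on where cells sit: any spatial
#' rearrangement of the same cells leaves them unchanged.  They serve as
#' space-blind baselines against which the spatial-entropy decomposition is
#' contrasted.
#'
#' @param pattern a [cell_pattern()].
#' @return Named numeric vector with `shannon` (nats) and `simpson`
#'   (Gini-Simpson, \eqn{1 - \sum p_j^2}).
#' @examples
#' p <- cell_pattern(runif(50), runif(50), sample(LETTERS[1:5], 50, TRUE))
#' diversity_baselines(p)
#' @export
diversity_baselines <- function(pattern) {
  stopifnot(inherits(pattern, "cell_pattern"))
  p <- as.numeric(table(pattern$type)) / pattern$n
  c(shannon = shannon_entropy(p), simpson = 1 - sum(p^2))
}
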