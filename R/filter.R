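#' Specification of an environmental-space occurrence filter
#'
#' Filtering partitions the environmental space spanned by the chosen filter
#' variables into hyper-rectangular cells of the given widths (in each
#' variable's native layer units) and keeps one record per occupied cell as
#' calibration data. The classic configuration for bioclimatic layers uses
#' widths of 200 units on temperature seasonality (bio4) and 200 mm on the
#' wettest- and driest-quarter precipitation (bio16, bio17).
#'
#' @param filter_variables Ordered variable labels.
#' @param cell_widths One positive width per variable, native units.
#' @param seed Integer seed for the within-cell representative draw.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(filter_variables = c("bio4", "bio16", "bio17"),
                        cell_widths = c(200, 200, 200), seed = 1L) {
  stopifnot(length(filter_variables) == length(cell_widths))
  if (any(cell_widths <= 0)) stop("filter cell widths must be > 0")
  structure(list(filter_variables = as.character(filter_variables),
                 cell_widths = as.numeric(cell_widths),
                 seed = as.integer(seed)),
            class = "filter_spec")
}

#' Split occurrences into balanced calibration and testing sets
#'
#' Environmental-space filtering: each filter variable's axis is divided into
#' bins of the configured width, anchored at that variable's observed minimum
#' over the input records (bin k covers `[min + k*w, min + (k+1)*w)`).
#' Records sharing every bin index occupy the same environmental cell; one
#' record per occupied cell — chosen uniformly at random under the filter
#' seed — goes to the calibration set, all others to the testing set. The
#' calibration count therefore equals the number of occupied cells and does
#' not depend on the seed; only which representative is kept does.
#'
#' @param env An `env_sample` whose rows correspond one-to-one with the
#'   records of `occ` and whose variables include the filter variables.
#' @param occ An `occurrence_set`.
#' @param spec A `filter_spec`.
#' @return An object of class `filter_result`: list with `calibration` and
#'   `testing` occurrence sets (roles set accordingly), matching
#'   `calibration_env` / `testing_env` samples, and `cell_assignment`, a
#'   data.frame mapping each input record to its environmental-cell index
#'   tuple and destination.
#' @export
filter_environmental <- function(env, occ, spec) {
  stopifnot(inherits(env, "env_sample"), inherits(occ, "occurrence_set"),
            inherits(spec, "filter_spec"))
  n <- nrow(env$matrix)
  if (n == 0) stop("empty occurrence set")
  if (n != n_occurrences(occ))
    stop("env rows (", n, ") do not match occurrence records (",
         n_occurrences(occ), ")")
  miss <- setdiff(spec$filter_variables, env$variable_names)
  if (length(miss))
    stop("filter variable(s) absent from env sample: ",
         paste(miss, collapse = ", "))
  bins <- vapply(seq_along(spec$filter_variables), function(i) {
    x <- env$matrix[, spec$filter_variables[i]]
    as.integer(floor((x - min(x)) / spec$cell_widths[i]))
  }, integer(n))
  if (n == 1L) bins <- matrix(bins, nrow = 1)
  colnames(bins) <- spec$filter_variables
  key <- apply(bins, 1, paste, collapse = "|")
  groups <- split(seq_len(n), key)
  calib_idx <- with_seed(spec$seed, {
    sort(vapply(groups, function(g)
      if (length(g) == 1L) g else g[sample.int(length(g), 1L)], integer(1)))
  })
  test_idx <- setdiff(seq_len(n), calib_idx)
  assignment <- data.frame(record = seq_len(n), bins,
                           cell = key,
                           set = ifelse(seq_len(n) %in% calib_idx,
                                        "calibration", "testing"),
                           stringsAsFactors = FALSE)
  structure(list(
    calibration = subset_occurrences(occ, calib_idx, role = "calibration"),
    testing = subset_occurrences(occ, test_idx, role = "testing"),
    calibration_env = subset_env(env, calib_idx),
    testing_env = if (length(test_idx)) subset_env(env, test_idx) else NULL,
    cell_assignment = assignment,
    spec = spec
  ), class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf(
    "filter_result: %d records -> %d calibration (occupied cells) + %d testing\n",
    nrow(x$cell_assignment), n_occurrences(x$calibration),
    n_occurrences(x$testing)))
  invisible(x)
}

#' Export a filter result as plain CSV files
#'
#' Writes the calibration and testing occurrence sets and the cell-assignment
#' audit table.
#'
#' @param fr A `filter_result`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
write_filter_result <- function(fr, dir, prefix = "occ") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, paste0(prefix, c("_calibration.csv", "_testing.csv",
                                       "_cells.csv")))
  write_occurrences(fr$calibration, p[1])
  write_occurrences(fr$testing, p[2])
  utils::write.csv(fr$cell_assignment, p[3], row.names = FALSE)
  invisible(p)
}

sample_stack_cells <- function(stack, n, seed) {
  cm <- stack_cell_matrix(stack)
  n_valid <- nrow(cm$matrix)
  if (n_valid == 0) stop("stack has no valid cells")
  i <- with_seed(seed, sample.int(n_valid, n, replace = TRUE))
  out <- env_sample(cm$matrix[i, , drop = FALSE], point_ids = i)
  attr(out, "cells") <- data.frame(row = cm$row[i], col = cm$col[i])
  out
}

#' Draw background points from the study extent
#'
#' Cells are drawn uniformly with replacement from the unmasked cells of the
#' stack; the returned sample carries each draw's cell coordinates in the
#' `"cells"` attribute for reporting. Background points characterize the
#' available environment in presence-background models.
#'
#' @param stack An `env_stack` with at least one valid cell.
#' @param n Number of draws (the classic configuration uses 10,000).
#' @param seed Integer seed.
#' @return An `env_sample` of `n` rows.
#' @export
sample_background <- function(stack, n = 10000, seed = 1L) {
  stopifnot(inherits(stack, "env_stack"), n >= 1)
  sample_stack_cells(stack, n, seed)
}

#' Draw pseudo-absences for model evaluation
#'
#' Identical sampling scheme to [sample_background()] but kept as a distinct
#' named operation because its count is tied to the testing-presence count:
#' evaluating with equally many presences and pseudo-absences fixes the
#' prevalence at 0.5.
#'
#' @param stack An `env_stack`.
#' @param n Number of pseudo-absences; must be >= 1 (prevalence is undefined
#'   for an empty absence set).
#' @param seed Integer seed.
#' @return An `env_sample` of `n` rows.
#' @export
sample_pseudoabsences <- function(stack, n, seed = 1L) {
  stopifnot(inherits(stack, "env_stack"))
  if (n < 1) stop("pseudo-absence count must be >= 1 (prevalence undefined)")
  sample_stack_cells(stack, n, seed)
}
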