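#' Project a fitted model onto a climate scenario
#'
#' Predicts suitability for every valid cell of the stack; masked cells stay
#' masked. No clamping is applied: maximum-entropy predictions extrapolate
#' freely outside the calibration range, and the number of extrapolating
#' cells (any variable outside its calibration min-max) is attached as
#' attribute `"n_extrapolated"` for auditing.
#'
#' @param model A `maxent_model` or `bioclim_model`.
#' @param stack An `env_stack` providing all model variables.
#' @param output Passed to [predict_maxent()] for maximum-entropy models.
#' @return An `env_raster` of continuous suitability.
#' @export
project <- function(model, stack, output = "logistic") {
  stopifnot(inherits(stack, "env_stack"))
  miss <- setdiff(model$variable_names, names(stack$layers))
  if (length(miss))
    stop("stack lacks model layer(s): ", paste(miss, collapse = ", "))
  cm <- stack_cell_matrix(stack)
  scores <- predict_suitability(model, env_sample(cm$matrix), output)
  vals <- matrix(NA_real_, stack$spec$n_rows, stack$spec$n_cols)
  vals[cbind(cm$row, cm$col)] <- scores
  out <- env_raster(stack$spec, vals,
                    name = paste0("suitability_", stack$scenario_name))
  if (inherits(model, "maxent_model")) {
    rng <- model$calib_range
    extra <- rep(FALSE, nrow(cm$matrix))
    for (v in model$variable_names)
      extra <- extra | cm$matrix[, v] < rng[1, v] | cm$matrix[, v] > rng[2, v]
    attr(out, "n_extrapolated") <- sum(extra)
  }
  out
}

#' Average an ensemble of continuous predictions
#'
#' Cell-wise arithmetic mean across aligned rasters — e.g. hindcasts driven
#' by different general circulation models. Averaging happens on the
#' continuous scale, before any thresholding.
#'
#' @param predictions List of aligned `env_raster` objects (>= 1).
#' @return An `env_raster`.
#' @export
ensemble_average <- function(predictions) {
  stopifnot(is.list(predictions), length(predictions) >= 1)
  spec <- predictions[[1]]$spec
  for (p in predictions[-1])
    if (!grids_aligned(spec, p$spec)) stop("ensemble rasters are not aligned")
  vals <- Reduce(`+`, lapply(predictions, function(p) p$values)) /
    length(predictions)
  env_raster(spec, vals, name = "ensemble_mean")
}

#' Threshold a continuous prediction into a binary range map
#'
#' A cell is suitable iff its value is greater than or equal to the
#' threshold (one convention, used everywhere: maps, omission, stability).
#'
#' @param suitability An `env_raster`.
#' @param threshold A `threshold_result` or numeric scalar.
#' @return An object of class `binary_map`: the grid spec plus an integer
#'   matrix with 1 = suitable, 0 = unsuitable, `NA` = nodata.
#' @export
binarize <- function(suitability, threshold) {
  stopifnot(inherits(suitability, "env_raster"))
  t <- if (inherits(threshold, "threshold_result")) threshold$threshold
       else threshold
  vals <- ifelse(is.na(suitability$values), NA_real_,
                 as.numeric(suitability$values >= t))
  structure(list(spec = suitability$spec, values = vals, threshold = t),
            class = "binary_map")
}

#' @export
print.binary_map <- function(x, ...) {
  cat(sprintf("binary_map: %d suitable / %d valid cells (threshold %.6g)\n",
              sum(x$values == 1, na.rm = TRUE),
              sum(!is.na(x$values)), x$threshold))
  invisible(x)
}

#' Classify range stability between two periods
#'
#' Compares a past and a present binary map cell by cell:
#' `stable` = suitable in both, `lost` = past only, `gained` = present only,
#' `never` = neither. Category counts always sum to the number of valid
#' cells.
#'
#' @param past,present Aligned `binary_map` objects.
#' @return An object of class `stability_map`: the spec, a categorical value
#'   matrix coded 0 = never, 1 = stable, 2 = lost, 3 = gained (`NA` nodata),
#'   and a named `counts` vector.
#' @export
stability_classify <- function(past, present) {
  stopifnot(inherits(past, "binary_map"), inherits(present, "binary_map"))
  if (!grids_aligned(past$spec, present$spec)) stop("maps are not aligned")
  p <- past$values
  q <- present$values
  vals <- ifelse(is.na(p) | is.na(q), NA_real_,
                 ifelse(p == 1 & q == 1, 1,
                        ifelse(p == 1, 2, ifelse(q == 1, 3, 0))))
  counts <- c(never = sum(vals == 0, na.rm = TRUE),
              stable = sum(vals == 1, na.rm = TRUE),
              lost = sum(vals == 2, na.rm = TRUE),
              gained = sum(vals == 3, na.rm = TRUE))
  structure(list(spec = past$spec, values = vals, counts = counts),
            class = "stability_map")
}

#' @export
print.stability_map <- function(x, ...) {
  cat("stability_map (cells): ",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a binary or stability map as an ESRI ASCII grid with a legend
#'
#' Integer codes: binary maps 0 = unsuitable, 1 = suitable; stability maps
#' 0 = never, 1 = stable, 2 = lost, 3 = gained. A plain-text sidecar
#' `<path>.legend.txt` documents the coding.
#'
#' @param map A `binary_map` or `stability_map`.
#' @param path Output path.
#' @export
write_map <- function(map, path) {
  r <- env_raster(map$spec, map$values, name = basename(path))
  write_raster(r, path)
  legend <- if (inherits(map, "stability_map"))
    c("0 never suitable", "1 stable", "2 lost (past only)",
      "3 gained (present only)", sprintf("%g nodata", map$spec$nodata_value))
  else
    c("0 unsuitable", "1 suitable", sprintf("%g nodata", map$spec$nodata_value))
  writeLines(legend, paste0(path, ".legend.txt"))
  invisible(path)
}

#' Change in host-parasite range overlap between two periods
#'
#' Overlap in a period is the proportion of the parasite's suitable cells
#' where the host is also suitable — the asymmetric quantity of interest:
#' where can the parasite find its host. The change is the absolute
#' difference between the two periods' overlaps, in percentage points. A
#' Jaccard overlap (intersection over union) is available as an alternative
#' normalization.
#'
#' @param parasite_past,host_past,parasite_present,host_present Aligned
#'   `binary_map` objects.
#' @param method `"parasite"` (default; denominator = parasite range) or
#'   `"jaccard"`.
#' @return List with `overlap_past`, `overlap_present` (proportions; `NA`
#'   with a flag when the parasite range is empty in a period) and
#'   `change_pct`.
#' @export
overlap_change <- function(parasite_past, host_past,
                           parasite_present, host_present,
                           method = c("parasite", "jaccard")) {
  method <- match.arg(method)
  maps <- list(parasite_past, host_past, parasite_present, host_present)
  for (m in maps) stopifnot(inherits(m, "binary_map"))
  for (m in maps[-1])
    if (!grids_aligned(maps[[1]]$spec, m$spec)) stop("maps are not aligned")
  ov <- function(par, hos) {
    p <- par$values == 1
    h <- hos$values == 1
    inter <- sum(p & h, na.rm = TRUE)
    denom <- if (method == "parasite") sum(p, na.rm = TRUE)
             else sum(p | h, na.rm = TRUE)
    if (denom == 0) NA_real_ else inter / denom
  }
  o_past <- ov(parasite_past, host_past)
  o_pres <- ov(parasite_present, host_present)
  list(overlap_past = o_past, overlap_present = o_pres,
       change_pct = abs(o_pres - o_past) * 100,
       undefined = is.na(o_past) || is.na(o_pres))
}

#' Turn a binary host map into a 0/1 predictor layer
#'
#' The host's thresholded presence becomes an additional predictor layer for
#' the parasite's model: 1 where the host is suitable, 0 where unsuitable,
#' nodata preserved. Build one layer per scenario so hindcasts use the
#' host's scenario-matched prediction. A constant layer (host suitable or
#' unsuitable everywhere) triggers a zero-variance warning.
#'
#' @param host_map A `binary_map`.
#' @param name Layer name (default `"host"`).
#' @return An `env_raster`.
#' @export
host_predictor_layer <- function(host_map, name = "host") {
  stopifnot(inherits(host_map, "binary_map"))
  v <- host_map$values[!is.na(host_map$values)]
  if (length(unique(v)) < 2)
    warning("host predictor layer has zero variance over the valid extent")
  env_raster(host_map$spec, host_map$values, name = name)
}

#' Add a layer to an existing stack
#' @param stack An `env_stack`.
#' @param layer An aligned `env_raster`.
#' @return A new `env_stack` (masks re-intersected).
#' @export
add_layer <- function(stack, layer) {
  env_stack(c(stack$layers, list(layer)),
            scenario_name = stack$scenario_name)
}

#' Fit, evaluate and compare parasite models with and without the host
#'
#' Runs the paired-model experiment at the heart of biotic-interaction
#' niche modelling: the parasite is modelled once from climate alone and
#' once from climate plus the host's 0/1 presence layer, on identical
#' occurrences, background cells and seeds, differing only by the host
#' predictor (which enters as a linear feature). Both models are evaluated,
#' their landscape-standardized AICc values and relative likelihoods
#' compared, and the cells suitable under climate-only but unsuitable once
#' the host is included are mapped.
#'
#' @param parasite_occ Raw parasite `occurrence_set`.
#' @param climate_stack Current-scenario `env_stack` (climate layers only).
#' @param host_layer 0/1 `env_raster` from [host_predictor_layer()].
#' @param fspec `filter_spec` for the calibration/testing split.
#' @param background_n Background sample size (default 10,000).
#' @param beta_multiplier Regularization multiplier (default 2).
#' @param seed Integer seed driving background, pseudo-absence and
#'   importance draws.
#' @param n_reps Permutation-importance repeats.
#' @return List of class `host_comparison`: `comparison` (data.frame with
#'   model, k, AICc, delta AICc, relative likelihood), `report_climate`,
#'   `report_host` (evaluation reports), `model_climate`, `model_host`,
#'   `difference_map` (`binary_map`, 1 where suitable under climate-only but
#'   unsuitable with the host), and the `filter` split used.
#' @export
compare_with_without_host <- function(parasite_occ, climate_stack, host_layer,
                                      fspec = filter_spec(),
                                      background_n = 10000,
                                      beta_multiplier = 2,
                                      seed = 1L, n_reps = 10L) {
  full_stack <- add_layer(climate_stack, host_layer)
  host_var <- host_layer$name
  # one extraction over the augmented stack keeps both designs on identical
  # records even if the host layer masks extra cells
  env_full <- extract_values(full_stack, parasite_occ)
  kept <- attr(env_full, "kept")
  occ_kept <- subset_occurrences(parasite_occ, kept)
  clim_vars <- setdiff(full_stack |> stack_variables(), host_var)
  drop_host <- function(env) env_sample(
    env$matrix[, clim_vars, drop = FALSE], env$point_ids)
  fr <- filter_environmental(drop_host(env_full), occ_kept, fspec)
  calib_full <- subset_env(env_full,
                           which(fr$cell_assignment$set == "calibration"))
  test_full <- subset_env(env_full,
                          which(fr$cell_assignment$set == "testing"))
  bg_full <- sample_background(full_stack, background_n, seed = seed)
  pa_full <- sample_pseudoabsences(full_stack, nrow(test_full$matrix),
                                   seed = seed + 1L)
  fit_one <- function(env_fun, lin_only) {
    fit_maxent(env_fun(calib_full), env_fun(bg_full),
               beta_multiplier = beta_multiplier, linear_only = lin_only)
  }
  m_clim <- fit_one(drop_host, character())
  m_host <- fit_one(identity, host_var)
  rep_clim <- evaluate_model(m_clim, drop_host(calib_full),
                             drop_host(test_full), drop_host(bg_full),
                             drop_host(pa_full), stack = climate_stack,
                             seed = seed, n_reps = n_reps)
  rep_host <- evaluate_model(m_host, calib_full, test_full, bg_full,
                             pa_full, stack = full_stack,
                             seed = seed, n_reps = n_reps)
  aiccs <- c(climate_only = rep_clim$aicc$aicc, climate_host = rep_host$aicc$aicc)
  rl <- relative_likelihood(aiccs)
  comparison <- data.frame(
    model = names(aiccs),
    k = c(rep_clim$k_parameters, rep_host$k_parameters),
    aicc = unname(aiccs),
    delta_aicc = unname(aiccs - min(aiccs, na.rm = TRUE)),
    rel_likelihood = unname(rl))
  map_clim <- binarize(project(m_clim, climate_stack), rep_clim$threshold)
  map_host <- binarize(project(m_host, full_stack), rep_host$threshold)
  diff_vals <- ifelse(is.na(map_clim$values) | is.na(map_host$values),
                      NA_real_,
                      as.numeric(map_clim$values == 1 & map_host$values == 0))
  structure(list(
    comparison = comparison,
    report_climate = rep_clim, report_host = rep_host,
    model_climate = m_clim, model_host = m_host,
    map_climate = map_clim, map_host = map_host,
    difference_map = structure(list(spec = map_clim$spec, values = diff_vals,
                                    threshold = NA_real_),
                               class = "binary_map"),
    filter = fr
  ), class = "host_comparison")
}

#' @export
print.host_comparison <- function(x, ...) {
  cat("Model comparison (with vs without host predictor):\n")
  print(x$comparison, row.names = FALSE)
  cat(sprintf("cells turning unsuitable after adding the host: %d\n",
              sum(x$difference_map$values == 1, na.rm = TRUE)))
  invisible(x)
}
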