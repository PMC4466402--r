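#' Fit a Bioclim percentile-envelope model
#'
#' Bioclim scores a site by how central its environment sits within the
#' calibration records' per-variable empirical distributions. Fitting simply
#' retains the sorted calibration values of every predictor. Variables with
#' fewer than two distinct calibration values are flagged degenerate (they
#' still score: any value equal to the single calibration value is maximally
#' central, anything else falls outside the envelope).
#'
#' @param calib An `env_sample` of calibration records (>= 2 rows).
#' @return An object of class `bioclim_model`.
#' @export
fit_bioclim <- function(calib) {
  stopifnot(inherits(calib, "env_sample"))
  if (nrow(calib$matrix) < 2) stop("need at least 2 calibration records")
  vals <- lapply(seq_len(ncol(calib$matrix)),
                 function(j) sort(calib$matrix[, j]))
  names(vals) <- calib$variable_names
  degen <- vapply(vals, function(v) length(unique(v)) < 2, logical(1))
  if (any(degen))
    warning("degenerate (constant) calibration variable(s): ",
            paste(names(vals)[degen], collapse = ", "))
  structure(list(values = vals, variable_names = calib$variable_names,
                 degenerate = degen, n = nrow(calib$matrix)),
            class = "bioclim_model")
}

#' @export
print.bioclim_model <- function(x, ...) {
  cat(sprintf("bioclim_model: %d calibration records, %d variables (%s)\n",
              x$n, length(x$values), paste(x$variable_names, collapse = ", ")))
  invisible(x)
}

# Tail-percentile score of points x against sorted calibration values v.
# F uses a midrank tie convention rescaled so the exact calibration minimum
# and maximum score 2/(n+1) rather than 0 (non-zero envelope edges):
#   F(x) = (#{v < x} + 0.5 #{v = x} + 0.5) / (n + 1)
# score = 2 * min(F, 1 - F) clipped to [0, 1]; outside [min(v), max(v)] -> 0.
bioclim_var_score <- function(x, v) {
  n <- length(v)
  n_lt <- findInterval(x, v, left.open = TRUE)   # strictly less than x
  n_le <- findInterval(x, v)                     # less than or equal
  f <- (n_lt + 0.5 * (n_le - n_lt) + 0.5) / (n + 1)
  s <- pmin(pmax(2 * pmin(f, 1 - f), 0), 1)
  s[x < v[1] | x > v[n]] <- 0
  s
}

#' Predict Bioclim suitability scores
#'
#' Per point and variable, the tail percentile `p = min(F(x), 1 - F(x))` of
#' the calibration empirical CDF (midrank tie convention) gives a variable
#' score `2p` in \[0, 1\]; the point score is the minimum over variables.
#' Any variable outside its calibration min-max range forces a score of 0;
#' the score at the exact calibration minimum or maximum is `2/(n+1)`, not 0.
#'
#' @param model A `bioclim_model`.
#' @param env An `env_sample` providing at least the model's variables.
#' @return Numeric vector of suitability scores in \[0, 1\], one per row.
#' @export
predict_bioclim <- function(model, env) {
  stopifnot(inherits(model, "bioclim_model"), inherits(env, "env_sample"))
  miss <- setdiff(model$variable_names, env$variable_names)
  if (length(miss))
    stop("env sample lacks model variable(s): ", paste(miss, collapse = ", "))
  scores <- vapply(model$variable_names, function(v)
    bioclim_var_score(env$matrix[, v], model$values[[v]]),
    numeric(nrow(env$matrix)))
  if (nrow(env$matrix) == 1L) scores <- matrix(scores, nrow = 1)
  apply(scores, 1, min)
}
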