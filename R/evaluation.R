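#' Rank-based AUC for presence vs (pseudo-)absence scores
#'
#' Area under the receiver-operating-characteristic curve computed as the
#' Mann-Whitney statistic: the probability that a random presence outscores a
#' random absence, with ties counted one half.
#'
#' @param presence_scores,absence_scores Nonempty numeric score vectors.
#' @return Scalar in \[0, 1\].
#' @export
auc <- function(presence_scores, absence_scores) {
  n1 <- length(presence_scores)
  n2 <- length(absence_scores)
  if (n1 == 0 || n2 == 0) stop("both score lists must be nonempty")
  r <- rank(c(presence_scores, absence_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Threshold maximizing sensitivity plus specificity
#'
#' Scans candidate thresholds — midpoints between consecutive distinct pooled
#' scores, plus -Inf and +Inf sentinels — under the prediction rule
#' "suitable iff score >= threshold", and returns the threshold maximizing
#' sensitivity + specificity. Ties among maxima are broken toward the lowest
#' threshold.
#'
#' @param presence_scores,absence_scores Nonempty numeric score vectors.
#' @return An object of class `threshold_result`: list with `threshold`,
#'   `sensitivity`, `specificity` (the pair attained at the threshold).
#' @export
max_sss_threshold <- function(presence_scores, absence_scores) {
  if (!length(presence_scores) || !length(absence_scores))
    stop("both score lists must be nonempty")
  pooled <- sort(unique(c(presence_scores, absence_scores)))
  cands <- c(-Inf,
             if (length(pooled) > 1)
               (pooled[-length(pooled)] + pooled[-1]) / 2,
             Inf)
  sp <- sort(presence_scores)
  sa <- sort(absence_scores)
  sens <- (length(sp) - findInterval(cands, sp)) / length(sp)
  # -Inf sentinel: every score >= -Inf
  sens[1] <- 1
  spec <- findInterval(cands, sa) / length(sa)
  spec[1] <- 0
  best <- which.max(sens + spec)  # which.max takes the first (lowest) maximum
  structure(list(threshold = cands[best],
                 sensitivity = sens[best], specificity = spec[best]),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("threshold %.6g (sensitivity %.3f, specificity %.3f)\n",
              x$threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' Omission rate of test presences at a threshold
#'
#' Fraction of test presences predicted unsuitable (score strictly below the
#' threshold).
#'
#' @param test_presence_scores Nonempty numeric vector.
#' @param threshold A `threshold_result` or numeric scalar.
#' @return Proportion in \[0, 1\].
#' @export
omission_rate <- function(test_presence_scores, threshold) {
  if (!length(test_presence_scores)) stop("score list must be nonempty")
  t <- if (inherits(threshold, "threshold_result")) threshold$threshold
       else threshold
  mean(test_presence_scores < t)
}

#' Small-sample AIC for a presence-background model
#'
#' Takes the model's raw (Gibbs) scores standardized to sum to 1 over the
#' prediction extent's valid cells, so each occurrence's score is a
#' probability over the landscape. Then `logL = sum(log p_i)`,
#' `AIC = 2k - 2 logL` and `AICc = AIC + 2k(k+1)/(n-k-1)`; AICc is undefined
#' (NA, with `defined = FALSE`) when `n <= k + 1`. A zero standardized score
#' at an occurrence (outside model support) also yields an undefined result,
#' with a diagnostic.
#'
#' @param occurrence_std_scores Standardized raw scores at the (calibration)
#'   occurrences; see [standardize_raw_scores()].
#' @param n Occurrence count used for the correction (defaults to the score
#'   count).
#' @param k Parameter count, e.g. [count_parameters()].
#' @return An object of class `aicc_result`: list with `log_lik`, `k`, `n`,
#'   `aic`, `aicc`, `defined`, and `reason` when undefined.
#' @export
aicc <- function(occurrence_std_scores, k, n = length(occurrence_std_scores)) {
  if (!length(occurrence_std_scores)) stop("no occurrence scores")
  if (any(occurrence_std_scores <= 0))
    return(structure(list(log_lik = NA_real_, k = k, n = n,
                          aic = NA_real_, aicc = NA_real_, defined = FALSE,
                          reason = "zero raw score at an occurrence (outside model support)"),
                     class = "aicc_result"))
  ll <- sum(log(occurrence_std_scores))
  aic <- 2 * k - 2 * ll
  if (n <= k + 1)
    return(structure(list(log_lik = ll, k = k, n = n, aic = aic,
                          aicc = NA_real_, defined = FALSE,
                          reason = sprintf("n (%d) <= k + 1 (%d)", n, k + 1)),
                     class = "aicc_result"))
  structure(list(log_lik = ll, k = k, n = n, aic = aic,
                 aicc = aic + 2 * k * (k + 1) / (n - k - 1),
                 defined = TRUE, reason = NULL),
            class = "aicc_result")
}

#' @export
print.aicc_result <- function(x, ...) {
  if (x$defined)
    cat(sprintf("AICc %.4f (AIC %.4f, logL %.4f, k %d, n %d)\n",
                x$aicc, x$aic, x$log_lik, x$k, x$n))
  else cat("AICc undefined:", x$reason, "\n")
  invisible(x)
}

#' Standardize raw model scores over a prediction extent
#'
#' Renormalizes the raw (Gibbs) prediction so it sums to 1 over the valid
#' cells of the given scenario stack — the landscape, not the background
#' sample, is the standardization extent — and returns the standardized
#' scores at the supplied occurrence environments.
#'
#' @param model A `maxent_model`.
#' @param stack The scenario `env_stack` defining the extent.
#' @param occ_env `env_sample` at the occurrences.
#' @return Numeric vector of standardized scores (landscape probabilities).
#' @export
standardize_raw_scores <- function(model, stack, occ_env) {
  cm <- stack_cell_matrix(stack)
  land <- predict_maxent(model, env_sample(cm$matrix), output = "raw")
  occ_raw <- predict_maxent(model, occ_env, output = "raw")
  occ_raw / sum(land)
}

#' Relative likelihood of models from their AICc values
#'
#' `exp((AICc_min - AICc_j) / 2)`: 1 for the best model, in (0, 1\] for the
#' others. Undefined AICc values propagate as NA; at least two defined values
#' are required.
#'
#' @param aicc_values Numeric vector (NA allowed) or list of `aicc_result`.
#' @return Numeric vector of relative likelihoods, same length and names.
#' @export
relative_likelihood <- function(aicc_values) {
  if (is.list(aicc_values))
    aicc_values <- vapply(aicc_values, function(a)
      if (inherits(a, "aicc_result")) a$aicc else as.numeric(a), numeric(1))
  if (sum(!is.na(aicc_values)) < 2)
    stop("need at least 2 defined AICc values")
  exp((min(aicc_values, na.rm = TRUE) - aicc_values) / 2)
}

predict_suitability <- function(model, env, output = "logistic") {
  if (inherits(model, "maxent_model")) predict_maxent(model, env, output)
  else if (inherits(model, "bioclim_model")) predict_bioclim(model, env)
  else stop("unsupported model class")
}

#' Permutation importance of each predictor variable
#'
#' For each model variable, the variable's values are permuted jointly across
#' the pooled presence + background rows (one permutation per repeat), the
#' model re-predicts, and the training AUC drop relative to the unpermuted
#' AUC is recorded. Importance is the mean drop over repeats, floored at 0
#' and normalized to sum to 100. A variable whose features all have zero
#' coefficients cannot change predictions and scores 0.
#'
#' @param model A fitted `maxent_model` or `bioclim_model`.
#' @param presences,background `env_sample` objects.
#' @param seed Integer seed for the permutations.
#' @param n_reps Permutation repeats per variable (default 10).
#' @return Named percentage vector summing to 100 (all-zero drops: zeros,
#'   with attribute `degenerate = TRUE`); attribute `"mean_drops"` carries
#'   the unnormalized mean AUC drops.
#' @export
permutation_importance <- function(model, presences, background,
                                   seed = 1L, n_reps = 10L) {
  vars <- model$variable_names
  np <- nrow(presences$matrix)
  pooled <- rbind(presences$matrix[, vars, drop = FALSE],
                  background$matrix[, vars, drop = FALSE])
  base_auc <- auc(predict_suitability(model, subset_rows_sample(pooled, seq_len(np))),
                  predict_suitability(model, subset_rows_sample(pooled, -seq_len(np))))
  drops <- with_seed(seed, {
    vapply(vars, function(v) {
      mean(vapply(seq_len(n_reps), function(r) {
        perm <- pooled
        perm[, v] <- perm[sample.int(nrow(perm)), v]
        a <- auc(predict_suitability(model, subset_rows_sample(perm, seq_len(np))),
                 predict_suitability(model, subset_rows_sample(perm, -seq_len(np))))
        base_auc - a
      }, numeric(1)))
    }, numeric(1))
  })
  floored <- pmax(drops, 0)
  total <- sum(floored)
  out <- if (total > 0) 100 * floored / total
         else structure(floored * 0, degenerate = TRUE)
  attr(out, "mean_drops") <- drops
  out
}

# Wrap a plain matrix (or row subset of one) as an env_sample.
subset_rows_sample <- function(m, i) {
  env_sample(m[i, , drop = FALSE])
}

#' Per-variable contribution from model coefficients
#'
#' The share of total absolute coefficient mass (on the normalized feature
#' scale) attributable to each variable's features, normalized to sum to
#' 100. Product features split their mass equally between their two
#' variables. This is a transparent surrogate for the training-path "percent
#' contribution" bookkeeping of the classic MaxEnt implementation, which is
#' not replicated here; because coefficients act on SD-normalized features,
#' the measure is invariant to rescaling any raw input variable.
#'
#' @param model A `maxent_model`.
#' @return Named percentage vector over the model's variables (attribute
#'   `degenerate = TRUE` and all zeros for an all-zero model).
#' @export
variable_contribution <- function(model) {
  stopifnot(inherits(model, "maxent_model"))
  mass <- stats::setNames(numeric(length(model$variable_names)),
                          model$variable_names)
  for (f in names(model$coefficients)) {
    vs <- model$feature_vars[[f]]
    mass[vs] <- mass[vs] + abs(model$coefficients[[f]]) / length(vs)
  }
  total <- sum(mass)
  if (total == 0) return(structure(mass, degenerate = TRUE))
  100 * mass / total
}

#' Evaluate a fitted niche model
#'
#' Assembles the standard report: training AUC (calibration presences vs
#' background), testing AUC (test presences vs an equal number of
#' pseudo-absences — prevalence 0.5 is enforced structurally), the
#' max-sensitivity-plus-specificity threshold computed on the test scores,
#' the omission rate of test presences at that threshold, the parameter
#' count and landscape-standardized AICc (maximum-entropy models only;
#' the envelope model defines no likelihood), and both variable-importance
#' tables.
#'
#' @param model A `maxent_model` or `bioclim_model`.
#' @param calibration_env,testing_env Presence `env_sample`s.
#' @param background Background `env_sample` (training contrast).
#' @param pseudoabsences Evaluation `env_sample`; must have exactly as many
#'   rows as `testing_env`.
#' @param stack Scenario `env_stack` used for AICc standardization (maximum-
#'   entropy models).
#' @param seed Seed for permutation importance.
#' @param n_reps Permutation repeats.
#' @return An object of class `evaluation_report`.
#' @export
evaluate_model <- function(model, calibration_env, testing_env, background,
                           pseudoabsences, stack = NULL, seed = 1L,
                           n_reps = 10L) {
  if (nrow(pseudoabsences$matrix) != nrow(testing_env$matrix))
    stop("pseudo-absence count must equal testing-presence count ",
         "(prevalence 0.5)")
  train_p <- predict_suitability(model, calibration_env)
  train_b <- predict_suitability(model, background)
  test_p <- predict_suitability(model, testing_env)
  test_a <- predict_suitability(model, pseudoabsences)
  thr <- max_sss_threshold(test_p, test_a)
  is_mx <- inherits(model, "maxent_model")
  ic <- NULL
  if (is_mx && !is.null(stack)) {
    std <- standardize_raw_scores(model, stack,
                                  env_sample(calibration_env$matrix))
    ic <- aicc(std, k = count_parameters(model))
  }
  structure(list(
    train_auc = auc(train_p, train_b),
    test_auc = auc(test_p, test_a),
    omission_rate = omission_rate(test_p, thr),
    threshold = thr,
    n_occurrences = nrow(calibration_env$matrix),
    k_parameters = if (is_mx) count_parameters(model) else NA_integer_,
    aicc = ic,
    variable_contribution = if (is_mx) variable_contribution(model) else NULL,
    permutation_importance = permutation_importance(
      model, calibration_env, background, seed = seed, n_reps = n_reps)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Training occurrences\t%d\n", x$n_occurrences))
  cat(sprintf("Training AUC\t%.3f\n", x$train_auc))
  if (!is.null(x$variable_contribution)) {
    cat("Individual contribution of the variables (%)\n")
    for (v in names(x$variable_contribution))
      cat(sprintf("  %s\t%.3f\n", v, x$variable_contribution[[v]]))
  }
  cat("Permutation importance of the variables (%)\n")
  for (v in names(x$permutation_importance))
    cat(sprintf("  %s\t%.3f\n", v, x$permutation_importance[[v]]))
  cat(sprintf("Testing AUC\t%.3f\n", x$test_auc))
  cat(sprintf("Omission rate\t%.3f\n", x$omission_rate))
  if (!is.na(x$k_parameters)) cat(sprintf("Parameters (k)\t%d\n", x$k_parameters))
  if (!is.null(x$aicc) && x$aicc$defined)
    cat(sprintf("AICc\t%.3f\n", x$aicc$aicc))
  invisible(x)
}

#' Export an evaluation report as a CSV table
#' @param report An `evaluation_report`.
#' @param path Output file path.
#' @export
write_evaluation_report <- function(report, path) {
  rows <- data.frame(
    quantity = c("n_occurrences", "train_auc", "test_auc", "omission_rate",
                 "threshold", "k_parameters",
                 if (!is.null(report$aicc)) "aicc",
                 paste0("contribution_", names(report$variable_contribution)),
                 paste0("perm_importance_", names(report$permutation_importance))),
    value = c(report$n_occurrences, report$train_auc, report$test_auc,
              report$omission_rate, report$threshold$threshold,
              report$k_parameters,
              if (!is.null(report$aicc)) report$aicc$aicc,
              unname(report$variable_contribution),
              unname(report$permutation_importance)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
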