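test_that("AUC equals the pairwise win/tie count and its symmetry holds", {
  expect_equal(auc(c(0.8, 0.9), c(0.1, 0.2)), 1)
  expect_equal(auc(rep(0.5, 10), rep(0.5, 7)), 0.5)
  set.seed(1)
  for (rep in 1:5) {
    p <- round(runif(30), 2)  # rounding forces ties
    a <- round(runif(30), 2)
    wins <- sum(outer(p, a, ">")) + 0.5 * sum(outer(p, a, "=="))
    expect_equal(auc(p, a), wins / 900)
    expect_equal(auc(p, a) + auc(a, p), 1)
  }
  # cross-check against an established ROC implementation
  set.seed(2)
  p <- runif(40); a <- runif(35)
  expect_equal(auc(p, a),
               as.numeric(pROC::auc(pROC::roc(
                 response = rep(1:0, c(40, 35)), predictor = c(p, a),
                 quiet = TRUE, direction = "<"))))
  expect_error(auc(numeric(0), a), "nonempty")
})

test_that("maxSSS threshold matches an exhaustive scan", {
  brute <- function(p, a) {
    cands <- c(-Inf, sort(unique(c(p, a))), Inf)
    # scan every candidate and every midpoint
    cands <- sort(unique(c(cands, (head(cands[-1], -1) + tail(cands[-1], -1)) / 2)))
    best <- -Inf
    for (t in cands) {
      v <- mean(p >= t) + mean(a < t)
      if (v > best) best <- v
    }
    best
  }
  # separable scores: perfect sensitivity and specificity at the lowest midpoint
  tr <- max_sss_threshold(c(0.7, 0.9), c(0.1, 0.3))
  expect_equal(tr$sensitivity, 1)
  expect_equal(tr$specificity, 1)
  expect_equal(tr$threshold, 0.5)
  set.seed(7)
  for (rep in 1:10) {
    p <- round(runif(15), 1)
    a <- round(runif(12), 1)
    got <- max_sss_threshold(p, a)
    expect_equal(got$sensitivity + got$specificity, brute(p, a))
    expect_equal(mean(p >= got$threshold), got$sensitivity)
    expect_equal(mean(a < got$threshold), got$specificity)
    # the all-suitable sentinel guarantees objective >= 1
    expect_gte(got$sensitivity + got$specificity, 1)
    # duplicating a presence score never changes the optimum objective
    got2 <- max_sss_threshold(c(p, p[1]), a)
    expect_equal(got2$sensitivity + got2$specificity, brute(c(p, p[1]), a))
  }
})

test_that("omission rate is the sub-threshold presence fraction", {
  expect_equal(omission_rate(c(0.6, 0.7, 0.8), 0.5), 0)
  expect_equal(omission_rate(c(0.1, 0.2), 0.5), 1)
  set.seed(3)
  s <- runif(50)
  expect_equal(omission_rate(s, 0.42), sum(s < 0.42) / 50)
})

test_that("AICc follows the small-sample formula with its boundary rules", {
  std <- c(0.1, 0.2, 0.05)                 # standardized landscape scores
  # hand-computed: logL = ln(0.001); k = 1, n = 3
  r1 <- aicc(std, k = 1)
  expect_true(r1$defined)
  expect_equal(r1$log_lik, log(0.001))
  expect_equal(r1$aic, 2 - 2 * log(0.001))
  expect_equal(r1$aicc, 2 - 2 * log(0.001) + 4 / 1)
  # n = k + 1: undefined, never infinite
  r2 <- aicc(std, k = 2)
  expect_false(r2$defined)
  expect_true(is.na(r2$aicc))
  # undefined exactly when n <= k + 1
  for (k in 0:5)
    expect_equal(aicc(runif(4, 0.01, 0.1), k = k)$defined, 4 > k + 1)
  # zero support at an occurrence
  r3 <- aicc(c(0.1, 0), k = 1)
  expect_false(r3$defined)
  expect_match(r3$reason, "support")
  # strictly increasing in k at fixed likelihood
  ks <- sapply(1:5, function(k) aicc(rep(0.02, 20), k = k)$aicc)
  expect_true(all(diff(ks) > 0))
})

test_that("AICc standardization is invariant to the raw normalization constant", {
  set.seed(11)
  stack <- make_test_stack(seed = 11)
  B <- sample_background(stack, 400, seed = 1)
  P <- subset_env(sample_background(stack, 30, seed = 2), 1:30)
  m <- fit_maxent(P, B)
  std <- standardize_raw_scores(m, stack, P)
  expect_equal(sum(standardize_raw_scores(
    m, stack, env_sample(stack_cell_matrix(stack)$matrix))), 1)
  # scaling the raw output (via log-partition shift) leaves standardized
  # scores unchanged
  m2 <- m
  m2$log_partition <- m$log_partition + log(7)
  expect_equal(standardize_raw_scores(m2, stack, P), std)
})

test_that("relative likelihood is exp(-delta/2) with NA propagation", {
  expect_equal(relative_likelihood(c(100, 100, 100)), rep(1, 3))
  rl <- relative_likelihood(c(10, 12))
  expect_equal(rl, c(1, exp(-1)))
  expect_equal(unname(relative_likelihood(c(a = 5, b = NA, c = 7))[2]),
               NA_real_)
  expect_error(relative_likelihood(c(1, NA)), "at least 2")
})

test_that("permutation importance isolates the variables a model uses", {
  set.seed(21)
  B <- cbind(bio4 = rnorm(400), bio16 = rnorm(400), bio17 = rnorm(400))
  P <- cbind(bio4 = rnorm(80, 1.2, 0.5), bio16 = rnorm(80),
             bio17 = rnorm(80))
  m <- fit_maxent(env_sample(P), env_sample(B))
  pim <- permutation_importance(m, env_sample(P), env_sample(B),
                                seed = 1, n_reps = 5)
  expect_equal(sum(pim), 100, tolerance = 0.01)
  # variables with all-zero coefficients cannot matter
  zeroed <- names(which(sapply(c("bio16", "bio17"), function(v)
    all(m$coefficients[startsWith(names(m$coefficients), v)] == 0))))
  for (v in zeroed) expect_equal(unname(pim[v]), 0)

  # a single-variable model concentrates all importance
  m1 <- fit_maxent(env_sample(P[, "bio4", drop = FALSE]),
                   env_sample(B[, "bio4", drop = FALSE]))
  pim1 <- permutation_importance(m1, env_sample(P[, "bio4", drop = FALSE]),
                                 env_sample(B[, "bio4", drop = FALSE]),
                                 seed = 1, n_reps = 3)
  expect_equal(as.numeric(pim1), 100)
})

test_that("symmetric two-variable signals get symmetric importance", {
  set.seed(31)
  # exactly exchangeable design: the second column is the reversed first, so
  # swapping variables maps the dataset onto itself and the fitted optimum
  # treats both variables identically
  b1 <- rnorm(600)
  p1 <- rnorm(120, 1, 0.6)
  B <- cbind(bio4 = b1, bio16 = rev(b1))
  P <- cbind(bio4 = p1, bio16 = rev(p1))
  m <- fit_maxent(env_sample(P), env_sample(B), beta_multiplier = 1)
  pim <- permutation_importance(m, env_sample(P), env_sample(B),
                                seed = 2, n_reps = 20)
  expect_lt(abs(pim[["bio4"]] - pim[["bio16"]]), 5 * 2)  # +/-5 per variable
})

test_that("variable contribution reflects coefficient mass, scale-free", {
  set.seed(41)
  B <- cbind(bio4 = rnorm(300), bio16 = rnorm(300))
  P <- cbind(bio4 = rnorm(60, 1.5, 0.4), bio16 = rnorm(60))
  m <- fit_maxent(env_sample(P), env_sample(B))
  vc <- variable_contribution(m)
  expect_equal(sum(vc), 100, tolerance = 0.01)
  # refit with bio16 rescaled by 1000: contributions unchanged
  scale_col <- function(X) { X[, "bio16"] <- X[, "bio16"] * 1000; X }
  m2 <- fit_maxent(env_sample(scale_col(P)), env_sample(scale_col(B)))
  expect_equal(variable_contribution(m2), vc, tolerance = 1e-6)
  # an all-zero model is flagged degenerate
  mz <- fit_maxent(env_sample(P), env_sample(B), beta_multiplier = 1e6)
  vz <- variable_contribution(mz)
  expect_true(all(vz == 0))
  expect_true(attr(vz, "degenerate"))
})

test_that("evaluation reports enforce prevalence 0.5 and assemble cleanly", {
  stack <- make_test_stack(seed = 51, n_rows = 25, n_cols = 25,
                           mask_cells = 40)
  niche <- true_niche(c(bio4 = 120, bio16 = 230), c(bio4 = 10, bio16 = 15))
  suit <- true_suitability(niche, stack)
  occ <- sample_occurrences(suit, 80, seed = 3)
  env <- extract_values(stack, occ)
  set.seed(4)
  fr <- filter_environmental(env, subset_occurrences(occ, attr(env, "kept")),
                             filter_spec(filter_variables = c("bio4", "bio16"),
                                         cell_widths = c(10, 10), seed = 2))
  bg <- sample_background(stack, 1500, seed = 5)
  pa <- sample_pseudoabsences(stack, n_occurrences(fr$testing), seed = 6)
  m <- fit_maxent(fr$calibration_env, bg)
  expect_error(evaluate_model(m, fr$calibration_env, fr$testing_env, bg,
                              subset_env(pa, 1:3), stack),
               "prevalence")
  rep_mx <- evaluate_model(m, fr$calibration_env, fr$testing_env, bg, pa,
                           stack = stack, n_reps = 3)
  expect_s3_class(rep_mx, "evaluation_report")
  expect_true(rep_mx$train_auc > 0.5)
  expect_equal(rep_mx$k_parameters, count_parameters(m))
  expect_true(rep_mx$aicc$defined)
  expect_equal(sum(rep_mx$permutation_importance), 100, tolerance = 0.01)
  # the envelope model gets no information criterion
  bc <- fit_bioclim(fr$calibration_env)
  rep_bc <- evaluate_model(bc, fr$calibration_env, fr$testing_env, bg, pa,
                           n_reps = 3)
  expect_null(rep_bc$aicc)
  expect_true(is.na(rep_bc$k_parameters))
})
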