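# Feature construction for the maximum-entropy model.
#
# Features default to linear + quadratic per variable; pairwise products are
# available but off by default, and variables named in `linear_only` (e.g. a
# binary host-presence predictor) get a linear feature only. Returns the raw
# feature matrix plus a map from feature to source variable(s).
build_features <- function(X, quadratic = TRUE, products = FALSE,
                           linear_only = character()) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  vars <- colnames(X)
  feats <- list()
  fvar <- list()
  for (v in vars) {
    feats[[v]] <- X[, v]
    fvar[[v]] <- v
    if (quadratic && !(v %in% linear_only)) {
      nm <- paste0(v, "^2")
      feats[[nm]] <- X[, v]^2
      fvar[[nm]] <- v
    }
  }
  if (products && length(vars) > 1) {
    for (i in seq_len(length(vars) - 1)) for (j in (i + 1):length(vars)) {
      if (any(c(vars[i], vars[j]) %in% linear_only)) next
      nm <- paste0(vars[i], "*", vars[j])
      feats[[nm]] <- X[, vars[i]] * X[, vars[j]]
      fvar[[nm]] <- c(vars[i], vars[j])
    }
  }
  m <- do.call(cbind, feats)
  if (nrow(X) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(feats)))
  list(matrix = m, feature_vars = fvar)
}

maxent_objective <- function(beta, Zp, Zb, lambda) {
  eta_p <- drop(Zp %*% beta)
  eta_b <- drop(Zb %*% beta)
  -mean(eta_p) + log_sum_exp(eta_b) + sum(lambda * abs(beta))
}

#' Fit an L1-regularized maximum-entropy niche model
#'
#' Fits the Gibbs distribution over the background sample whose features
#' match the presence sample's feature means, i.e. maximizes the penalized
#' presence log-likelihood
#' \deqn{\frac{1}{m}\sum_i \eta(x_i) - \log \sum_b e^{\eta(x_b)} -
#'   \sum_j \lambda_j |\beta_j|}
#' where \eqn{\eta(x) = \beta^\top f(x)} over normalized features. The
#' per-feature penalty is \eqn{\lambda_j = \beta_{mult} \, s_j / \sqrt{m}}
#' with \eqn{s_j} the feature's sample SD over presences plus background and
#' \eqn{m} the presence count; on SD-normalized features this is the uniform
#' \eqn{\beta_{mult}/\sqrt m}. The beta multiplier scales the overall
#' regularization: larger values shrink more coefficients to exactly zero,
#' restraining model complexity.
#'
#' Optimization is cyclic coordinate descent with per-coordinate Newton steps
#' and soft-thresholding, with backtracking so the penalized objective is
#' non-increasing across iterations (the objective trace is stored on the
#' model). Convergence is declared when the largest coefficient change in a
#' sweep falls below `tol_coef` or the objective change below `tol_obj`.
#'
#' Constant (degenerate) features — e.g. from an inert decoy variable or an
#' all-suitable host layer — are kept at coefficient zero with a warning.
#'
#' @param presences An `env_sample` of presence records (>= 2 rows).
#' @param background An `env_sample` of background records, same variables.
#' @param beta_multiplier Positive regularization multiplier (classic
#'   conservative setting: 2).
#' @param quadratic Add quadratic features (default `TRUE`).
#' @param products Add pairwise product features (default `FALSE`).
#' @param linear_only Variables restricted to a linear feature (binary
#'   predictors such as host presence).
#' @param max_iter Iteration (sweep) cap; exceeding it raises an error that
#'   carries the objective trace.
#' @param tol_coef,tol_obj Convergence tolerances.
#' @return An object of class `maxent_model`.
#' @export
fit_maxent <- function(presences, background, beta_multiplier = 2,
                       quadratic = TRUE, products = FALSE,
                       linear_only = character(),
                       max_iter = 2000L, tol_coef = 1e-6, tol_obj = 1e-9) {
  stopifnot(inherits(presences, "env_sample"),
            inherits(background, "env_sample"))
  if (nrow(presences$matrix) < 2) stop("need at least 2 presence records")
  if (nrow(background$matrix) < 1) stop("background sample is empty")
  if (beta_multiplier <= 0) stop("beta_multiplier must be > 0")
  vars <- presences$variable_names
  if (!all(vars %in% background$variable_names))
    stop("background lacks presence variables")
  fp <- build_features(presences$matrix[, vars, drop = FALSE],
                       quadratic, products, linear_only)
  fb <- build_features(background$matrix[, vars, drop = FALSE],
                       quadratic, products, linear_only)
  m <- nrow(fp$matrix)
  all_f <- rbind(fp$matrix, fb$matrix)
  mu <- colMeans(all_f)
  sdev <- apply(all_f, 2, stats::sd)
  degen <- sdev == 0 | !is.finite(sdev)
  if (any(degen))
    warning("degenerate (constant) feature(s) kept at zero: ",
            paste(colnames(all_f)[degen], collapse = ", "))
  sdev[degen] <- 1
  Zp <- sweep(sweep(fp$matrix, 2, mu), 2, sdev, "/")
  Zb <- sweep(sweep(fb$matrix, 2, mu), 2, sdev, "/")
  J <- ncol(Zp)
  lambda <- rep(beta_multiplier / sqrt(m), J)  # = beta * s_j / sqrt(m) on raw scale
  lambda[degen] <- 0  # degenerate features are excluded from optimization;
                      # their coefficients stay exactly 0

  beta <- numeric(J)
  fbar <- colMeans(Zp)           # presence feature means (the constraints)
  eta_b <- numeric(nrow(Zb))
  obj <- maxent_objective(beta, Zp, Zb, lambda)
  trace <- obj
  converged <- FALSE
  active <- which(!degen)
  for (it in seq_len(max_iter)) {
    max_delta <- 0
    for (j in active) {
      mx <- max(eta_b)
      w <- exp(eta_b - mx)
      q <- w / sum(w)
      fj <- Zb[, j]
      Eq <- sum(q * fj)
      grad <- -fbar[j] + Eq
      hess <- max(sum(q * fj^2) - Eq^2, 1e-10)
      bj_new <- soft_threshold(beta[j] - grad / hess, lambda[j] / hess)
      delta <- bj_new - beta[j]
      if (delta == 0) next
      # backtrack: the quadratic model can overshoot when q shifts a lot
      pen_old <- lambda[j] * abs(beta[j])
      f_old <- -fbar[j] * beta[j] + (mx + log(sum(w))) + pen_old
      repeat {
        bj_try <- beta[j] + delta
        eta_try <- eta_b + delta * fj
        f_new <- -fbar[j] * bj_try + log_sum_exp(eta_try) +
          lambda[j] * abs(bj_try)
        if (f_new <= f_old + 1e-12 || abs(delta) < 1e-12) break
        delta <- delta / 2
      }
      if (f_new > f_old + 1e-12) next
      beta[j] <- beta[j] + delta
      eta_b <- eta_b + delta * fj
      max_delta <- max(max_delta, abs(delta))
    }
    obj_new <- maxent_objective(beta, Zp, Zb, lambda)
    trace <- c(trace, obj_new)
    if (max_delta < tol_coef || abs(obj - obj_new) < tol_obj) {
      converged <- TRUE
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  if (!converged) {
    e <- simpleError(paste0("maxent fit did not converge within ", max_iter,
                            " iterations"))
    e$trace <- trace
    stop(e)
  }
  beta[abs(beta) < 1e-12] <- 0   # exact zeros from soft-thresholding
  log_z <- log_sum_exp(drop(Zb %*% beta))
  structure(list(
    coefficients = stats::setNames(beta, colnames(all_f)),
    feature_vars = fp$feature_vars,
    feature_mean = mu, feature_scale = sdev, degenerate = degen,
    variable_names = vars,
    quadratic = quadratic, products = products, linear_only = linear_only,
    beta_multiplier = beta_multiplier, lambda = lambda,
    n_presence = m,
    background_reference = Zb,
    log_partition = log_z,
    avg_gain = mean(drop(Zp %*% beta)),
    calib_range = apply(presences$matrix[, vars, drop = FALSE], 2, range),
    objective_trace = trace, converged = converged
  ), class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  k <- sum(x$coefficients != 0)
  cat(sprintf(
    "maxent_model: %d presences, %d background, beta_multiplier %.3g\n",
    x$n_presence, nrow(x$background_reference), x$beta_multiplier))
  cat(sprintf("  %d/%d nonzero coefficients; final objective %.6g\n",
              k, length(x$coefficients), utils::tail(x$objective_trace, 1)))
  invisible(x)
}

maxent_eta <- function(model, X) {
  f <- build_features(X[, model$variable_names, drop = FALSE],
                      model$quadratic, model$products, model$linear_only)
  Z <- sweep(sweep(f$matrix, 2, model$feature_mean), 2,
             model$feature_scale, "/")
  drop(Z %*% model$coefficients)
}

#' Predict suitability from a maximum-entropy model
#'
#' `raw` output is the Gibbs probability `exp(eta(x)) / Z` with the partition
#' constant computed over the model's background reference, so raw scores
#' over the background sum to 1. `logistic` output applies the classic
#' transform `tau e^(eta - g) / (1 - tau + tau e^(eta - g))` with prevalence
#' `tau = 0.5` and `g` the mean linear predictor over the presence sample;
#' a model with all-zero coefficients scores 0.5 everywhere. The two outputs
#' are monotone transforms of each other.
#'
#' @param model A `maxent_model`.
#' @param env An `env_sample` covering the model's variables.
#' @param output `"logistic"` (default) or `"raw"`.
#' @return Numeric score vector, one per row of `env`.
#' @export
predict_maxent <- function(model, env, output = c("logistic", "raw")) {
  output <- match.arg(output)
  stopifnot(inherits(model, "maxent_model"), inherits(env, "env_sample"))
  miss <- setdiff(model$variable_names, env$variable_names)
  if (length(miss))
    stop("env sample lacks model variable(s): ", paste(miss, collapse = ", "))
  eta <- maxent_eta(model, env$matrix)
  if (output == "raw") exp(eta - model$log_partition)
  else stats::plogis(eta - model$avg_gain)
}

#' Number of parameters of a fitted maximum-entropy model
#'
#' Counts coefficients that are not exactly zero (L1 regularization produces
#' exact zeros); this is the `k` used by small-sample AICc.
#'
#' @param model A `maxent_model`.
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "maxent_model"))
  sum(model$coefficients != 0)
}

#' Serialize a maximum-entropy model to a JSON file
#'
#' Writes features, coefficients, normalizers and fit metadata (plus a hash
#' of the background reference) so a model reloads exactly. The background
#' reference matrix itself is stored too; files stay plain text.
#'
#' @param model A `maxent_model`.
#' @param path Output path.
#' @export
write_maxent_model <- function(model, path) {
  obj <- model
  class(obj) <- NULL
  obj$coefficients <- as.list(obj$coefficients)  # keeps feature names in JSON
  obj$background_digest <- sum(abs(model$background_reference))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Reload a serialized maximum-entropy model
#' @param path Path written by [write_maxent_model()].
#' @return A `maxent_model`.
#' @export
read_maxent_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$background_digest <- NULL
  obj$coefficients <- unlist(obj$coefficients)
  obj$feature_vars <- lapply(obj$feature_vars, unlist)
  obj$feature_mean <- unlist(obj$feature_mean)
  obj$feature_scale <- unlist(obj$feature_scale)
  obj$degenerate <- unlist(obj$degenerate)
  obj$calib_range <- matrix(unlist(obj$calib_range), nrow = 2,
                            dimnames = list(NULL, obj$variable_names))
  obj$background_reference <- matrix(as.numeric(obj$background_reference),
                                     nrow = nrow(obj$background_reference),
                                     dimnames = list(NULL, names(obj$coefficients)))
  structure(obj, class = "maxent_model")
}
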