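fit_small_system <- function(seed = 61) {
  stack <- make_test_stack(seed = seed, n_rows = 25, n_cols = 25,
                           mask_cells = 50)
  niche <- true_niche(c(bio4 = 110, bio16 = 210), c(bio4 = 15, bio16 = 25))
  occ <- sample_occurrences(true_suitability(niche, stack), 60, seed = seed)
  env <- extract_values(stack, occ)
  bg <- sample_background(stack, 1000, seed = seed + 1)
  list(stack = stack, env = env, bg = bg,
       model = fit_maxent(env, bg))
}

test_that("projection reproduces point predictions and masks", {
  sys <- fit_small_system()
  proj <- project(sys$model, sys$stack)
  expect_identical(is.na(proj$values), is.na(sys$stack$layers[[1]]$values))
  # consistency with predict at extracted points
  cells <- attr(sys$env, "cells")
  expect_equal(proj$values[cbind(cells$row, cells$col)],
               predict_maxent(sys$model, sys$env))
  # spot-check cells against direct formula evaluation
  cm <- stack_cell_matrix(sys$stack)
  pick <- seq(1, nrow(cm$matrix), length.out = 20)
  one <- env_sample(cm$matrix[pick, , drop = FALSE])
  expect_equal(proj$values[cbind(cm$row[pick], cm$col[pick])],
               predict_maxent(sys$model, one))
  # an all-zero model projects a flat 0.5 logistic surface
  mz <- fit_maxent(sys$env, sys$bg, beta_multiplier = 1e6)
  pz <- project(mz, sys$stack)
  expect_true(all(pz$values[!is.na(pz$values)] == 0.5))
})

test_that("ensemble averaging is the cell-wise mean on the continuous scale", {
  sys <- fit_small_system(seed = 62)
  p1 <- project(sys$model, sys$stack)
  expect_equal(ensemble_average(list(p1, p1))$values, p1$values)
  spec <- grid_spec(2, 2, 0, 2, 1)
  a <- env_raster(spec, matrix(0, 2, 2))
  b <- env_raster(spec, matrix(1, 2, 2))
  expect_equal(ensemble_average(list(a, b))$values, matrix(0.5, 2, 2))
  set.seed(1)
  r1 <- env_raster(spec, matrix(runif(4), 2, 2))
  r2 <- env_raster(spec, matrix(runif(4), 2, 2))
  r3 <- env_raster(spec, matrix(runif(4), 2, 2))
  expect_equal(ensemble_average(list(r1, r2, r3))$values,
               (r1$values + r2$values + r3$values) / 3)
  bad <- env_raster(grid_spec(2, 2, 5, 2, 1), matrix(0, 2, 2))
  expect_error(ensemble_average(list(a, bad)), "aligned")
})

test_that("binarization uses score >= threshold and is monotone", {
  set.seed(3)
  spec <- grid_spec(5, 5, 0, 5, 1)
  vals <- matrix(runif(25), 5, 5)
  vals[c(3, 9)] <- NA
  r <- env_raster(spec, vals)
  expect_true(all(binarize(r, -Inf)$values[!is.na(vals)] == 1))
  expect_true(all(binarize(r, max(vals, na.rm = TRUE) + 1)$values[!is.na(vals)] == 0))
  bm <- binarize(r, 0.5)
  expect_equal(bm$values[!is.na(vals)], as.numeric(vals[!is.na(vals)] >= 0.5))
  n_suit <- sapply(seq(0, 1, 0.1), function(t)
    sum(binarize(r, t)$values, na.rm = TRUE))
  expect_true(all(diff(n_suit) <= 0))
})

test_that("stability classes partition the valid cells", {
  set.seed(5)
  spec <- grid_spec(8, 8, 0, 8, 1)
  mk <- function() {
    v <- matrix(rbinom(64, 1, 0.5), 8, 8)
    v[c(2, 40)] <- NA
    structure(list(spec = spec, values = v, threshold = 0.5),
              class = "binary_map")
  }
  past <- mk(); present <- mk()
  sm <- stability_classify(past, present)
  p <- past$values; q <- present$values
  expect_equal(unname(sm$counts["stable"]), sum(p == 1 & q == 1, na.rm = TRUE))
  expect_equal(unname(sm$counts["lost"]), sum(p == 1 & q == 0, na.rm = TRUE))
  expect_equal(unname(sm$counts["gained"]), sum(p == 0 & q == 1, na.rm = TRUE))
  expect_equal(unname(sm$counts["never"]), sum(p == 0 & q == 0, na.rm = TRUE))
  expect_equal(sum(sm$counts), 62)
  # identical periods: only stable/never
  sm2 <- stability_classify(past, past)
  expect_equal(unname(sm2$counts[c("lost", "gained")]), c(0L, 0L))
  # full loss
  all1 <- mk(); all1$values[!is.na(all1$values)] <- 1
  all0 <- mk(); all0$values[!is.na(all0$values)] <- 0
  expect_equal(unname(stability_classify(all1, all0)$counts["lost"]), 62)
})

test_that("overlap change equals brute-force set arithmetic", {
  set.seed(6)
  spec <- grid_spec(10, 10, 0, 10, 1)
  mk <- function(p) structure(
    list(spec = spec, values = matrix(rbinom(100, 1, p), 10, 10),
         threshold = 0.5), class = "binary_map")
  pp <- mk(0.4); hp <- mk(0.6); pc <- mk(0.4); hc <- mk(0.6)
  oc <- overlap_change(pp, hp, pc, hc)
  ov <- function(par, hos) sum(par$values & hos$values) / sum(par$values)
  expect_equal(oc$overlap_past, ov(pp, hp))
  expect_equal(oc$overlap_present, ov(pc, hc))
  expect_equal(oc$change_pct, abs(ov(pc, hc) - ov(pp, hp)) * 100)
  # identical scenario pairs: zero change
  expect_equal(overlap_change(pp, hp, pp, hp)$change_pct, 0)
  # parasite fully inside the host range in both periods
  inside <- mk(0.3); inside$values <- inside$values * hp$values
  oc2 <- overlap_change(inside, hp, inside, hp)
  expect_equal(oc2$overlap_past, 1)
  expect_equal(oc2$change_pct, 0)
  # empty parasite range flags undefined
  none <- mk(0); none$values[] <- 0
  expect_true(overlap_change(none, hp, pc, hc)$undefined)
  # Jaccard alternative
  ocj <- overlap_change(pp, hp, pc, hc, method = "jaccard")
  jac <- function(par, hos) sum(par$values & hos$values) /
    sum(par$values | hos$values)
  expect_equal(ocj$overlap_past, jac(pp, hp))
})

test_that("host predictor layers are faithful 0/1 indicators", {
  set.seed(7)
  spec <- grid_spec(6, 6, 0, 6, 1)
  vals <- matrix(runif(36), 6, 6)
  vals[c(4, 17)] <- NA
  bm <- binarize(env_raster(spec, vals), 0.5)
  hl <- host_predictor_layer(bm)
  expect_equal(hl$values, bm$values)           # cellwise indicator
  expect_equal(hl$name, "host")
  # round-trip through threshold 0.5 recovers the map
  expect_equal(binarize(hl, 0.5)$values, bm$values)
  all1 <- binarize(env_raster(spec, vals), -Inf)
  expect_warning(host_predictor_layer(all1), "zero variance")
})

test_that("maps round-trip to ESRI ASCII with a legend sidecar", {
  set.seed(8)
  spec <- grid_spec(5, 5, 0, 5, 1)
  vals <- matrix(runif(25), 5, 5); vals[7] <- NA
  bm <- binarize(env_raster(spec, vals), 0.4)
  sm <- stability_classify(bm, binarize(env_raster(spec, vals), 0.6))
  p <- tempfile(fileext = ".asc")
  write_map(sm, p)
  back <- read_raster(p)
  expect_equal(back$values, sm$values)
  expect_true(file.exists(paste0(p, ".legend.txt")))
})

test_that("an uninformative constant host layer changes nothing", {
  stack <- make_test_stack(seed = 71, n_rows = 25, n_cols = 25,
                           mask_cells = 30)
  niche <- true_niche(c(bio4 = 110, bio16 = 210), c(bio4 = 15, bio16 = 25))
  occ <- sample_occurrences(true_suitability(niche, stack), 60, seed = 2)
  const_host <- suppressWarnings(host_predictor_layer(
    binarize(env_raster(stack$spec,
                        ifelse(is.na(stack$layers[[1]]$values), NA, 1)), 0.5)))
  hc <- suppressWarnings(compare_with_without_host(
    occ, stack, const_host,
    fspec = filter_spec(filter_variables = c("bio4", "bio16"),
                        cell_widths = c(10, 10), seed = 1),
    background_n = 800, seed = 3, n_reps = 3))
  expect_equal(unname(hc$model_host$coefficients["host"]), 0)
  expect_equal(hc$comparison$k[1], hc$comparison$k[2])
  expect_equal(hc$comparison$delta_aicc, c(0, 0), tolerance = 1e-8)
  expect_equal(sum(hc$difference_map$values == 1, na.rm = TRUE), 0)
})
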