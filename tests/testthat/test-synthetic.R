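test_that("scenario generation is bit-reproducible and respects offsets", {
  cfg <- climate_sim_config(grid = grid_spec(30, 30, -60, 5, 0.5), seed = 11)
  s1 <- generate_scenarios(cfg)
  s2 <- generate_scenarios(cfg)
  expect_identical(s1, s2)
  expect_named(s1, c("current", "lgm_ccsm", "lgm_miroc"))

  # zero offsets reproduce the current stack exactly
  cfg0 <- climate_sim_config(grid = grid_spec(30, 30, -60, 5, 0.5), seed = 11,
                             lgm_offsets = list(flat = c(bio4 = 0, bio8 = 0,
                                                         bio9 = 0, bio16 = 0,
                                                         bio17 = 0)))
  s0 <- generate_scenarios(cfg0)
  for (v in names(s0$current$layers))
    expect_equal(s0$flat$layers[[v]]$values, s0$current$layers[[v]]$values)

  # an additive shift of -30 on bio4 moves the valid-cell mean by exactly -30
  cfgd <- climate_sim_config(grid = grid_spec(30, 30, -60, 5, 0.5), seed = 11,
                             lgm_offsets = list(cool = c(bio4 = -30, bio8 = 0,
                                                         bio9 = 0, bio16 = 0,
                                                         bio17 = 0)))
  sd <- generate_scenarios(cfgd)
  d <- sd$cool$layers$bio4$values - sd$current$layers$bio4$values
  expect_equal(mean(d, na.rm = TRUE), -30, tolerance = 1e-9)

  # scenarios share one mask
  expect_identical(is.na(s1$lgm_ccsm$layers$bio9$values),
                   is.na(s1$current$layers$bio9$values))
})

test_that("degenerate grids are refused", {
  expect_error(generate_scenarios(
    climate_sim_config(grid = grid_spec(3, 10, 0, 5, 0.5))), "degenerate")
})

test_that("true suitability follows the Gaussian bell closed form", {
  stack <- make_test_stack(seed = 2, vars = c("bio4", "bio16"))
  niche <- true_niche(optima = c(bio4 = 100, bio16 = 200),
                      breadths = c(bio4 = 20, bio16 = 30),
                      max_suitability = 0.8)
  suit <- true_suitability(niche, stack)
  # brute-force oracle: independent cell-by-cell evaluation
  for (idx in sample(which(!is.na(suit$values)), 25)) {
    x4 <- stack$layers$bio4$values[idx]
    x16 <- stack$layers$bio16$values[idx]
    expect_equal(suit$values[idx],
                 0.8 * exp(-0.5 * ((x4 - 100) / 20)^2) *
                   exp(-0.5 * ((x16 - 200) / 30)^2),
                 tolerance = 1e-12)
  }
  # exact optimum scores max_suitability; 1 breadth away on one variable
  spec <- grid_spec(1, 2, 0, 1, 1)
  st <- env_stack(list(
    env_raster(spec, matrix(c(100, 120), 1, 2), "bio4"),
    env_raster(spec, matrix(c(200, 200), 1, 2), "bio16")))
  s <- true_suitability(niche, st)
  expect_equal(s$values[1, 1], 0.8)
  expect_equal(s$values[1, 2], 0.8 * exp(-0.5))
  expect_error(true_suitability(
    true_niche(c(bio99 = 1), c(bio99 = 1)), stack), "bio99")
})

test_that("occurrence sampling honors weights, masks and seeds", {
  # binary suitability: every point lands in a suitable cell
  spec <- grid_spec(4, 4, 0, 4, 1)
  suit <- matrix(0, 4, 4)
  suit[1:2, ] <- 1
  suit[3, 1] <- NA
  r <- env_raster(spec, suit)
  occ <- sample_occurrences(r, 200, seed = 8)
  rc <- cell_at(spec, occ$records$longitude, occ$records$latitude)
  expect_true(all(suit[cbind(rc$row, rc$col)] == 1))

  # two-cell binomial oracle: shares within 3 SE of 0.2/0.8
  spec2 <- grid_spec(1, 2, 0, 1, 1)
  r2 <- env_raster(spec2, matrix(c(0.2, 0.8), 1, 2))
  o2 <- sample_occurrences(r2, 10000, seed = 5)
  share <- mean(cell_at(spec2, o2$records$longitude, o2$records$latitude)$col == 2)
  se <- sqrt(0.8 * 0.2 / 10000)
  expect_lt(abs(share - 0.8), 3 * se)

  expect_identical(sample_occurrences(r, 50, seed = 3),
                   sample_occurrences(r, 50, seed = 3))
  expect_error(sample_occurrences(env_raster(spec2, matrix(0, 1, 2)), 5),
               "zero")
})

test_that("sampling bias multiplies the cell weights", {
  spec <- grid_spec(1, 2, 0, 1, 1)
  suit <- env_raster(spec, matrix(c(0.5, 0.5), 1, 2))
  bias <- env_raster(spec, matrix(c(1, 3), 1, 2))
  o <- sample_occurrences(suit, 8000, bias = bias, seed = 2)
  share <- mean(cell_at(spec, o$records$longitude, o$records$latitude)$col == 2)
  expect_lt(abs(share - 0.75), 3 * sqrt(0.75 * 0.25 / 8000))
})

test_that("host-parasite coupling shapes the parasite distribution", {
  cfg <- climate_sim_config(grid = grid_spec(40, 40, -60, 5, 0.5), seed = 21)
  sc <- generate_scenarios(cfg)
  host <- true_niche(c(bio4 = 1200, bio16 = 1000), c(bio4 = 250, bio16 = 250))
  para <- true_niche(c(bio4 = 1350, bio16 = 900), c(bio4 = 300, bio16 = 300))

  # coupling 0: parasite draw identical in law (and draws) to climate-only
  c0 <- biotic_coupling(host, para, 0)
  hp0 <- sample_host_parasite(c0, sc$current, 50, 60, seed = 4)
  solo <- sample_occurrences(true_suitability(para, sc$current), 60,
                             seed = 5, species = "virtual_parasite")
  expect_equal(hp0$parasite$records[c("longitude", "latitude")],
               solo$records[c("longitude", "latitude")])

  # coupling 1 with host suitability zeroed over the east half:
  # no parasite points there
  host_zero <- true_suitability(host, sc$current)
  host_zero$values[, 21:40] <- ifelse(is.na(host_zero$values[, 21:40]), NA, 0)
  para_suit <- true_suitability(para, sc$current)
  prod_suit <- env_raster(sc$current$spec, para_suit$values * host_zero$values)
  occ <- sample_occurrences(prod_suit, 300, seed = 9)
  cols <- cell_at(sc$current$spec, occ$records$longitude,
                  occ$records$latitude)$col
  expect_true(all(cols <= 20))

  # coupling raises mean host suitability at parasite points
  c1 <- biotic_coupling(host, para, 1)
  hp1 <- sample_host_parasite(c1, sc$current, 50, 5000, seed = 4)
  hs <- true_suitability(host, sc$current)
  at_points <- function(occ) {
    rc <- cell_at(sc$current$spec, occ$records$longitude, occ$records$latitude)
    mean(hs$values[cbind(rc$row, rc$col)])
  }
  hp0b <- sample_host_parasite(c0, sc$current, 50, 5000, seed = 4)
  expect_gt(at_points(hp1$parasite), at_points(hp0b$parasite))
})
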