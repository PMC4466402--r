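# Shared fixtures, built in code at test time.

# A small random stack with a fixed-seed mask and smooth-ish values.
make_test_stack <- function(seed = 1, n_rows = 20, n_cols = 20,
                            vars = c("bio4", "bio16", "bio17"),
                            mask_cells = 30, scenario = "current") {
  set.seed(seed)
  spec <- grid_spec(n_rows, n_cols, x_origin = -60, y_origin = 5,
                    cell_size = 0.5)
  masked <- sample.int(n_rows * n_cols, mask_cells)
  layers <- lapply(seq_along(vars), function(i) {
    m <- matrix(rnorm(n_rows * n_cols, mean = 100 * i, sd = 20),
                n_rows, n_cols)
    m[masked] <- NA_real_
    env_raster(spec, m, name = vars[i])
  })
  env_stack(layers, scenario_name = scenario)
}

# Random env_sample with named variables.
make_test_env <- function(seed = 1, n = 30,
                          vars = c("bio4", "bio16", "bio17"),
                          mean = 0, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * length(vars), mean, sd), n, length(vars),
              dimnames = list(NULL, vars))
  env_sample(m)
}

# A small ESRI ASCII grid written to a temp file; returns the path.
write_ascii_fixture <- function(values_text, path = tempfile(fileext = ".asc"),
                                nodata = -9999) {
  writeLines(c("NCOLS 3", "NROWS 3", "XLLCORNER -10", "YLLCORNER 0",
               "CELLSIZE 1", paste("NODATA_value", nodata), values_text),
             path)
  path
}

# Smooth random field on an n x n grid (simple square moving average),
# used to build spatial patterns that are independent of any climate layer.
make_smooth_field <- function(seed, n, radius) {
  set.seed(seed)
  m <- matrix(rnorm(n * n), n, n)
  run_mean <- function(v) {
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_along(v) - radius, 1L)
    hi <- pmin(seq_along(v) + radius, length(v))
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  m <- apply(m, 2, run_mean)
  t(apply(m, 1, run_mean))
}

expect_same_raster <- function(a, b) {
  expect_true(grids_aligned(a$spec, b$spec))
  expect_identical(is.na(a$values), is.na(b$values))
  expect_equal(a$values, b$values)
}
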