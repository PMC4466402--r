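#' Grid geometry for gridded climate layers
#'
#' A `grid_spec` describes the geometry of a regular latitude/longitude grid:
#' its dimensions, the coordinates of its north-west corner, the (square) cell
#' size in decimal degrees, and the sentinel value that marks nodata cells in
#' files on disk. All layers, predictions and maps in a pipeline share one
#' `grid_spec`; two grids are "aligned" when all five geometry fields are
#' equal.
#'
#' Coordinates are geographic decimal degrees (WGS84 assumed); there is no
#' reprojection support. Cell membership uses half-open intervals
#' \[west, east) x (south, north\] so every point belongs to exactly one cell;
#' points exactly on the far east or far south outer edge of the grid are out
#' of bounds.
#'
#' @param n_rows,n_cols Grid dimensions (rows count from the north).
#' @param x_origin Longitude of the west edge of the grid, degrees.
#' @param y_origin Latitude of the north edge of the grid, degrees.
#' @param cell_size Cell side length in degrees; cells are square.
#' @param nodata_value Sentinel written to files for masked cells.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, x_origin, y_origin, cell_size,
                      nodata_value = -9999) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L, is.finite(cell_size), cell_size > 0)
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         x_origin = as.numeric(x_origin), y_origin = as.numeric(y_origin),
         cell_size = as.numeric(cell_size),
         nodata_value = as.numeric(nodata_value)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d rows x %d cols, cell %.6g deg\n",
              x$n_rows, x$n_cols, x$cell_size))
  cat(sprintf("  extent: lon [%.6g, %.6g), lat (%.6g, %.6g]\n",
              x$x_origin, x$x_origin + x$n_cols * x$cell_size,
              x$y_origin - x$n_rows * x$cell_size, x$y_origin))
  invisible(x)
}

#' Test whether two grid specs are aligned
#'
#' Alignment requires equality of all five geometry fields (dimensions,
#' origin, cell size); the nodata sentinel does not affect alignment.
#'
#' @param a,b `grid_spec` objects.
#' @return Logical scalar.
#' @export
grids_aligned <- function(a, b) {
  stopifnot(inherits(a, "grid_spec"), inherits(b, "grid_spec"))
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    a$x_origin == b$x_origin && a$y_origin == b$y_origin &&
    a$cell_size == b$cell_size
}

#' Locate the grid cell containing each point
#'
#' Applies the half-open cell convention \[west, east) x (south, north\].
#' Points outside the grid (including those exactly on the far east or far
#' south outer edge) get `NA` row/column.
#'
#' @param spec A `grid_spec`.
#' @param lon,lat Numeric vectors of equal length, degrees.
#' @return A data.frame with integer columns `row`, `col` (`NA` when out of
#'   bounds). Row 1 is the northernmost row, column 1 the westernmost column.
#' @export
cell_at <- function(spec, lon, lat) {
  stopifnot(inherits(spec, "grid_spec"), length(lon) == length(lat))
  col <- floor((lon - spec$x_origin) / spec$cell_size) + 1
  # north edges belong to the cell below them: exact multiples of cell_size
  # down from y_origin open the next row
  drow <- (spec$y_origin - lat) / spec$cell_size
  row <- floor(drow) + 1
  out <- col < 1 | col > spec$n_cols | row < 1 | row > spec$n_rows |
    lat > spec$y_origin | !is.finite(lon) | !is.finite(lat)
  col[out] <- NA_integer_
  row[out] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Centre coordinates of grid cells
#'
#' @param spec A `grid_spec`.
#' @param row,col Integer vectors of cell indices (row 1 = north).
#' @return data.frame with `lon`, `lat` of each cell centre.
#' @export
cell_centre <- function(spec, row, col) {
  data.frame(
    lon = spec$x_origin + (col - 0.5) * spec$cell_size,
    lat = spec$y_origin - (row - 0.5) * spec$cell_size
  )
}

#' A single gridded layer
#'
#' An `env_raster` couples a `grid_spec` with a numeric value matrix
#' (row 1 = northernmost row) and a layer name. Masked (nodata) cells are
#' stored as `NA` internally and converted to the spec's sentinel only when
#' written to disk; masked cells never enter any statistic.
#'
#' @param spec A `grid_spec`.
#' @param values Numeric matrix of dimension `n_rows x n_cols`; `NA` = masked.
#' @param name Layer label, e.g. `"bio4"`.
#' @return An object of class `env_raster`.
#' @export
env_raster <- function(spec, values, name = "layer") {
  stopifnot(inherits(spec, "grid_spec"), is.matrix(values))
  if (!identical(dim(values), c(spec$n_rows, spec$n_cols)))
    stop("values must be a ", spec$n_rows, " x ", spec$n_cols, " matrix")
  storage.mode(values) <- "double"
  structure(list(spec = spec, values = values, name = as.character(name)),
            class = "env_raster")
}

#' @export
print.env_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("env_raster '%s': %d x %d, %d valid cells",
              x$name, x$spec$n_rows, x$spec$n_cols, length(v)))
  if (length(v))
    cat(sprintf(", range [%.4g, %.4g]", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' Logical mask of valid (unmasked) cells
#' @param r An `env_raster`.
#' @return Logical matrix, `TRUE` where the cell carries data.
#' @export
valid_mask <- function(r) !is.na(r$values)

#' Read a gridded layer from disk
#'
#' Reads a single-band raster in ESRI ASCII grid format (the
#' `NCOLS`/`NROWS`/`XLLCORNER`/`YLLCORNER`/`CELLSIZE`/`NODATA_value` header
#' followed by rows of values, north first). Cells equal to the declared
#' nodata value become masked (`NA`). `XLLCENTER`/`YLLCENTER` headers are
#' accepted and converted to corner registration.
#'
#' GeoTIFF is recognised as a format name but not supported by this build;
#' requesting it raises an error rather than mis-reading the file.
#'
#' @param path File path.
#' @param fmt Format, `"esri_ascii"` (default) or `"geotiff"`.
#' @param name Layer name; defaults to the file name without extension.
#' @return An `env_raster`.
#' @export
read_raster <- function(path, fmt = c("esri_ascii", "geotiff"), name = NULL) {
  fmt <- match.arg(fmt)
  if (fmt == "geotiff")
    stop("GeoTIFF input is not supported by this build; ",
         "convert the layer to ESRI ASCII grid format")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(toks) == 2 && grepl("^[A-Za-z_]+$", toks[1]) &&
        !is.na(suppressWarnings(as.numeric(toks[2])))) {
      hdr[[tolower(toks[1])]] <- as.numeric(toks[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  if (!is.null(hdr$dx) || !is.null(hdr$dy))
    stop("unsupported geometry: non-square cells (DX/DY header)")
  req_dims <- c("ncols", "nrows", "cellsize")
  for (f in req_dims)
    if (is.null(hdr[[f]])) stop("malformed ESRI ASCII header: missing ", f)
  centre_x <- !is.null(hdr$xllcenter)
  centre_y <- !is.null(hdr$yllcenter)
  xll <- if (centre_x) hdr$xllcenter - hdr$cellsize / 2 else hdr$xllcorner
  yll <- if (centre_y) hdr$yllcenter - hdr$cellsize / 2 else hdr$yllcorner
  if (is.null(xll)) stop("malformed ESRI ASCII header: missing xllcorner")
  if (is.null(yll)) stop("malformed ESRI ASCII header: missing yllcorner")
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  n_rows <- as.integer(hdr$nrows)
  n_cols <- as.integer(hdr$ncols)
  body <- paste(lines[(n_hdr + 1L):length(lines)], collapse = " ")
  vals <- suppressWarnings(as.numeric(strsplit(trimws(body), "\\s+")[[1]]))
  if (length(vals) != n_rows * n_cols || anyNA(vals))
    stop("malformed ESRI ASCII body: expected ", n_rows * n_cols,
         " numeric values, got ", length(vals))
  m <- matrix(vals, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  spec <- grid_spec(n_rows, n_cols,
                    x_origin = xll,
                    y_origin = yll + n_rows * hdr$cellsize,
                    cell_size = hdr$cellsize,
                    nodata_value = nodata)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  env_raster(spec, m, name = name)
}

#' Write a gridded layer to disk as ESRI ASCII
#'
#' Masked cells are written as the spec's nodata sentinel. A raster written
#' with [write_raster()] and read back with [read_raster()] is value-exact.
#'
#' @param r An `env_raster`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path) {
  stopifnot(inherits(r, "env_raster"))
  s <- r$spec
  hdr <- c(
    sprintf("NCOLS %d", s$n_cols),
    sprintf("NROWS %d", s$n_rows),
    sprintf("XLLCORNER %.17g", s$x_origin),
    sprintf("YLLCORNER %.17g", s$y_origin - s$n_rows * s$cell_size),
    sprintf("CELLSIZE %.17g", s$cell_size),
    sprintf("NODATA_value %.17g", s$nodata_value)
  )
  vals <- r$values
  vals[is.na(vals)] <- s$nodata_value
  rows <- apply(vals, 1, function(v) paste(sprintf("%.17g", v), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' A stack of aligned climate layers for one scenario
#'
#' Bundles several `env_raster` layers that share one `grid_spec` into a
#' named scenario (e.g. `"current"`, `"lgm_ccsm"`). At construction the
#' nodata masks of all layers are intersected: a cell masked in any layer
#' becomes masked in every layer, so the stack presents a single common mask.
#'
#' @param layers List of `env_raster` objects with unique names.
#' @param scenario_name Scenario label.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(layers, scenario_name = "current") {
  stopifnot(is.list(layers), length(layers) >= 1)
  lapply(layers, function(l) stopifnot(inherits(l, "env_raster")))
  nms <- vapply(layers, function(l) l$name, character(1))
  if (anyDuplicated(nms)) stop("layer names must be unique")
  spec <- layers[[1]]$spec
  for (l in layers[-1])
    if (!grids_aligned(spec, l$spec)) stop("layers are not aligned")
  shared_na <- Reduce(`|`, lapply(layers, function(l) is.na(l$values)))
  layers <- lapply(layers, function(l) {
    l$values[shared_na] <- NA_real_
    l
  })
  names(layers) <- nms
  structure(list(layers = layers, spec = spec,
                 scenario_name = as.character(scenario_name)),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack '%s': %d layers (%s), %d x %d grid, %d valid cells\n",
              x$scenario_name, length(x$layers),
              paste(names(x$layers), collapse = ", "),
              x$spec$n_rows, x$spec$n_cols,
              sum(!is.na(x$layers[[1]]$values))))
  invisible(x)
}

#' Layer names of a stack
#' @param stack An `env_stack`.
#' @return Character vector.
#' @export
stack_variables <- function(stack) names(stack$layers)

#' Environment matrix of the valid cells of a stack
#'
#' Returns the values of every unmasked cell as a cells x variables matrix,
#' together with the cell indices, in a fixed (row-major from the north-west)
#' order. This is the prediction extent used for landscape projection and
#' AICc standardization.
#'
#' @param stack An `env_stack`.
#' @return List with `matrix` (cells x variables), `row`, `col` (integer cell
#'   indices).
#' @export
stack_cell_matrix <- function(stack) {
  ok <- !is.na(stack$layers[[1]]$values)
  idx <- which(ok)  # column-major over the matrix; fixed deterministic order
  m <- vapply(stack$layers, function(l) l$values[idx],
              numeric(length(idx)))
  if (length(idx) == 1L) m <- matrix(m, nrow = 1,
                                     dimnames = list(NULL, names(stack$layers)))
  list(matrix = m,
       row = as.integer((idx - 1L) %% stack$spec$n_rows + 1L),
       col = as.integer((idx - 1L) %/% stack$spec$n_rows + 1L))
}
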