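#' Presence-only occurrence records for one species
#'
#' @param species Species label.
#' @param lon,lat Numeric coordinate vectors, degrees (WGS84 assumed).
#' @param source Optional per-record provenance strings.
#' @param role One of `"raw"`, `"calibration"`, `"testing"`.
#' @return An object of class `occurrence_set`.
#' @export
occurrence_set <- function(species, lon, lat, source = NULL,
                           role = c("raw", "calibration", "testing")) {
  role <- match.arg(role)
  lon <- as.numeric(lon)
  lat <- as.numeric(lat)
  stopifnot(length(lon) == length(lat))
  if (length(lon) && (any(lon < -180 | lon > 180) || any(lat < -90 | lat > 90)))
    stop("coordinates out of range: longitude must be in [-180, 180], ",
         "latitude in [-90, 90]")
  if (is.null(source)) source <- rep("", length(lon))
  structure(
    list(species = as.character(species),
         records = data.frame(longitude = lon, latitude = lat,
                              source = as.character(source),
                              stringsAsFactors = FALSE),
         role = role),
    class = "occurrence_set"
  )
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set: %s, %d records (role: %s)\n",
              x$species, nrow(x$records), x$role))
  invisible(x)
}

#' Number of records in an occurrence set
#' @param occ An `occurrence_set`.
#' @export
n_occurrences <- function(occ) nrow(occ$records)

#' Subset an occurrence set by record index
#' @param occ An `occurrence_set`.
#' @param i Integer index vector.
#' @param role Role assigned to the subset.
#' @export
subset_occurrences <- function(occ, i, role = occ$role) {
  occurrence_set(occ$species,
                 occ$records$longitude[i], occ$records$latitude[i],
                 occ$records$source[i], role = role)
}

#' Read occurrence records from a delimited text table
#'
#' Accepts comma- or tab-delimited files (auto-detected from the header
#' line) with a header naming at least the species, longitude and latitude
#' columns; column order is free. Recognised header names (case-insensitive):
#' `species`; `longitude`, `lon` or `x`; `latitude`, `lat` or `y`. Decimal
#' points only (no comma decimals). Rows with unparseable or out-of-range
#' coordinates are skipped with a warning listing the offending row numbers.
#' Exact duplicate coordinates are retained: deduplication is an explicit,
#' separate choice, not an import side effect.
#'
#' @param path File path.
#' @param species Optional species filter; by default all rows are read and
#'   the species label is taken from the (single) value in the species column.
#' @return An `occurrence_set` with role `"raw"`.
#' @export
read_occurrences <- function(path, species = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first) || !nzchar(trimws(first)))
    stop("empty occurrence file: ", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"")
  if (nrow(df) == 0) stop("occurrence file has a header but no records: ", path)
  nm <- tolower(names(df))
  pick <- function(cands, what) {
    i <- which(nm %in% cands)[1]
    if (is.na(i)) stop("occurrence table lacks a ", what,
                       " column (looked for: ", paste(cands, collapse = ", "), ")")
    i
  }
  i_sp <- pick("species", "species")
  i_lon <- pick(c("longitude", "lon", "x"), "longitude")
  i_lat <- pick(c("latitude", "lat", "y"), "latitude")
  if (!is.null(species)) {
    keep0 <- df[[i_sp]] == species
    df <- df[keep0, , drop = FALSE]
    if (nrow(df) == 0) stop("no records for species '", species, "' in ", path)
  }
  lon <- suppressWarnings(as.numeric(df[[i_lon]]))
  lat <- suppressWarnings(as.numeric(df[[i_lat]]))
  bad <- is.na(lon) | is.na(lat) |
    lon < -180 | lon > 180 | lat < -90 | lat > 90
  if (any(bad))
    warning(sum(bad), " row(s) skipped (unparseable or out-of-range ",
            "coordinates): rows ", paste(which(bad), collapse = ", "))
  keep <- !bad
  if (!any(keep)) stop("no valid records in ", path)
  src <- if ("source" %in% nm) df[[which(nm == "source")[1]]][keep]
         else rep(basename(path), sum(keep))
  sp <- unique(df[[i_sp]][keep])
  occurrence_set(paste(sp, collapse = "+"), lon[keep], lat[keep],
                 source = src, role = "raw")
}

#' Write an occurrence set as CSV
#' @param occ An `occurrence_set`.
#' @param path Output file path.
#' @export
write_occurrences <- function(occ, path) {
  df <- data.frame(species = occ$species, occ$records,
                   role = occ$role, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Environment values extracted at point locations
#'
#' An `env_sample` is the points x variables matrix carried into all model
#' fitting. Column order always matches the layer order of the stack the
#' sample was extracted from, and the matrix never contains nodata values.
#'
#' @param matrix Numeric points x variables matrix with column names.
#' @param point_ids Identifier per row.
#' @return An object of class `env_sample`.
#' @export
env_sample <- function(matrix, point_ids = seq_len(nrow(matrix))) {
  stopifnot(is.matrix(matrix), !is.null(colnames(matrix)))
  if (anyNA(matrix)) stop("env_sample matrix must not contain nodata values")
  structure(list(point_ids = point_ids, matrix = matrix,
                 variable_names = colnames(matrix)),
            class = "env_sample")
}

#' @export
print.env_sample <- function(x, ...) {
  cat(sprintf("env_sample: %d points x %d variables (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(x$variable_names, collapse = ", ")))
  rej <- attr(x, "rejections")
  if (!is.null(rej) && nrow(rej))
    cat(sprintf("  %d point(s) rejected (see attr 'rejections')\n", nrow(rej)))
  invisible(x)
}

#' Subset the rows of an env_sample
#' @param env An `env_sample`.
#' @param i Integer row indices.
#' @export
subset_env <- function(env, i) {
  env_sample(env$matrix[i, , drop = FALSE], point_ids = env$point_ids[i])
}

#' Extract climate values at occurrence locations
#'
#' Each point takes the value of the grid cell containing it (half-open cell
#' membership, see [grid_spec()]). Points that fall outside the grid or on a
#' masked cell are excluded from the matrix and listed in the rejection
#' report attached as attribute `"rejections"` — they are reported, never
#' silently dropped.
#'
#' @param stack An `env_stack`.
#' @param occ An `occurrence_set`.
#' @return An `env_sample` whose rows correspond (in order) to the retained
#'   occurrence records; attribute `"rejections"` is a data.frame with
#'   columns `point_id`, `longitude`, `latitude`, `reason`
#'   (`"out_of_bounds"` or `"masked_cell"`); attribute `"kept"` gives the
#'   indices of the retained records in the input set.
#' @export
extract_values <- function(stack, occ) {
  stopifnot(inherits(stack, "env_stack"), inherits(occ, "occurrence_set"))
  rc <- cell_at(stack$spec, occ$records$longitude, occ$records$latitude)
  n <- nrow(rc)
  reason <- rep(NA_character_, n)
  reason[is.na(rc$row)] <- "out_of_bounds"
  inb <- which(is.na(reason))
  if (length(inb)) {
    masked <- is.na(stack$layers[[1]]$values[cbind(rc$row[inb], rc$col[inb])])
    reason[inb[masked]] <- "masked_cell"
  }
  kept <- which(is.na(reason))
  m <- vapply(stack$layers,
              function(l) l$values[cbind(rc$row[kept], rc$col[kept])],
              numeric(length(kept)))
  if (length(kept) == 1L)
    m <- matrix(m, nrow = 1, dimnames = list(NULL, names(stack$layers)))
  if (length(kept) == 0L)
    m <- matrix(numeric(0), nrow = 0, ncol = length(stack$layers),
                dimnames = list(NULL, names(stack$layers)))
  out <- env_sample(m, point_ids = kept)
  rej <- which(!is.na(reason))
  attr(out, "rejections") <- data.frame(
    point_id = rej,
    longitude = occ$records$longitude[rej],
    latitude = occ$records$latitude[rej],
    reason = reason[rej],
    stringsAsFactors = FALSE)
  attr(out, "kept") <- kept
  attr(out, "cells") <- data.frame(row = rc$row[kept], col = rc$col[kept])
  out
}
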