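#' NDVI time-series stack
#'
#' An in-memory raster time series: a `time x row x col` array of NDVI values
#' with per-step day-of-year (DOY) timestamps. Nodata cells are `NA`.
#' Georeferencing is carried as an affine geotransform in GDAL order
#' `(x_origin, x_res, row_rot, y_origin, col_rot, y_res)` and treated as
#' opaque metadata: the pipeline never reprojects or resamples.
#'
#' @param values numeric array `time x row x col`, NDVI in `[-1, 1]`,
#'   `NA` for nodata.
#' @param timestamps integer day-of-year per time step, strictly increasing.
#' @param year calendar year of the stack.
#' @param pixel_area pixel area in square metres (900 for 30 m pixels).
#' @param geotransform numeric length-6 affine transform.
#' @return An object of class `ndvi_stack`.
#' @export
ndvi_stack <- function(values, timestamps, year,
                       pixel_area = 900,
                       geotransform = c(0, 30, 0, 0, 0, -30)) {
  if (!is.array(values) || length(dim(values)) != 3) {
    abort("`values` must be a 3-d array (time x row x col).")
  }
  timestamps <- as.integer(timestamps)
  if (length(timestamps) != dim(values)[1]) {
    abort(sprintf(
      "timestamp count (%d) does not match the time dimension (%d).",
      length(timestamps), dim(values)[1]))
  }
  if (any(diff(timestamps) <= 0)) {
    abort("`timestamps` must be strictly increasing within the year.")
  }
  assert_scalar_number(pixel_area, "pixel_area", min = 0)
  if (pixel_area <= 0) abort("`pixel_area` must be > 0.")
  if (length(geotransform) != 6) abort("`geotransform` must have length 6.")
  structure(
    list(values = values, timestamps = timestamps, year = as.integer(year),
         pixel_area = pixel_area, geotransform = as.numeric(geotransform)),
    class = "ndvi_stack")
}

#' @export
print.ndvi_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<ndvi_stack> %d x %d cells, %d time steps (DOY %d..%d), year %d\n",
    d[2], d[3], d[1], min(x$timestamps), max(x$timestamps), x$year))
  cat(sprintf("  nodata cells: %d / %d observations\n",
              sum(is.na(x$values)), length(x$values)))
  invisible(x)
}

#' @export
dim.ndvi_stack <- function(x) dim(x$values)

#' Binary maize classification map
#'
#' @param values integer matrix, 1 = maize, 0 = non-maize, `NA` allowed for
#'   cells outside the evaluated region.
#' @param year calendar year.
#' @param region optional region identifier.
#' @param geotransform affine transform as in [ndvi_stack()].
#' @return An object of class `maize_map`.
#' @export
maize_map <- function(values, year, region = NA_character_,
                      geotransform = c(0, 30, 0, 0, 0, -30)) {
  if (!is.matrix(values)) abort("`values` must be a matrix.")
  vals <- values[!is.na(values)]
  if (length(vals) && !all(vals %in% c(0L, 1L))) {
    abort("map values must be 0 (non-maize) or 1 (maize).")
  }
  storage.mode(values) <- "integer"
  structure(
    list(values = values, year = as.integer(year),
         region = as.character(region),
         geotransform = as.numeric(geotransform)),
    class = "maize_map")
}

#' @export
print.maize_map <- function(x, ...) {
  cat(sprintf("<maize_map> %d x %d, year %d, maize cells: %d\n",
              nrow(x$values), ncol(x$values), x$year,
              sum(x$values == 1L, na.rm = TRUE)))
  invisible(x)
}

# --- TIFF value encoding -----------------------------------------------------
# The bundled TIFF writer only preserves samples in [0, 1]; NDVI in [-1, 1] is
# stored as s = (v + 3) / 4 in [0.5, 1] at 32-bit float, with s = 0 reserved
# for nodata. Round trip is exact to single precision (~2e-7 NDVI).
.encode_ndvi <- function(v) {
  s <- (v + 3) / 4
  s[is.na(v)] <- 0
  s
}
.decode_ndvi <- function(s) {
  v <- 4 * s - 3
  v[s < 0.25] <- NA_real_
  v
}

.sidecar_path <- function(path) paste0(path, ".aux.json")

.write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
}

.read_sidecar <- function(path) {
  sp <- .sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write an NDVI stack to a multi-page TIFF
#'
#' One 32-bit-float page per time step; timestamps, year, pixel area and the
#' geotransform go to a JSON sidecar (`<path>.aux.json`).
#'
#' @param stack an [ndvi_stack()].
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ndvi_stack"))
  pages <- lapply(seq_len(dim(stack$values)[1]), function(t) {
    .encode_ndvi(stack$values[t, , ])
  })
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L))
  .write_sidecar(path, list(
    type = "ndvi_stack", year = stack$year, timestamps = stack$timestamps,
    pixel_area = stack$pixel_area, geotransform = stack$geotransform,
    encoding = "s=(ndvi+3)/4, 0=nodata"))
  invisible(path)
}

#' Read an NDVI stack from TIFF files
#'
#' Accepts either a single multi-page TIFF (one page per time step) or a
#' vector of single-page TIFFs, one per time step. All rasters must share the
#' same grid; a mismatch is a hard error naming the offending file.
#'
#' @param paths one or more TIFF paths.
#' @param timestamps day-of-year per step; defaults to the sidecar's record.
#' @param year calendar year; defaults to the sidecar's record.
#' @param pixel_area,geotransform grid metadata overrides.
#' @return An [ndvi_stack()].
#' @export
read_stack <- function(paths, timestamps = NULL, year = NULL,
                       pixel_area = NULL, geotransform = NULL) {
  meta <- .read_sidecar(paths[[1]])
  timestamps <- timestamps %||% meta$timestamps
  year <- year %||% meta$year %||% abort("`year` is required (no sidecar).")
  pixel_area <- pixel_area %||% meta$pixel_area %||% 900
  geotransform <- geotransform %||% meta$geotransform %||% c(0, 30, 0, 0, 0, -30)
  if (is.null(timestamps)) abort("`timestamps` is required (no sidecar).")

  pages <- list()
  for (p in paths) {
    pg <- tiff::readTIFF(p, all = TRUE)
    if (!is.list(pg)) pg <- list(pg)
    for (page in pg) {
      if (length(pages) && !identical(dim(page), dim(pages[[1]]))) {
        abort(sprintf("grid mismatch in '%s': %s vs %s", p,
                      paste(dim(page), collapse = "x"),
                      paste(dim(pages[[1]]), collapse = "x")))
      }
      pages[[length(pages) + 1]] <- page
    }
  }
  if (length(pages) != length(timestamps)) {
    abort(sprintf("read %d raster pages but %d timestamps were given.",
                  length(pages), length(timestamps)))
  }
  vals <- array(NA_real_, c(length(pages), dim(pages[[1]])))
  for (t in seq_along(pages)) vals[t, , ] <- .decode_ndvi(pages[[t]])
  ndvi_stack(vals, timestamps, year, pixel_area, geotransform)
}

#' Write a binary maize map to TIFF
#'
#' Single-band 8-bit integer raster (1 = maize, 0 = non-maize); round-trips
#' bit-exactly. `NA` cells are written as 0 and flagged in the sidecar.
#'
#' @param map a [maize_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "maize_map"))
  v <- map$values
  if (any(!is.na(v) & !(v %in% c(0L, 1L)))) {
    abort("map values must be 0 or 1.")
  }
  out <- v
  out[is.na(out)] <- 0L
  tiff::writeTIFF(matrix(as.numeric(out), nrow(v), ncol(v)), path,
                  bits.per.sample = 8L)
  .write_sidecar(path, list(
    type = "maize_map", year = map$year, region = map$region,
    geotransform = map$geotransform, n_na = sum(is.na(v))))
  invisible(path)
}

#' Read a binary maize map from TIFF
#'
#' @param path TIFF path written by [write_map()] (or any single-band binary
#'   raster).
#' @param year,region,geotransform metadata overrides (default: sidecar).
#' @return A [maize_map()].
#' @export
read_map <- function(path, year = NULL, region = NULL, geotransform = NULL) {
  meta <- .read_sidecar(path)
  v <- tiff::readTIFF(path)
  if (length(dim(v)) == 3) v <- v[, , 1]
  vals <- matrix(as.integer(round(v)), nrow(v), ncol(v))
  maize_map(vals,
            year = year %||% meta$year %||% NA_integer_,
            region = region %||% meta$region %||% NA_character_,
            geotransform = geotransform %||% meta$geotransform %||%
              c(0, 30, 0, 0, 0, -30))
}

#' Read a point-sample table
#'
#' Delimited text with a header. Required columns: `id`, `year`,
#' `label` (`maize` or `other`), `region`, and either `row`/`col` (1-based
#' grid indices) or `lon`/`lat` (resolved against a geotransform downstream).
#' An optional `season` column (`spring`/`summer`) marks which standard curve
#' a maize sample belongs to.
#'
#' @param path CSV path.
#' @return A tibble of samples.
#' @export
read_samples <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("id", "year", "label", "region")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("samples table is missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (!(all(c("row", "col") %in% names(df)) ||
        all(c("lon", "lat") %in% names(df)))) {
    abort("samples table needs either row/col or lon/lat columns.")
  }
  bad <- setdiff(unique(df$label), c("maize", "other"))
  if (length(bad)) {
    abort(sprintf("unknown sample label(s): %s (allowed: maize, other)",
                  paste(bad, collapse = ", ")))
  }
  as_tibble(df)
}

#' Read a regional planting-statistics table
#'
#' Delimited text with header and columns `region`, `year`, `area_ha`
#' (statistical maize planting area in hectares, non-negative).
#'
#' @param path CSV path.
#' @return A tibble with one row per (region, year).
#' @export
read_region_stats <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(c("region", "year", "area_ha"), names(df))
  if (length(missing)) {
    abort(sprintf("statistics table is missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (any(df$area_ha < 0, na.rm = TRUE)) {
    abort("`area_ha` must be non-negative.")
  }
  as_tibble(df)
}

#' Resolve sample coordinates to grid cells
#'
#' Samples with `row`/`col` are used as-is; samples with `lon`/`lat` are
#' mapped through the geotransform using half-open pixel intervals with the
#' origin at the raster's upper-left corner.
#'
#' @param samples a samples tibble (see [read_samples()]).
#' @param geotransform affine transform of the target grid.
#' @param nrow,ncol grid dimensions.
#' @return The samples tibble with integer `row`, `col` columns; samples
#'   falling off the grid are dropped with a warning.
#' @export
resolve_cells <- function(samples, geotransform, nrow, ncol) {
  s <- samples
  if (!all(c("row", "col") %in% names(s))) {
    gt <- geotransform
    if (abs(gt[2]) < 1e-12 || abs(gt[6]) < 1e-12) {
      abort("degenerate geotransform: zero pixel size.")
    }
    s$col <- floor((s$lon - gt[1]) / gt[2]) + 1L
    s$row <- floor((s$lat - gt[4]) / gt[6]) + 1L
  }
  s$row <- as.integer(s$row); s$col <- as.integer(s$col)
  on_grid <- s$row >= 1L & s$row <= nrow & s$col >= 1L & s$col <= ncol
  if (any(!on_grid)) {
    warn(sprintf("%d sample(s) fall outside the grid and were dropped.",
                 sum(!on_grid)))
  }
  s[on_grid, , drop = FALSE]
}
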