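#' Split samples into reference and validation sets
#'
#' Randomly selects `n_reference` maize samples (uniformly, without
#' replacement) for building the standard seasonal curve; everything else —
#' the remaining maize samples and all non-maize samples — is kept for
#' validation. The two sets are disjoint and their union is the input.
#'
#' @param samples samples tibble (see [read_samples()]).
#' @param n_reference number of maize samples to reserve (default 50).
#' @param seed integer seed.
#' @param season optional season filter (`"spring"`/`"summer"`) applied to
#'   the maize pool before drawing.
#' @return A list with tibbles `reference` and `validation`.
#' @export
holdout_split <- function(samples, n_reference = 50, seed = 1L,
                          season = NULL) {
  pool <- samples$label == "maize"
  if (!is.null(season) && "season" %in% names(samples)) {
    pool <- pool & !is.na(samples$season) & samples$season == season
  }
  n_avail <- sum(pool)
  if (n_avail < n_reference) {
    abort(sprintf(
      "need %d maize samples%s but only %d are available (short by %d).",
      n_reference,
      if (is.null(season)) "" else sprintf(" (season %s)", season),
      n_avail, n_reference - n_avail))
  }
  idx <- which(pool)
  take <- with_seed(seed, sample(idx, n_reference))
  list(reference = samples[sort(take), , drop = FALSE],
       validation = samples[-sort(take), , drop = FALSE])
}

#' Build a standard seasonal NDVI curve from maize samples
#'
#' Draws `n_samples` maize samples uniformly without replacement under
#' `seed`, extracts their per-pixel NDVI series from the stack, and averages
#' them per time step (nodata observations are ignored per step; a step with
#' no valid observation at all is linearly interpolated from its
#' neighbours).
#'
#' @param stack an [ndvi_stack()].
#' @param samples samples tibble; maize rows are the candidate pool.
#' @param n_samples number of maize samples to average (default 50).
#' @param seed integer seed for the draw.
#' @param season optional season filter, and the season recorded on the
#'   curve (default `"spring"` when unset).
#' @param region region label recorded on the curve.
#' @return An object of class `reference_curve` with fields `crop`, `season`,
#'   `timestamps`, `values`, `sample_ids`, `seed`.
#' @export
build_reference <- function(stack, samples, n_samples = 50, seed = 1L,
                            season = NULL, region = NA_character_) {
  stopifnot(inherits(stack, "ndvi_stack"))
  d <- dim(stack$values)
  samples <- resolve_cells(samples, stack$geotransform, d[2], d[3])
  pool <- samples$label == "maize"
  if (!is.null(season) && "season" %in% names(samples)) {
    pool <- pool & !is.na(samples$season) & samples$season == season
  }
  n_avail <- sum(pool)
  if (n_avail < n_samples) {
    abort(sprintf(
      "need %d maize samples%s on the stack but only %d resolve (short by %d).",
      n_samples,
      if (is.null(season)) "" else sprintf(" (season %s)", season),
      n_avail, n_samples - n_avail))
  }
  chosen <- with_seed(seed, sample(which(pool), n_samples))
  sel <- samples[chosen, , drop = FALSE]
  series <- vapply(seq_len(nrow(sel)), function(k) {
    stack$values[, sel$row[k], sel$col[k]]
  }, numeric(d[1]))
  values <- rowMeans(series, na.rm = TRUE)
  if (any(!is.finite(values))) {     # time steps with zero observations
    ok <- is.finite(values)
    values <- approx(stack$timestamps[ok], values[ok],
                     xout = stack$timestamps, rule = 2)$y
  }
  structure(
    list(crop = "maize", season = season %||% "spring",
         timestamps = stack$timestamps, values = values,
         sample_ids = sel$id, seed = seed, region = region),
    class = "reference_curve")
}

#' @export
print.reference_curve <- function(x, ...) {
  cat(sprintf(
    "<reference_curve> %s maize, %d steps, NDVI %.2f..%.2f, %d samples\n",
    x$season, length(x$values), min(x$values), max(x$values),
    length(x$sample_ids)))
  invisible(x)
}

#' @export
as_tibble.reference_curve <- function(x, ...) {
  tibble(doy = x$timestamps, ndvi = x$values, season = x$season,
         region = x$region)
}

#' Write/read reference curves as CSV (columns doy, ndvi, season, region)
#'
#' @param curves a `reference_curve` or list of them.
#' @param path CSV path.
#' @return `path` invisibly; `read_reference_csv()` returns a list of
#'   `reference_curve` objects keyed by season.
#' @export
write_reference_csv <- function(curves, path) {
  if (inherits(curves, "reference_curve")) curves <- list(curves)
  readr::write_csv(purrr::map_dfr(curves, as_tibble), path)
  invisible(path)
}

#' @rdname write_reference_csv
#' @export
read_reference_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(c("doy", "ndvi", "season"), names(df))
  if (length(missing)) {
    abort(sprintf("reference CSV missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  split(df, df$season) |>
    purrr::imap(function(g, s) {
      structure(list(crop = "maize", season = s,
                     timestamps = as.integer(g$doy), values = g$ndvi,
                     sample_ids = character(0), seed = NA_integer_,
                     region = g$region[1] %||% NA_character_),
                class = "reference_curve")
    })
}
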