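#' Run configuration
#'
#' Bundles every tunable of the classification pipeline. Defaults follow the
#' standard operating point of phenology-based maize mapping: logistic time
#' weight with steepness 0.1/day and midpoint 50 days, potential-maize NDVI
#' threshold 0.3, 50 reference samples per standard curve.
#'
#' @param params a [twdtw_params()].
#' @param mask_threshold NDVI threshold of the potential-maize mask.
#' @param windows named list of growing-season DOY windows per season.
#' @param n_reference maize samples averaged per standard curve.
#' @param seed integer seed.
#' @param connectivity patch connectivity (4 or 8) for landscape metrics.
#' @return An object of class `run_config`.
#' @export
run_config <- function(params = twdtw_params(), mask_threshold = 0.3,
                       windows = list(spring = c(60, 300),
                                      summer = c(140, 300)),
                       n_reference = 50, seed = 1L, connectivity = 8) {
  stopifnot(inherits(params, "twdtw_params"))
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  structure(list(params = params, mask_threshold = mask_threshold,
                 windows = windows, n_reference = n_reference,
                 seed = as.integer(seed), connectivity = connectivity),
            class = "run_config")
}

#' Potential-maize mask
#'
#' A pixel is potential maize iff its maximum NDVI over the time steps
#' inside the growing window is strictly greater than the threshold
#' (default 0.3). The mask is a hard pre-filter: pixels failing it are
#' non-maize regardless of the area statistics.
#'
#' @param stack an [ndvi_stack()].
#' @param growing_window DOY interval `c(first, last)`, inclusive.
#' @param threshold NDVI threshold (default 0.3, strict inequality).
#' @return A logical matrix (`TRUE` = potential maize).
#' @export
potential_mask <- function(stack, growing_window = c(60, 300),
                           threshold = 0.3) {
  stopifnot(inherits(stack, "ndvi_stack"))
  inside <- stack$timestamps >= growing_window[1] &
    stack$timestamps <= growing_window[2]
  if (!any(inside)) {
    abort(sprintf("growing window [%s, %s] contains no time steps.",
                  growing_window[1], growing_window[2]))
  }
  sub <- stack$values[inside, , , drop = FALSE]
  peak <- apply(sub, c(2, 3), function(v) {
    if (all(is.na(v))) -Inf else max(v, na.rm = TRUE)
  })
  peak > threshold
}

#' Per-pixel TWDTW dissimilarity against one or two reference curves
#'
#' For every masked pixel, computes the TWDTW distance to each provided
#' standard curve and keeps the minimum (the most similar season). When two
#' curves tie, the season is broken to `"spring"` (list order).
#'
#' @param stack an [ndvi_stack()].
#' @param refs a `reference_curve` or list of them (typically spring and
#'   summer maize).
#' @param mask logical matrix of pixels to evaluate (see
#'   [potential_mask()]).
#' @param params a [twdtw_params()].
#' @return An object of class `dissimilarity_map`: `distance` (numeric
#'   matrix, `NA` where unevaluated), `season` (character matrix), `mask`.
#' @export
dissimilarity_map <- function(stack, refs, mask, params = twdtw_params()) {
  stopifnot(inherits(stack, "ndvi_stack"))
  if (inherits(refs, "reference_curve")) refs <- list(refs)
  if (!length(refs)) abort("`refs` must contain at least one curve.")
  d <- dim(stack$values)
  if (!identical(dim(mask), d[2:3])) abort("`mask` does not match the grid.")

  dist_mat <- matrix(NA_real_, d[2], d[3])
  season_mat <- matrix(NA_character_, d[2], d[3])
  cells <- which(mask)
  if (!length(cells)) {
    log_msg("warning", "no masked cells to evaluate; empty result.")
    return(structure(list(distance = dist_mat, season = season_mat,
                          mask = mask), class = "dissimilarity_map"))
  }
  flat <- matrix(stack$values, d[1], d[2] * d[3])
  series <- t(flat[, cells, drop = FALSE])       # pixels x time
  per_ref <- vapply(refs, function(rc) {
    twdtw_batch(series, stack$timestamps, rc$values, rc$timestamps, params)
  }, numeric(length(cells)))
  per_ref <- matrix(per_ref, nrow = length(cells))
  best <- max.col(-per_ref, ties.method = "first")
  seasons <- vapply(refs, function(rc) rc$season %||% "spring", character(1))
  dist_mat[cells] <- per_ref[cbind(seq_along(cells), best)]
  season_mat[cells] <- seasons[best]
  structure(list(distance = dist_mat, season = season_mat, mask = mask),
            class = "dissimilarity_map")
}

#' @export
print.dissimilarity_map <- function(x, ...) {
  n <- sum(!is.na(x$distance))
  cat(sprintf("<dissimilarity_map> %d x %d, %d evaluated cells\n",
              nrow(x$distance), ncol(x$distance), n))
  invisible(x)
}

#' Area-constrained selection of maize pixels
#'
#' Selects the `n` evaluated pixels with the smallest TWDTW distance, where
#' `n = round(statistical_area * 1e4 / pixel_area)` so the identified area
#' matches the regional statistic to within one pixel. Ties at the cut are
#' broken by row-major scan order. If fewer than `n` pixels were evaluated,
#' all are selected and the deficit is logged.
#'
#' @param dmap a [dissimilarity_map()].
#' @param statistical_area regional statistical maize area, hectares.
#' @param pixel_area pixel area in square metres.
#' @param year,region metadata stamped on the outputs.
#' @return A list: `map` ([maize_map()]) and `record` (one-row tibble with
#'   region, year, statistical and identified areas, pixel count, deficit).
#' @export
area_constrained_select <- function(dmap, statistical_area,
                                    pixel_area = 900, year = NA_integer_,
                                    region = NA_character_) {
  stopifnot(inherits(dmap, "dissimilarity_map"))
  assert_scalar_number(statistical_area, "statistical_area", min = 0)
  n_target <- round(statistical_area * 1e4 / pixel_area)
  dm <- dmap$distance
  cells <- which(!is.na(dm))
  r <- (cells - 1L) %% nrow(dm) + 1L
  co <- (cells - 1L) %/% nrow(dm) + 1L
  ord <- order(dm[cells], r, co)               # ties: row-major scan order
  n_sel <- min(n_target, length(cells))
  if (n_sel < n_target) {
    log_msg("warning", sprintf(
      "region %s: only %d evaluated pixels for a target of %d.",
      region, length(cells), n_target))
  }
  sel <- cells[ord[seq_len(n_sel)]]
  vals <- matrix(0L, nrow(dm), ncol(dm))
  vals[sel] <- 1L
  record <- tibble(
    region = region, year = as.integer(year),
    statistical_area_ha = statistical_area,
    identified_area_ha = n_sel * pixel_area / 1e4,
    n_pixels = n_sel, n_candidates = length(cells),
    deficit = n_target - n_sel)
  list(map = maize_map(vals, year, region), record = record)
}

#' End-to-end annual maize classification
#'
#' Composes the full pipeline per region: potential-maize mask over the
#' union of the seasonal growing windows, standard-curve construction from a
#' random reference draw of maize samples (held out from validation),
#' per-pixel TWDTW dissimilarity against the available seasonal curves, and
#' area-constrained selection against that region's statistical area.
#'
#' @param stack an [ndvi_stack()].
#' @param samples samples tibble for the stack's year.
#' @param stats statistics tibble (`region`, `year`, `area_ha`).
#' @param config a [run_config()].
#' @param region_map optional integer matrix of region membership (ids in
#'   the order of `sort(unique(samples$region))`); with a single region the
#'   whole grid is used.
#' @return An object of class `maize_classification`: `map` (combined
#'   [maize_map()]), `records` (tibble), `references` (list of curves per
#'   region), `validation_samples` (samples never used in any curve).
#' @export
classify_region <- function(stack, samples, stats, config = run_config(),
                            region_map = NULL) {
  stopifnot(inherits(stack, "ndvi_stack"), inherits(config, "run_config"))
  d <- dim(stack$values)
  samples <- resolve_cells(samples, stack$geotransform, d[2], d[3])
  regions <- sort(unique(samples$region))
  if (is.null(region_map)) {
    if (length(regions) > 1) {
      abort("`region_map` is required when samples span several regions.")
    }
    region_map <- matrix(1L, d[2], d[3])
  }

  combined <- matrix(0L, d[2], d[3])
  records <- list()
  references <- list()
  ref_ids <- character(0)

  for (ri in seq_along(regions)) {
    reg <- regions[ri]
    reg_samples <- samples[samples$region == reg, , drop = FALSE]
    stat_row <- stats[stats$region == reg & stats$year == stack$year, ]
    if (!nrow(stat_row)) {
      abort(sprintf("no statistics row for region '%s', year %d.",
                    reg, stack$year))
    }
    seasons <- if ("season" %in% names(reg_samples)) {
      intersect(c("spring", "summer"),
                unique(reg_samples$season[!is.na(reg_samples$season)]))
    } else "spring"
    if (!length(seasons)) seasons <- "spring"

    refs <- list()
    for (si in seq_along(seasons)) {
      s <- seasons[si]
      refs[[s]] <- build_reference(
        stack, reg_samples, n_samples = config$n_reference,
        seed = derive_seed(config$seed, ri * 10L + si),
        season = if ("season" %in% names(reg_samples)) s else NULL,
        region = reg)
      ref_ids <- c(ref_ids, refs[[s]]$sample_ids)
    }
    references[[reg]] <- refs

    win <- range(unlist(config$windows[seasons]))
    mask <- potential_mask(stack, win, config$mask_threshold) &
      (region_map == ri)
    log_msg("info", sprintf("region %s: %d potential maize pixels.",
                            reg, sum(mask)))
    dmap <- dissimilarity_map(stack, refs, mask, config$params)
    sel <- area_constrained_select(
      dmap, stat_row$area_ha[1], stack$pixel_area, stack$year, reg)
    combined <- combined + sel$map$values
    records[[reg]] <- sel$record
  }

  structure(
    list(map = maize_map(combined, stack$year,
                         paste(regions, collapse = "+"),
                         stack$geotransform),
         records = dplyr::bind_rows(records),
         references = references,
         validation_samples = samples[!(samples$id %in% ref_ids), ,
                                      drop = FALSE]),
    class = "maize_classification")
}

#' @export
print.maize_classification <- function(x, ...) {
  cat(sprintf("<maize_classification> year %d, %d region(s), %d maize pixels\n",
              x$map$year, nrow(x$records), sum(x$map$values == 1L)))
  print(x$records)
  invisible(x)
}
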