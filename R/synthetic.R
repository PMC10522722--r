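#' Double-logistic seasonal phenology parameters
#'
#' The standard two-parameter-per-shoulder seasonal NDVI model: a winter
#' baseline plus a green-up/senescence plateau,
#' `NDVI(t) = winter + (peak - winter) * (s(gr * (t - g)) +
#' s(-sr * (t - d)) - 1)` with `s` the logistic function, `g`/`d` the
#' green-up and senescence inflection days and `gr`/`sr` their rates.
#' An optional `second_season` block adds a second bump of the same form
#' (e.g. a winter-wheat cycle preceding summer maize in rotation pixels).
#'
#' @param winter_ndvi baseline (off-season) NDVI.
#' @param peak_ndvi seasonal maximum NDVI; must exceed `winter_ndvi`.
#' @param greenup_doy,senescence_doy inflection days of year,
#'   `greenup_doy < senescence_doy`.
#' @param greenup_rate,senescence_rate logistic slopes (1/day), `> 0`.
#' @param second_season optional `phenology()` whose bump (relative to its
#'   own baseline) is added to the curve.
#' @return An object of class `phenology`.
#' @export
phenology <- function(winter_ndvi, peak_ndvi, greenup_doy, senescence_doy,
                      greenup_rate, senescence_rate, second_season = NULL) {
  if (winter_ndvi >= peak_ndvi) abort("`winter_ndvi` must be < `peak_ndvi`.")
  if (greenup_doy >= senescence_doy) {
    abort("`greenup_doy` must be < `senescence_doy`.")
  }
  if (greenup_rate <= 0 || senescence_rate <= 0) abort("rates must be > 0.")
  if (!is.null(second_season) && !inherits(second_season, "phenology")) {
    abort("`second_season` must be a phenology object.")
  }
  structure(list(winter_ndvi = winter_ndvi, peak_ndvi = peak_ndvi,
                 greenup_doy = greenup_doy, senescence_doy = senescence_doy,
                 greenup_rate = greenup_rate,
                 senescence_rate = senescence_rate,
                 second_season = second_season),
            class = "phenology")
}

#' Evaluate a double-logistic phenology
#'
#' @param t day of year, in `[1, 366]` (vectorized).
#' @param p a [phenology()].
#' @return NDVI values, clipped to `[-1, 1]`.
#' @export
double_logistic <- function(t, p) {
  stopifnot(inherits(p, "phenology"))
  if (any(t < 1 | t > 366)) abort("`t` must lie in [1, 366].")
  sig <- function(z) 1 / (1 + exp(-z))
  bump <- function(q) {
    (q$peak_ndvi - q$winter_ndvi) *
      (sig(q$greenup_rate * (t - q$greenup_doy)) +
         sig(-q$senescence_rate * (t - q$senescence_doy)) - 1)
  }
  v <- p$winter_ndvi + bump(p)
  if (!is.null(p$second_season)) v <- v + bump(p$second_season)
  pmin(pmax(v, -1), 1)
}

#' Default class phenologies for the synthetic landscape
#'
#' Six land-cover classes with seasonal curves chosen to mimic the relevant
#' confusions in Chinese maize systems: spring maize (single long season),
#' summer maize (later, preceded by a winter-wheat bump in rotation pixels),
#' rice (deliberately maize-like: flood-depressed early NDVI then a rapid
#' rise, the known failure mode of NDVI-only phenology classification),
#' forest (broad high plateau), built/bare (flat low), water (flat, near
#' zero).
#'
#' @return Named list of [phenology()] objects with a `maize` attribute
#'   naming the maize classes.
#' @export
default_phenologies <- function() {
  winter_wheat_bump <- phenology(0.15, 0.65, 40, 140, 0.08, 0.10)
  ph <- list(
    spring_maize = phenology(0.15, 0.85, 130, 270, 0.08, 0.08),
    summer_maize = phenology(0.15, 0.85, 170, 285, 0.09, 0.10,
                             second_season = winter_wheat_bump),
    rice         = phenology(0.10, 0.80, 185, 290, 0.15, 0.12),
    forest       = phenology(0.35, 0.80, 100, 300, 0.05, 0.05),
    built        = phenology(0.12, 0.18, 150, 250, 0.02, 0.02),
    water        = phenology(-0.10, -0.02, 150, 250, 0.02, 0.02)
  )
  attr(ph, "maize") <- c("spring_maize", "summer_maize")
  ph
}

#' Synthetic landscape configuration
#'
#' @param nrow,ncol grid size in pixels.
#' @param classes tibble with columns `class` (names matching `phenologies`)
#'   and `proportion` (summing to 1).
#' @param phenologies named list of [phenology()] per class.
#' @param patch_meanlog,patch_sdlog lognormal patch-size distribution
#'   (pixels).
#' @param noise_sd Gaussian observation noise, NDVI units.
#' @param gap_prob per-observation deletion probability in `[0, 1)`.
#' @param n_regions number of administrative regions (vertical bands).
#' @param n_samples_per_region point samples drawn per region.
#' @param area_error multiplicative log-scale error applied to the emitted
#'   statistical areas (0 = statistics equal truth exactly).
#' @param timestamps composite days of year (default 8-day, 46 steps).
#' @param year calendar year stamped on outputs.
#' @param pixel_area pixel area in square metres.
#' @return An object of class `landscape_config`.
#' @export
landscape_config <- function(nrow = 100, ncol = 100,
                             classes = NULL,
                             phenologies = default_phenologies(),
                             patch_meanlog = 4, patch_sdlog = 1.5,
                             noise_sd = 0.02, gap_prob = 0,
                             n_regions = 1, n_samples_per_region = 600,
                             area_error = 0,
                             timestamps = seq(1, 361, by = 8),
                             year = 2019, pixel_area = 900) {
  if (is.null(classes)) {
    classes <- tibble(
      class = c("spring_maize", "summer_maize", "rice", "forest", "built",
                "water"),
      proportion = c(0.20, 0.15, 0.15, 0.25, 0.15, 0.10))
  }
  if (abs(sum(classes$proportion) - 1) > 1e-8) {
    abort("class proportions must sum to 1.")
  }
  if (gap_prob < 0 || gap_prob >= 1) abort("`gap_prob` must be in [0, 1).")
  missing_ph <- setdiff(classes$class, names(phenologies))
  if (length(missing_ph)) {
    abort(sprintf("no phenology for class(es): %s",
                  paste(missing_ph, collapse = ", ")))
  }
  structure(list(nrow = nrow, ncol = ncol, classes = classes,
                 phenologies = phenologies,
                 patch_meanlog = patch_meanlog, patch_sdlog = patch_sdlog,
                 noise_sd = noise_sd, gap_prob = gap_prob,
                 n_regions = n_regions,
                 n_samples_per_region = n_samples_per_region,
                 area_error = area_error,
                 timestamps = as.integer(timestamps), year = year,
                 pixel_area = pixel_area),
            class = "landscape_config")
}

#' Generate a synthetic landscape
#'
#' Builds a patch mosaic by seeded region growing (lognormal target sizes),
#' assigns each patch the class with the largest remaining pixel deficit so
#' realized class areas track the requested proportions to within one patch,
#' samples each pixel's NDVI series from its class phenology at the
#' composite days plus Gaussian noise, draws labeled point samples per
#' region, and emits regional statistics computed from the truth map.
#' Fully deterministic under a fixed seed.
#'
#' @param cfg a [landscape_config()].
#' @param seed integer seed governing all randomness.
#' @return A list with elements `stack` ([ndvi_stack()]), `truth`
#'   ([maize_map()] of the maize/non-maize truth), `truth_class` (matrix of
#'   class names), `region_map` (integer matrix of region ids), `samples`
#'   (tibble), and `stats` (tibble of region, year, area_ha).
#' @export
generate_landscape <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "landscape_config"))
  ncell <- cfg$nrow * cfg$ncol
  if (exp(cfg$patch_meanlog) > ncell) {
    abort("patch-size distribution unattainable on this grid.")
  }
  with_seed(seed, {
    # target patch sizes until they cover the grid
    sizes <- numeric(0)
    while (sum(sizes) < ncell) {
      sizes <- c(sizes, pmax(1, round(
        rlnorm(64, cfg$patch_meanlog, cfg$patch_sdlog))))
    }
    patch <- cpp_grow_patches(cfg$nrow, cfg$ncol, sizes)
    n_patch <- max(patch)
    patch_sizes <- tabulate(patch, n_patch)

    # assign classes by largest remaining deficit
    target <- cfg$classes$proportion * ncell
    assigned <- numeric(nrow(cfg$classes))
    patch_class <- integer(n_patch)
    for (p in order(patch_sizes, decreasing = TRUE)) {
      k <- which.max(target - assigned)
      patch_class[p] <- k
      assigned[k] <- assigned[k] + patch_sizes[p]
    }
    class_map <- matrix(cfg$classes$class[patch_class[patch]],
                        cfg$nrow, cfg$ncol)

    # per-pixel NDVI series
    nt <- length(cfg$timestamps)
    vals <- array(NA_real_, c(nt, cfg$nrow, cfg$ncol))
    curves <- vapply(cfg$classes$class, function(cl) {
      double_logistic(cfg$timestamps, cfg$phenologies[[cl]])
    }, numeric(nt))
    for (k in seq_len(nrow(cfg$classes))) {
      idx <- which(class_map == cfg$classes$class[k], arr.ind = TRUE)
      if (!nrow(idx)) next
      noise <- if (cfg$noise_sd > 0) {
        matrix(rnorm(nt * nrow(idx), 0, cfg$noise_sd), nt)
      } else 0
      series <- pmin(pmax(curves[, k] + noise, -1), 1)
      for (q in seq_len(nrow(idx))) {
        vals[, idx[q, 1], idx[q, 2]] <- if (is.matrix(series)) {
          series[, q]
        } else series
      }
    }
    stack <- ndvi_stack(vals, cfg$timestamps, cfg$year, cfg$pixel_area)

    maize_classes <- attr(cfg$phenologies, "maize") %||%
      c("spring_maize", "summer_maize")
    truth_vals <- matrix(as.integer(class_map %in% maize_classes),
                         cfg$nrow, cfg$ncol)
    truth <- maize_map(truth_vals, cfg$year, "all")

    # vertical-band regions
    region_map <- matrix(
      rep(pmin(cfg$n_regions,
               ceiling(seq_len(cfg$ncol) / (cfg$ncol / cfg$n_regions))),
          each = cfg$nrow),
      cfg$nrow, cfg$ncol)

    # point samples per region, labeled from truth
    samples <- purrr::map_dfr(seq_len(cfg$n_regions), function(r) {
      cells <- which(region_map == r)
      n <- min(cfg$n_samples_per_region, length(cells))
      cells <- sample(cells, n)
      row <- (cells - 1L) %% cfg$nrow + 1L
      col <- (cells - 1L) %/% cfg$nrow + 1L
      cl <- class_map[cbind(row, col)]
      tibble(
        id = sprintf("r%d_s%04d", r, seq_len(n)),
        row = row, col = col, year = cfg$year,
        label = ifelse(cl %in% maize_classes, "maize", "other"),
        region = sprintf("region%02d", r),
        season = dplyr::case_when(cl == "spring_maize" ~ "spring",
                                  cl == "summer_maize" ~ "summer",
                                  TRUE ~ NA_character_),
        class = cl)
    })

    # statistics from truth (optionally perturbed)
    stats <- purrr::map_dfr(seq_len(cfg$n_regions), function(r) {
      n_maize <- sum(truth_vals[region_map == r])
      area <- n_maize * cfg$pixel_area / 1e4
      if (cfg$area_error > 0) area <- area * exp(rnorm(1, 0, cfg$area_error))
      tibble(region = sprintf("region%02d", r), year = cfg$year,
             area_ha = area)
    })

    list(stack = stack, truth = truth, truth_class = class_map,
         region_map = region_map, samples = samples, stats = stats)
  })
}

#' Delete observations and refill by temporal interpolation
#'
#' Emulates cloud gaps in the fused product: each observation is deleted
#' independently with probability `gap_prob`, then refilled by linear
#' interpolation in time (edge values held constant). A pixel losing every
#' observation becomes all-nodata. The realized deleted-and-refilled
#' fraction is recorded as `filled_fraction` on the returned stack.
#'
#' @param stack an [ndvi_stack()].
#' @param gap_prob per-observation deletion probability in `[0, 1)`.
#' @param seed integer seed.
#' @return The gap-filled [ndvi_stack()] with a `filled_fraction` field.
#' @export
apply_gaps_and_fill <- function(stack, gap_prob, seed = 1L) {
  stopifnot(inherits(stack, "ndvi_stack"))
  if (gap_prob < 0 || gap_prob >= 1) abort("`gap_prob` must be in [0, 1).")
  if (gap_prob == 0) {
    stack$filled_fraction <- 0
    return(stack)
  }
  d <- dim(stack$values)
  ts <- stack$timestamps
  with_seed(seed, {
    drop <- array(runif(prod(d)) < gap_prob, d)
    vals <- stack$values
    vals[drop] <- NA_real_
    n_pix <- d[2] * d[3]
    flat <- matrix(vals, d[1], n_pix)
    for (p in seq_len(n_pix)) {
      ok <- !is.na(flat[, p])
      if (all(ok)) next
      if (!any(ok)) next                      # fully deleted: stays nodata
      flat[, p] <- approx(ts[ok], flat[ok, p], xout = ts, rule = 2)$y
    }
    stack$values <- array(flat, d)
    stack$filled_fraction <- mean(drop)
    stack
  })
}
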