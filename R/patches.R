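#' Label maize patches (connected components)
#'
#' Connected-component labeling of the maize cells of a binary map under
#' 4- or 8-neighbour connectivity (default 8, the common remote-sensing
#' choice for field patches).
#'
#' @param map a [maize_map()] or binary integer matrix.
#' @param connectivity 4 or 8.
#' @return Integer label matrix (0 = background, patches numbered from 1).
#' @export
label_patches <- function(map, connectivity = 8) {
  v <- if (inherits(map, "maize_map")) map$values else map
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  v[is.na(v)] <- 0L
  storage.mode(v) <- "integer"
  cpp_label_components(v, as.integer(connectivity))
}

#' Patch sizes of a maize map
#'
#' @inheritParams label_patches
#' @return Integer vector, one size (in pixels) per patch. Sizes partition
#'   the maize cells: they sum to the maize cell count.
#' @export
patch_sizes <- function(map, connectivity = 8) {
  lab <- label_patches(map, connectivity)
  n <- max(lab)
  if (n == 0) return(integer(0))
  tabulate(lab, n)
}

#' Fragmentation statistics and class scheme
#'
#' Small patches are those of `small_max` (default 10) pixels or fewer
#' (about 0.9 ha at 30 m); large patches exceed `large_min` (default 1000)
#' pixels (about 90 ha). The fragmentation class is `I` when the
#' small-patch proportion is below 15%, `II` between 15% and 30%
#' (inclusive), and `III` above 30%.
#'
#' @param sizes integer vector of patch sizes (see [patch_sizes()]).
#' @param small_max largest pixel count still counted as a small patch.
#' @param large_min patch sizes strictly above this count as large.
#' @return A one-row tibble: `n_patches`, `small_patch_proportion`,
#'   `large_patch_proportion`, `fragmentation_class`.
#' @export
fragmentation_stats <- function(sizes, small_max = 10, large_min = 1000) {
  if (!length(sizes)) abort("need at least one patch.")
  if (any(sizes < 1)) abort("patch sizes must be >= 1.")
  small <- mean(sizes <= small_max)
  large <- mean(sizes > large_min)
  cls <- if (small < 0.15) "I" else if (small <= 0.30) "II" else "III"
  tibble(n_patches = length(sizes),
         small_patch_proportion = small,
         large_patch_proportion = large,
         fragmentation_class = cls)
}

#' Multi-year planting-frequency map
#'
#' Counts, per cell, the years classified as maize across a list of annual
#' maps, plus the longest consecutive run of maize years (the two readings
#' of "continuous planting"). Category fractions use as denominator the
#' cells classified maize in at least one year.
#'
#' @param maps list of [maize_map()] on a shared grid (one per year).
#' @param long_run_years threshold for the long-planting category
#'   (default 10, counted as `>=`).
#' @param short_run_years threshold for the short-planting category
#'   (default 5, counted as `<`).
#' @return An object of class `frequency_map`: `count` (matrix of total
#'   maize years), `longest_run` (matrix), `n_years`, and `summary` (tibble
#'   with the category fractions under both readings).
#' @export
planting_frequency <- function(maps, long_run_years = 10,
                               short_run_years = 5) {
  if (!length(maps)) abort("need at least one annual map.")
  dims <- lapply(maps, function(m) dim(m$values))
  if (length(unique(dims)) != 1) abort("annual maps are on different grids.")
  arr <- array(unlist(lapply(maps, function(m) {
    v <- m$values; v[is.na(v)] <- 0L; v
  })), c(dims[[1]][1], dims[[1]][2], length(maps)))
  count <- apply(arr, c(1, 2), sum)
  longest_run <- apply(arr, c(1, 2), function(x) {
    r <- rle(x)
    runs <- r$lengths[r$values == 1L]
    if (length(runs)) max(runs) else 0L
  })
  ever <- count > 0
  frac <- function(m, test) if (any(ever)) mean(test(m[ever])) else NA_real_
  summary <- tibble(
    measure = rep(c("total_years", "longest_run"), each = 2),
    category = rep(c(sprintf(">=%d years", long_run_years),
                     sprintf("<%d years", short_run_years)), 2),
    fraction = c(frac(count, function(x) x >= long_run_years),
                 frac(count, function(x) x < short_run_years),
                 frac(longest_run, function(x) x >= long_run_years),
                 frac(longest_run, function(x) x < short_run_years)))
  structure(list(count = count, longest_run = longest_run,
                 n_years = length(maps), summary = summary),
            class = "frequency_map")
}

#' @export
print.frequency_map <- function(x, ...) {
  cat(sprintf("<frequency_map> %d years, %d ever-maize cells\n",
              x$n_years, sum(x$count > 0)))
  print(x$summary)
  invisible(x)
}
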