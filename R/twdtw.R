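#' Time-weighted DTW parameters
#'
#' The time weight is an additive logistic penalty on the elapsed days
#' between aligned observations: `w = 1 / (1 + exp(-alpha * (dt - beta)))`.
#' The defaults (`alpha = 0.1` per day, `beta = 50` days) penalize time
#' warps of more than about 50 days while leaving shorter warps nearly
#' free. With `time_weight_enabled = FALSE` the alignment reduces to
#' classical DTW on `|x_i - y_j|`.
#'
#' @param alpha logistic steepness (1/day), `>= 0`.
#' @param beta logistic midpoint (days), `>= 0`.
#' @param time_weight_enabled logical; `FALSE` gives plain DTW.
#' @param circular_time if `TRUE`, day-of-year gaps wrap around the year
#'   (`period` days); default is plain elapsed-day magnitude.
#' @param period year length in days used when `circular_time = TRUE`.
#' @return An object of class `twdtw_params`.
#' @export
twdtw_params <- function(alpha = 0.1, beta = 50, time_weight_enabled = TRUE,
                         circular_time = FALSE, period = 366) {
  assert_scalar_number(alpha, "alpha", min = 0)
  assert_scalar_number(beta, "beta", min = 0)
  structure(list(alpha = alpha, beta = beta,
                 time_weight_enabled = isTRUE(time_weight_enabled),
                 circular_time = isTRUE(circular_time),
                 period = period),
            class = "twdtw_params")
}

#' Logistic time weight
#'
#' @param delta_days elapsed days between two observations, `>= 0`.
#' @param params a [twdtw_params()].
#' @return Weight in `(0, 1)`, strictly increasing in `delta_days`.
#' @export
time_weight <- function(delta_days, params = twdtw_params()) {
  if (any(delta_days < 0)) abort("`delta_days` must be non-negative.")
  1 / (1 + exp(-params$alpha * (delta_days - params$beta)))
}

.check_series <- function(x, tx, y, ty) {
  if (length(x) == 0 || length(y) == 0) abort("series must be non-empty.")
  if (length(x) != length(tx)) abort("`x` and `tx` lengths differ.")
  if (length(y) != length(ty)) abort("`y` and `ty` lengths differ.")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("series values must be finite (fill gaps first).")
  }
}

#' Base (local) cost matrix
#'
#' Entry `(i, j)` is `|x_i - y_j|` plus, when time weighting is enabled, the
#' logistic weight of the day gap `|tx_i - ty_j|`.
#'
#' @param x,tx query series values and day-of-year timestamps.
#' @param y,ty reference series values and timestamps.
#' @param params a [twdtw_params()].
#' @return An `n x m` numeric matrix.
#' @export
base_cost_matrix <- function(x, tx, y, ty, params = twdtw_params()) {
  .check_series(x, tx, y, ty)
  cpp_base_cost(as.numeric(x), as.numeric(tx), as.numeric(y), as.numeric(ty),
                params$alpha, params$beta, params$time_weight_enabled,
                params$circular_time, params$period)
}

#' Cumulative cost matrix
#'
#' Dynamic-programming accumulation over the three monotone steps
#' (up, left, diagonal): `d[i,j] = base[i,j] + min(d[i-1,j], d[i-1,j-1],
#' d[i,j-1])`, with running-sum boundaries.
#'
#' @param base a base cost matrix.
#' @return The cumulative cost matrix, same shape.
#' @export
accumulate_cost <- function(base) {
  if (!is.matrix(base) || !all(is.finite(base))) {
    abort("`base` must be a finite numeric matrix.")
  }
  cpp_accumulate(base)
}

#' Time-weighted DTW distance and alignment
#'
#' Full-sequence alignment from `(1, 1)` to `(n, m)`. The distance is the
#' minimum, over all monotone warping paths, of the summed base costs; the
#' optimal path is recovered by backtracking with a deterministic tie-break
#' (diagonal, then up, then left).
#'
#' @inheritParams base_cost_matrix
#' @return An object of class `twdtw_alignment` with elements `distance`,
#'   `base_matrix`, `cumulative_matrix`, and `path` (a tibble of `i`, `j`).
#' @export
twdtw_distance <- function(x, tx, y, ty, params = twdtw_params()) {
  base <- base_cost_matrix(x, tx, y, ty, params)
  cum <- cpp_accumulate(base)
  path <- cpp_backtrack(cum)
  structure(
    list(distance = cum[nrow(cum), ncol(cum)],
         base_matrix = base, cumulative_matrix = cum,
         path = tibble(i = path[, 1], j = path[, 2]),
         params = params,
         n = length(x), m = length(y)),
    class = "twdtw_alignment")
}

#' @export
print.twdtw_alignment <- function(x, ...) {
  cat(sprintf("<twdtw_alignment> n=%d, m=%d, distance=%.6g, path length=%d\n",
              x$n, x$m, x$distance, nrow(x$path)))
  invisible(x)
}

#' @describeIn twdtw_distance one row per warping-path step with its local
#'   cost.
#' @param x a `twdtw_alignment`.
#' @param ... unused.
#' @export
tidy.twdtw_alignment <- function(x, ...) {
  dplyr::mutate(x$path, base_cost = x$base_matrix[cbind(.data$i, .data$j)])
}

#' @describeIn twdtw_distance one-row summary (distance, sizes, path length).
#' @export
glance.twdtw_alignment <- function(x, ...) {
  tibble(distance = x$distance, n = x$n, m = x$m,
         path_length = nrow(x$path),
         time_weighted = x$params$time_weight_enabled)
}

# batch distances for classification: series as pixels x time matrix
twdtw_batch <- function(series, tx, y, ty, params) {
  cpp_twdtw_batch(series, as.numeric(tx), as.numeric(y), as.numeric(ty),
                  params$alpha, params$beta, params$time_weight_enabled,
                  params$circular_time, params$period)
}
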