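# Independent brute-force DTW oracle: enumerate every monotone warping path
# from (1,1) to (n,m) with steps {down, right, diagonal} and take the minimum
# summed base cost. Feasible for n, m <= 6 (<= 1683 paths); path sets are
# cached per shape.
.oracle_paths <- new.env(parent = emptyenv())

enumerate_monotone_paths <- function(n, m) {
  key <- paste(n, m, sep = "x")
  if (!is.null(.oracle_paths[[key]])) return(.oracle_paths[[key]])
  res <- list()
  walk <- function(i, j, acc) {
    acc[[length(acc) + 1]] <- c(i, j)
    if (i == n && j == m) {
      res[[length(res) + 1]] <<- do.call(rbind, acc)
      return(invisible())
    }
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
    if (i < n && j < m) walk(i + 1, j + 1, acc)
  }
  walk(1, 1, list())
  .oracle_paths[[key]] <- res
  res
}

# base cost computed here from first principles (not via the package)
oracle_base <- function(x, tx, y, ty, alpha = 0.1, beta = 50,
                        weighted = TRUE) {
  d <- abs(outer(x, y, "-"))
  if (weighted) {
    dt <- abs(outer(tx, ty, "-"))
    d <- d + 1 / (1 + exp(-alpha * (dt - beta)))
  }
  d
}

oracle_dtw <- function(base) {
  paths <- enumerate_monotone_paths(nrow(base), ncol(base))
  min(vapply(paths, function(p) sum(base[p]), numeric(1)))
}

# small deterministic landscape for pipeline tests
small_landscape <- function(nrow = 60, ncol = 60, noise_sd = 0,
                            n_regions = 1, seed = 42,
                            n_samples_per_region = 700) {
  cfg <- landscape_config(nrow = nrow, ncol = ncol, noise_sd = noise_sd,
                          n_regions = n_regions,
                          n_samples_per_region = n_samples_per_region)
  generate_landscape(cfg, seed = seed)
}

# stack with a single pixel holding a given series
one_pixel_stack <- function(values, timestamps = seq(1, 361, by = 8),
                            year = 2019) {
  arr <- array(values, c(length(values), 1, 1))
  ndvi_stack(arr, timestamps, year)
}
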