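test_that("the potential-maize mask applies a strict 0.3 threshold", {
  ts <- seq(1, 361, by = 8)
  vals <- array(0, c(46, 1, 4))
  vals[, 1, 1] <- 0.2                          # flat low: excluded
  vals[, 1, 2] <- 0.2; vals[20, 1, 2] <- 0.8   # peak inside window: included
  vals[, 1, 3] <- 0.3                          # exactly 0.3: excluded
  vals[, 1, 4] <- 0.2; vals[1, 1, 4] <- 0.9    # peak outside window
  stack <- ndvi_stack(vals, ts, 2019)
  m <- potential_mask(stack, c(60, 300))
  expect_equal(as.vector(m), c(FALSE, TRUE, FALSE, FALSE))
  expect_error(potential_mask(stack, c(362, 365)), "no time steps")
})

test_that("dissimilarity against one or two curves keeps the closer season", {
  ts <- seq(1, 361, by = 8)
  spring <- double_logistic(ts, phenology(0.15, 0.85, 130, 270, 0.08, 0.08))
  summer <- double_logistic(ts, phenology(0.15, 0.85, 170, 285, 0.09, 0.10))
  vals <- array(NA_real_, c(46, 1, 2))
  vals[, 1, 1] <- spring
  vals[, 1, 2] <- summer
  stack <- ndvi_stack(vals, ts, 2019)
  mk_ref <- function(v, s) structure(
    list(crop = "maize", season = s, timestamps = ts, values = v,
         sample_ids = character(0), seed = 1, region = "r"),
    class = "reference_curve")
  refs <- list(mk_ref(spring, "spring"), mk_ref(summer, "summer"))
  mask <- matrix(TRUE, 1, 2)
  dm <- dissimilarity_map(stack, refs, mask, twdtw_params())
  # a pixel identical to a reference scores the 46-step self-distance
  expect_equal(dm$distance[1, 1], 46 / (1 + exp(5)), tolerance = 1e-9)
  expect_equal(dm$distance[1, 2], 46 / (1 + exp(5)), tolerance = 1e-9)
  expect_equal(dm$season[1, ], c("spring", "summer"))
  # single reference: the minimum is that reference's distance
  dm1 <- dissimilarity_map(stack, refs[[1]], mask, twdtw_params())
  expect_equal(dm1$distance[1, 1], 46 / (1 + exp(5)), tolerance = 1e-9)
  expect_gt(dm1$distance[1, 2], dm1$distance[1, 1])
  # two identical references: season tie broken to spring (list order)
  dm2 <- dissimilarity_map(stack, list(mk_ref(spring, "spring"),
                                       mk_ref(spring, "summer")),
                           mask, twdtw_params())
  expect_equal(unique(as.vector(dm2$season)), "spring")
  # no masked cells: empty result, not an error
  dm0 <- dissimilarity_map(stack, refs, matrix(FALSE, 1, 2), twdtw_params())
  expect_true(all(is.na(dm0$distance)))
})

toy_dmap <- function(distances = c(3, 1, 2, 5, 4)) {
  dm <- matrix(distances, 1, length(distances))
  structure(list(distance = dm,
                 season = matrix("spring", 1, length(distances)),
                 mask = !is.na(dm)),
            class = "dissimilarity_map")
}

test_that("area-constrained selection takes the closest n pixels", {
  dmap <- toy_dmap()
  # target n = 2 at 900 m2/pixel: area = 2 * 0.09 ha
  sel <- area_constrained_select(dmap, 2 * 900 / 1e4, 900, 2019, "r1")
  expect_equal(as.vector(sel$map$values), c(0L, 1L, 1L, 0L, 0L))
  expect_equal(sel$record$n_pixels, 2)
  expect_equal(sel$record$identified_area_ha, 2 * 900 / 1e4)
  # zero statistical area: all-zero map
  z <- area_constrained_select(dmap, 0, 900, 2019, "r1")
  expect_true(all(z$map$values == 0L))
  # saturation: target equals the evaluated count
  full <- area_constrained_select(dmap, 5 * 900 / 1e4, 900, 2019, "r1")
  expect_true(all(full$map$values == 1L))
  expect_error(area_constrained_select(dmap, -1), ">=")
})

test_that("selection conserves area and nests as the target grows", {
  set.seed(31)
  dm <- matrix(runif(400), 20, 20)
  dm[sample(400, 60)] <- NA
  dmap <- structure(list(distance = dm, season = matrix("spring", 20, 20),
                         mask = !is.na(dm)),
                    class = "dissimilarity_map")
  n_eval <- sum(!is.na(dm))
  prev <- NULL
  for (n in c(10, 50, 120, 250, 340)) {
    sel <- area_constrained_select(dmap, n * 900 / 1e4, 900)
    expect_equal(sel$record$n_pixels, min(n, n_eval))
    expect_lte(abs(sel$record$identified_area_ha -
                     sel$record$statistical_area_ha),
               900 / 1e4 + 1e-12)
    if (!is.null(prev)) expect_true(all(sel$map$values[prev == 1L] == 1L))
    prev <- sel$map$values
  }
  # an infeasible target selects everything and reports the deficit
  over <- area_constrained_select(dmap, (n_eval + 50) * 900 / 1e4, 900)
  expect_equal(over$record$n_pixels, n_eval)
  expect_equal(over$record$deficit, 50)
})

test_that("ties at the cut are broken in row-major scan order", {
  dm <- matrix(c(1, 1, 1, 1), 2, 2)     # all equal: first two in scan order
  dmap <- structure(list(distance = dm, season = matrix("spring", 2, 2),
                         mask = matrix(TRUE, 2, 2)),
                    class = "dissimilarity_map")
  sel <- area_constrained_select(dmap, 2 * 900 / 1e4, 900)
  expect_equal(sel$map$values, matrix(c(1L, 0L, 1L, 0L), 2, 2))
})

test_that("zero-noise classification with exact statistics recovers truth", {
  land <- small_landscape(nrow = 60, ncol = 60, noise_sd = 0, seed = 13)
  res <- classify_region(land$stack, land$samples, land$stats,
                         run_config(seed = 3))
  expect_identical(res$map$values, land$truth$values)
  # reference samples are held out of the validation set
  used <- unlist(lapply(res$references[[1]], function(r) r$sample_ids))
  expect_length(intersect(used, res$validation_samples$id), 0)
})

test_that("classification is deterministic and validates its stats input", {
  land <- small_landscape(nrow = 40, ncol = 40, noise_sd = 0.02, seed = 17,
                          n_samples_per_region = 800)
  r1 <- classify_region(land$stack, land$samples, land$stats,
                        run_config(seed = 5, n_reference = 25))
  r2 <- classify_region(land$stack, land$samples, land$stats,
                        run_config(seed = 5, n_reference = 25))
  expect_identical(r1$map$values, r2$map$values)
  bad_stats <- dplyr::mutate(land$stats, year = 1999)
  expect_error(classify_region(land$stack, land$samples, bad_stats,
                               run_config(seed = 5, n_reference = 25)),
               "region01.*2019")
})
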