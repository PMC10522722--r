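test_that("double-logistic curve matches its closed form and limits", {
  p <- phenology(0.2, 0.9, 150, 260, 0.1, 0.1)
  sig <- function(z) 1 / (1 + exp(-z))
  expect_equal(double_logistic(150, p),
               0.2 + 0.7 * (0.5 + sig(-0.1 * (150 - 260)) - 1),
               tolerance = 1e-12)
  # steep symmetric plateau: midway value ~ peak
  steep <- phenology(0.2, 0.9, 150, 260, 2, 2)
  expect_equal(double_logistic(205, steep), 0.9, tolerance = 1e-6)
  # far off-season: ~ winter baseline
  expect_equal(double_logistic(1, steep), 0.2, tolerance = 1e-6)
  expect_error(double_logistic(0, p), "1, 366")
  expect_error(phenology(0.9, 0.2, 150, 260, 0.1, 0.1), "winter")
  expect_error(phenology(0.2, 0.9, 260, 150, 0.1, 0.1), "greenup")
  expect_error(phenology(0.2, 0.9, 150, 260, -0.1, 0.1), "rates")
})

test_that("a second season adds its bump on top of the first", {
  wheat <- phenology(0.15, 0.65, 40, 140, 0.08, 0.10)
  rot <- phenology(0.15, 0.85, 170, 285, 0.09, 0.10, second_season = wheat)
  base <- phenology(0.15, 0.85, 170, 285, 0.09, 0.10)
  # around the wheat peak the rotation curve sits clearly higher
  expect_gt(double_logistic(90, rot), double_logistic(90, base) + 0.3)
  # late-season values coincide (wheat bump has died off)
  expect_equal(double_logistic(240, rot), double_logistic(240, base),
               tolerance = 1e-3)
})

test_that("landscape generation is deterministic and conserves areas", {
  a <- small_landscape(seed = 11)
  b <- small_landscape(seed = 11)
  expect_identical(a$truth$values, b$truth$values)
  expect_equal(a$stack$values, b$stack$values)
  expect_identical(a$samples, b$samples)
  # truth-map maize area flows exactly into the statistics
  n_maize <- sum(a$truth$values)
  expect_equal(a$stats$area_ha, n_maize * 900 / 1e4)
})

test_that("a pure-maize mixture yields an all-maize truth map", {
  cfg <- landscape_config(
    nrow = 30, ncol = 30,
    classes = tibble::tibble(class = "spring_maize", proportion = 1))
  land <- generate_landscape(cfg, seed = 3)
  expect_true(all(land$truth$values == 1L))
  expect_equal(land$stats$area_ha, 900 * 900 / 1e4)
})

test_that("class pixel counts deviate from targets by at most one patch", {
  cfg <- landscape_config(nrow = 100, ncol = 100)
  land <- generate_landscape(cfg, seed = 5)
  counts <- as.vector(table(factor(land$truth_class,
                                   levels = cfg$classes$class)))
  target <- cfg$classes$proportion * 100 * 100
  # patch sizes of the mosaic bound the assignment error
  mosaic_sizes <- as.vector(table(land$truth_class))  # per class, not patch
  # recover actual patch sizes from connected components of each class
  max_patch <- max(vapply(cfg$classes$class, function(cl) {
    sz <- patch_sizes(matrix(as.integer(land$truth_class == cl), 100, 100), 4)
    if (length(sz)) max(sz) else 0L
  }, numeric(1)))
  expect_true(all(abs(counts - target) <= max_patch))
})

test_that("unattainable patch-size distributions are rejected", {
  expect_error(
    generate_landscape(landscape_config(nrow = 10, ncol = 10,
                                        patch_meanlog = 10), seed = 1),
    "unattainable")
})

test_that("gap filling recovers linear series and reports the filled share", {
  nt <- 46; ts <- seq(1, 361, by = 8)
  lin <- array(rep(seq(0, 0.9, length.out = nt), times = 25), c(nt, 5, 5))
  stack <- ndvi_stack(lin, ts, 2019)
  same <- apply_gaps_and_fill(stack, 0, seed = 1)
  expect_equal(same$values, stack$values)
  expect_equal(same$filled_fraction, 0)
  filled <- apply_gaps_and_fill(stack, 0.5, seed = 7)
  expect_equal(filled$filled_fraction, 0.5, tolerance = 0.1)
  # linear interpolation is exact on lines wherever the endpoints survived;
  # check pixels whose first and last observations were kept
  for (r in 1:5) for (co in 1:5) {
    v <- filled$values[, r, co]
    if (!any(is.na(v)) &&
        isTRUE(all.equal(v[1], lin[1, r, co])) &&
        isTRUE(all.equal(v[nt], lin[nt, r, co]))) {
      expect_equal(v, lin[, r, co], tolerance = 1e-12)
    }
  }
  expect_error(apply_gaps_and_fill(stack, 1), "\\[0, 1\\)")
})

test_that("heavier noise degrades downstream classification accuracy", {
  oa <- vapply(c(0.02, 0.35), function(sd) {
    land <- small_landscape(nrow = 50, ncol = 50, noise_sd = sd, seed = 21,
                            n_samples_per_region = 1000)
    res <- classify_region(land$stack, land$samples, land$stats,
                           run_config(seed = 9, n_reference = 30))
    mean(res$map$values == land$truth$values) * 100
  }, numeric(1))
  expect_gt(oa[1], oa[2])
})
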