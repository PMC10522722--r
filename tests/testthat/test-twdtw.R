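test_that("logistic time weight has the right midpoint, tails and monotonicity", {
  p <- twdtw_params(alpha = 0.1, beta = 50)
  expect_equal(time_weight(50, p), 0.5, tolerance = 1e-12)
  expect_equal(time_weight(0, p), 1 / (1 + exp(5)), tolerance = 1e-12)
  expect_equal(time_weight(1000, p), 1, tolerance = 1e-9)
  deltas <- seq(0, 400, by = 5)
  w <- time_weight(deltas, p)
  expect_true(all(diff(w) > 0))
  expect_true(all(w > 0 & w < 1))
  expect_error(time_weight(-1, p), "non-negative")
})

test_that("twdtw_params validates its domain", {
  expect_error(twdtw_params(alpha = -0.1), ">=")
  expect_error(twdtw_params(beta = -5), ">=")
})

test_that("base cost matrix matches the closed form", {
  p <- twdtw_params()
  # identical series, weights disabled: zero diagonal
  x <- c(0.1, 0.5, 0.9); tx <- c(9, 17, 25)
  b0 <- base_cost_matrix(x, tx, x, tx, twdtw_params(time_weight_enabled = FALSE))
  expect_equal(diag(b0), rep(0, 3))
  # single-entry evaluation
  b1 <- base_cost_matrix(0.5, 100, 0.2, 100, p)
  expect_equal(b1[1, 1], 0.3 + 1 / (1 + exp(5)), tolerance = 1e-12)
  # weighted entries always exceed the plain value difference
  set.seed(1)
  x <- runif(5); y <- runif(4)
  tx <- sort(sample(1:360, 5)); ty <- sort(sample(1:360, 4))
  b <- base_cost_matrix(x, tx, y, ty, p)
  expect_true(all(b >= abs(outer(x, y, "-"))))
  expect_error(base_cost_matrix(numeric(0), numeric(0), y, ty, p),
               "non-empty")
})

test_that("cumulative matrix follows the recursion and its boundaries", {
  base <- matrix(c(1, 3, 2, 1), 2, 2)   # [[1,2],[3,1]] row-wise
  expect_equal(accumulate_cost(base), matrix(c(1, 4, 3, 2), 2, 2))
  # 1 x m: forced path, prefix sums
  b <- matrix(c(2, 1, 4), 1, 3)
  expect_equal(accumulate_cost(b), matrix(cumsum(c(2, 1, 4)), 1, 3))
  z <- matrix(0, 4, 5)
  expect_equal(accumulate_cost(z), z)
  set.seed(2)
  r <- matrix(runif(30), 5, 6)
  expect_true(all(accumulate_cost(r) >= r))
})

test_that("self-alignment distances take their analytic values", {
  p <- twdtw_params()
  tx <- seq(1, 361, by = 8)
  x <- sin(tx / 60) * 0.4 + 0.4
  al <- twdtw_distance(x, tx, x, tx, p)
  expect_equal(al$distance, length(x) / (1 + exp(5)), tolerance = 1e-9)
  al0 <- twdtw_distance(x, tx, x, tx,
                        twdtw_params(time_weight_enabled = FALSE))
  expect_equal(al0$distance, 0, tolerance = 1e-12)
})

test_that("alignment path is monotone, complete, and prices the distance", {
  set.seed(3)
  x <- runif(7); tx <- sort(sample(1:300, 7))
  y <- runif(5); ty <- sort(sample(1:300, 5))
  al <- twdtw_distance(x, tx, y, ty, twdtw_params())
  path <- as.matrix(al$path)
  expect_equal(path[1, ], c(i = 1, j = 1))
  expect_equal(path[nrow(path), ], c(i = 7, j = 5))
  steps <- diff(path)
  expect_true(all(steps %in% 0:1) && all(rowSums(steps) >= 1))
  expect_equal(sum(al$base_matrix[path]), al$distance, tolerance = 1e-9)
  expect_gte(al$distance, 0)
})

test_that("distance equals exhaustive path enumeration (weighted and not)", {
  set.seed(4)
  for (k in 1:60) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    x <- runif(n); y <- runif(m)
    tx <- sort(sample(1:360, n)); ty <- sort(sample(1:360, m))
    for (w in c(TRUE, FALSE)) {
      p <- twdtw_params(time_weight_enabled = w)
      got <- twdtw_distance(x, tx, y, ty, p)$distance
      want <- oracle_dtw(oracle_base(x, tx, y, ty, weighted = w))
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
  # the spec'd toy: step pattern vs its stretched version
  got <- twdtw_distance(c(0, 1, 0), c(1, 9, 17),
                        c(0, 0, 1, 1, 0, 0), c(1, 9, 17, 25, 33, 41),
                        twdtw_params(time_weight_enabled = FALSE))$distance
  want <- oracle_dtw(oracle_base(c(0, 1, 0), c(1, 9, 17),
                                 c(0, 0, 1, 1, 0, 0), c(1, 9, 17, 25, 33, 41),
                                 weighted = FALSE))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("unweighted distance is symmetric; weighted grows with time gaps", {
  set.seed(5)
  p0 <- twdtw_params(time_weight_enabled = FALSE)
  pw <- twdtw_params()
  for (k in 1:20) {
    n <- sample(3:8, 1); m <- sample(3:8, 1)
    x <- runif(n); y <- runif(m)
    tx <- sort(sample(1:180, n)); ty <- sort(sample(1:180, m))
    expect_equal(twdtw_distance(x, tx, y, ty, p0)$distance,
                 twdtw_distance(y, ty, x, tx, p0)$distance,
                 tolerance = 1e-12)
    # doubling every timestamp doubles every |t_i - t_j| gap
    d1 <- twdtw_distance(x, tx, y, ty, pw)$distance
    d2 <- twdtw_distance(x, 2 * tx, y, 2 * ty, pw)$distance
    expect_gte(d2, d1 - 1e-12)
  }
})

test_that("tidy and glance expose the alignment as tables", {
  al <- twdtw_distance(c(0.2, 0.8), c(10, 50), c(0.2, 0.8), c(10, 50))
  td <- tidy(al)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("i", "j", "base_cost"))
  gl <- glance(al)
  expect_equal(gl$distance, al$distance)
  expect_equal(gl$n, 2)
})
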