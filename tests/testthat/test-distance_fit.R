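test_that("distance bins tile the range and map distances uniquely", {
  b <- distance_bins()
  expect_equal(nrow(b), 75)
  expect_equal(b$lower[1], 0)
  expect_equal(b$upper[75], 1.5e6)
  expect_equal(b$upper[-75], b$lower[-1])
  # boundary mapping: half-open (lower, upper]
  expect_equal(assign_bins(c(1, 20000, 20001, 1.5e6), b), c(1L, 1L, 2L, 75L))
  expect_true(is.na(assign_bins(0, b)))
  expect_true(is.na(assign_bins(1.5e6 + 1, b)))
  expect_true(is.na(assign_bins(NA_real_, b)))
  expect_error(distance_bins(20000, 1.49e6), "multiple")
})

test_that("per-bin estimates are geometric means of non-zero counts", {
  b <- distance_bins()
  tbl <- tibble::tibble(
    bait_id = 1, other_id = 2:9,
    count = c(2, 0, 8, 5, 0, 0, 3, 3),
    distance_bp = c(10000, 12000, 15000, 30000, 50000, 52000, 70000, 71000))
  est <- estimate_distance_function(tbl, b)
  expect_equal(est$geo_mean[1], exp((log(2) + log(8)) / 2)) # {2,0,8} -> 4
  expect_equal(est$geo_mean[1], 4)
  expect_equal(est$geo_mean[2], 5)                          # singleton
  expect_true(est$empty[3])                                 # {0,0}
  expect_equal(est$n_nonzero[4], 2)
  expect_error(estimate_distance_function(tbl[0, ], b), "no interactions")
})

test_that("noiseless log-log fits are recovered exactly", {
  b <- distance_bins()
  centers <- b$center
  # exact power law: log f = 3 - log d
  est <- tibble::tibble(bin = b$bin, center = centers,
                        geo_mean = exp(3 - log(centers)),
                        n_nonzero = 10L, n_pairs = 10L, empty = FALSE)
  fits <- fit_distance_curves(est, b)
  expect_equal(unname(fits$linear$coefficients), c(3, -1), tolerance = 1e-10)
  expect_equal(unname(fits$cubic$coefficients[3:4]), c(0, 0), tolerance = 1e-8)
  expect_equal(unname(fits$theoretical$coefficients), 3, tolerance = 1e-10)
  expect_equal(fits$linear$curvature_K, 0)
  expect_equal(fits$theoretical$curvature_K, 0)
  # noiseless quadratic recovered by the cubic fit
  est2 <- est |>
    dplyr::mutate(geo_mean = exp(1 + 0.5 * log(centers) -
                                   0.02 * log(centers)^2))
  cub <- fit_distance_curves(est2, b)$cubic
  expect_equal(unname(cub$coefficients), c(1, 0.5, -0.02, 0),
               tolerance = 1e-6)
  # too few usable bins
  est3 <- est |> dplyr::mutate(empty = dplyr::row_number() > 4)
  expect_error(fit_distance_curves(est3, b), "at least 5")
})

test_that("curvature integral matches the closed form and its invariances", {
  # y(x) = x^2/2 has K = x/sqrt(1+x^2) evaluated at the bounds
  f <- chicbench:::new_distance_fit("cubic", c(a0 = 0, a1 = 0, a2 = 0.5, a3 = 0),
                                    rss = 0)
  x0 <- log(1e4); x1 <- log(1.5e6)
  closed <- x1 / sqrt(1 + x1^2) - x0 / sqrt(1 + x0^2)
  expect_equal(curvature_K(f), closed, tolerance = 1e-8)
  # invariant under vertical shift
  g <- f; g$coefficients["a0"] <- 17
  expect_equal(curvature_K(g), curvature_K(f), tolerance = 1e-10)
  # affine fits have exactly zero curvature
  lin <- chicbench:::new_distance_fit("linear", c(b0 = 2, b1 = -1.2), rss = 0)
  expect_identical(curvature_K(lin), 0)
})

test_that("distance fits extrapolate linearly on the log-log scale", {
  f <- chicbench:::new_distance_fit("cubic",
                                    c(a0 = 1, a1 = -0.5, a2 = 0.02, a3 = -0.001),
                                    rss = 0)
  lo <- 1e4; hi <- 1.5e6
  # slope below/above the range equals the boundary tangent slope
  for (edge in list(c(lo, 0.5), c(hi, 2))) {
    d0 <- edge[1] * edge[2]
    d1 <- d0 * 1.1
    slope_out <- (log(eval_distance_fit(f, d1)) -
                    log(eval_distance_fit(f, d0))) / (log(d1) - log(d0))
    x <- log(edge[1])
    slope_edge <- -0.5 + 2 * 0.02 * x + 3 * (-0.001) * x^2
    expect_equal(slope_out, slope_edge, tolerance = 1e-9)
  }
  # continuous at the boundaries
  expect_equal(eval_distance_fit(f, lo * (1 - 1e-9)),
               eval_distance_fit(f, lo), tolerance = 1e-6)
})

test_that("tidy and glance expose fit coefficients and quality", {
  b <- distance_bins()
  est <- tibble::tibble(bin = b$bin, center = b$center,
                        geo_mean = exp(3 - log(b$center)),
                        n_nonzero = 10L, n_pairs = 10L, empty = FALSE)
  fits <- fit_distance_curves(est, b)
  td <- tidy(fits$cubic)
  expect_equal(td$term, c("a0", "a1", "a2", "a3"))
  gl <- glance(fits$linear)
  expect_equal(gl$kind, "linear")
  expect_true(gl$rss >= 0)
})
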