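test_that("the uniform profile follows the inverse-square law in L", {
  p <- strat_problem(list(dist_spec("uniform", location = 0, scale = 12)),
                     y0 = 0, d = 12, L = 4, npts = 600)
  prof <- strata_profile(p, L_max = 6, n = 100)
  # V(1) = d^2 / (12 n) = 0.12, then 0.03 at L = 2, 0.0075 at L = 4
  expect_equal(prof$variance[1], 0.12, tolerance = 1e-6)
  expect_equal(prof$variance[2], 0.03, tolerance = 0.02 * 0.03)
  expect_equal(prof$variance[4], 0.0075, tolerance = 0.02 * 0.0075)
  for (L in 1:6) {
    expect_equal(prof$variance[L], 0.12 / L^2, tolerance = 0.02 * 0.12 / L^2)
  }
  expect_equal(prof$variance, prof$objective^2 / 100, tolerance = 1e-12)
  expect_true(all(diff(prof$objective) <= 1e-12))
})

test_that("elbow heuristics behave on stylized profiles", {
  mk <- function(V) data.frame(L = seq_along(V), variance = V)
  inv_sq <- mk(1 / (1:25)^2)
  expect_identical(suggest_elbow(inv_sq, threshold = 0.10), 19L)
  expect_identical(suggest_elbow(inv_sq, threshold = 0.25), 7L)
  expect_identical(suggest_elbow(mk(rep(0.5, 10))), 1L)
  expect_warning(res <- suggest_elbow(mk(0.5^(1:10)), threshold = 0.10),
                 "L_max")
  expect_identical(res, 10L)
  # curvature rule flags the kink of a piecewise-geometric profile
  kinked <- mk(c(1, 0.25, 0.0625, 0.055, 0.049, 0.045))
  expect_identical(suggest_elbow(kinked, method = "curvature"), 3L)
})

test_that("cumulative sqrt(f) boundaries match hand enumeration", {
  # 4 bins on [0, 4] with frequencies 9, 1, 1, 9 -> cut after bin 2
  x <- c(0, rep(0.5, 8), 1.5, 2.5, rep(3.5, 8), 4)
  b <- cum_sqrt_f_boundaries(x, L = 2, n_bins = 4)
  expect_equal(b, 2, tolerance = 1e-6)
  # equal frequencies split at the middle edge
  xe <- rep(seq(0.05, 0.95, by = 0.1), each = 5)
  expect_equal(cum_sqrt_f_boundaries(c(0, xe, 1), L = 2, n_bins = 10), 0.5,
               tolerance = 1e-9)
  # saturation: L = n_bins puts every bin in its own stratum
  expect_equal(cum_sqrt_f_boundaries(c(0, xe, 1), L = 10, n_bins = 10),
               seq(0.1, 0.9, by = 0.1), tolerance = 1e-9)
  expect_error(cum_sqrt_f_boundaries(rep(1, 30), 2), "degenerate")
  expect_error(cum_sqrt_f_boundaries(runif(30), 5, n_bins = 4), "at least L")
})

test_that("geometric boundaries follow the progression", {
  expect_equal(geometric_boundaries(1, 16, 4), c(2, 4, 8))
  expect_equal(geometric_boundaries(1, 100, 2), 10)
  expect_length(geometric_boundaries(1, 10, 1), 0)
  expect_error(geometric_boundaries(0, 10, 3), "a > 0")
  expect_error(geometric_boundaries(2, 2, 3), "exceed")
})

test_that("efficiency is a plain ratio with its antisymmetry identity", {
  expect_equal(efficiency(0.1, 0.1), 100)
  expect_equal(efficiency(0.12, 0.10), 120)
  expect_equal(efficiency(0.07, 0.09) * efficiency(0.09, 0.07), 100^2)
  expect_error(efficiency(0, 1), "positive")
})

test_that("DP dominates the data-based baselines under the shared objective", {
  set.seed(61)
  x <- rweibull(3000, 1.6, 1) + 0.2
  xs <- x / max(x)
  fit <- fit_dist_mle(xs, "weibull3p")
  pr <- strat_problem(list(fit$dist), y0 = min(xs), d = max(xs) - min(xs),
                      L = 2, npts = 800)
  cmp <- compare_methods(pr, xs, L_range = 2:4)
  expect_true(all(cmp$dp <= cmp$cum_sqrt_f + 1e-10))
  expect_true(all(cmp$dp <= cmp$geometric + 1e-10))
  expect_true(all(cmp$eff_cum_sqrt_f >= 100 - 1e-8))
})
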