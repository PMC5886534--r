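test_that("densities match their closed forms and vanish off-support", {
  expect_equal(ddist(weib(1), 0), 1)                      # exponential at 0
  expect_equal(ddist(weib(2), -0.5), 0)
  expect_equal(ddist(gam3(2), 1), exp(-1))                # x e^{-x} at x = 1
  expect_equal(ddist(gam3(2, location = 3), 2.9), 0)
  expect_equal(ddist(dist_spec("std_normal_error"), 0), dnorm(0))
  # densities integrate to 1 over the support
  for (d in list(weib(2), gam3(3, 0.5, 1), unif01())) {
    expect_equal(stratum_weight(d, -10, Inf), 1, tolerance = 1e-8)
  }
})

test_that("stratum weights follow the survival-function differences", {
  expect_equal(stratum_weight(weib(1), 0, Inf), 1)
  expect_equal(stratum_weight(weib(2), 0.5, 0), 0)
  expect_equal(stratum_weight(weib(2), 0.5, 0.5), exp(-0.25) - exp(-1))
  expect_equal(stratum_weight(gam3(2), 0, 1), pgamma(1, 2))
  # boundaries below the support are clipped, not an error
  expect_equal(stratum_weight(weib(2, 1, 5), 0, 5.5),
               stratum_weight(weib(2, 1, 5), 5, 0.5))
  expect_error(stratum_weight(weib(1), 0, -1), "nonnegative")
})

test_that("full-support means and variances reduce to textbook moments", {
  expect_equal(stratum_mean(weib(2), 0, Inf), gamma(1.5))        # sqrt(pi)/2
  expect_equal(stratum_mean(weib(1, 1, 5), 5, Inf), 6)           # shift by 5
  expect_equal(stratum_mean(gam3(2), 0, Inf), 2)                 # alpha*theta
  expect_equal(stratum_variance(weib(1, 2), 0, Inf), 4)          # theta^2
  e <- dist_spec("std_normal_error")
  expect_equal(stratum_variance(e, -Inf, Inf), 1)
  expect_equal(stratum_variance(e, -1, 2),
               1 - 2 * dnorm(1) / (2 * pnorm(1) - 1), tolerance = 1e-12)
  expect_equal(truncated_moment(weib(2), 4, 0, Inf), gamma(3))   # = 2
  expect_equal(truncated_moment(weib(2), 0, 0.2, 0.3), 1)
  expect_equal(truncated_moment(weib(2), 1, 0.2, 0.3),
               stratum_mean(weib(2), 0.2, 0.3))
})

test_that("closed forms agree with the quadrature oracle on a parameter sweep", {
  # reduced sweep; the full grid runs in the acceptance suite
  for (r in c(0.8, 2)) for (g in c(0, 5)) {
    d <- weib(r, 1.3, g)
    for (k in 0:4) {
      expect_equal(truncated_moment(d, k, g + 0.2, 0.9),
                   quadrature_moment(d, k, g + 0.2, 0.9),
                   tolerance = 1e-8)
    }
  }
  d <- gam3(2.5, 0.7, 1)
  for (k in 0:4) {
    expect_equal(truncated_moment(d, k, 1.5, 2),
                 quadrature_moment(d, k, 1.5, 2), tolerance = 1e-8)
  }
  e <- dist_spec("std_normal_error")
  for (k in 0:4) {
    expect_equal(truncated_moment(e, k, -0.7, 1.4),
                 quadrature_moment(e, k, -0.7, 1.4), tolerance = 1e-8)
  }
  expect_equal(quadrature_moment(unif01(), 1, 0, 0.5), 0.25)
  expect_equal(quadrature_moment(unif01(), 0, 0, 1), 1)
})

test_that("weights add and the law of total variance holds across partitions", {
  set.seed(42)
  for (dist in list(weib(1.7, 0.9, 0.3), gam3(2.2, 0.5, 0.1))) {
    for (rep in 1:5) {
      lo <- dist$location + runif(1, 0, 0.5)
      wid <- runif(1, 0.5, 2)
      cut <- runif(1, 0.1, 0.9) * wid
      W <- stratum_weight(dist, lo, wid)
      W1 <- stratum_weight(dist, lo, cut)
      W2 <- stratum_weight(dist, lo + cut, wid - cut)
      expect_equal(W1 + W2, W, tolerance = 1e-10)
      m <- stratum_mean(dist, lo, wid)
      m1 <- stratum_mean(dist, lo, cut)
      m2 <- stratum_mean(dist, lo + cut, wid - cut)
      expect_equal((W1 * m1 + W2 * m2) / W, m, tolerance = 1e-8)
      v <- stratum_variance(dist, lo, wid)
      v1 <- stratum_variance(dist, lo, cut)
      v2 <- stratum_variance(dist, lo + cut, wid - cut)
      within <- (W1 * v1 + W2 * v2) / W
      between <- (W1 * (m1 - m)^2 + W2 * (m2 - m)^2) / W
      expect_equal(within + between, v, tolerance = 1e-8)
    }
  }
})

test_that("moments are location- and scale-equivariant", {
  base <- weib(2.3, 1, 0)
  shifted <- weib(2.3, 1, 4)
  expect_equal(stratum_weight(shifted, 4.2, 0.7), stratum_weight(base, 0.2, 0.7))
  expect_equal(stratum_mean(shifted, 4.2, 0.7),
               stratum_mean(base, 0.2, 0.7) + 4, tolerance = 1e-10)
  expect_equal(stratum_variance(shifted, 4.2, 0.7),
               stratum_variance(base, 0.2, 0.7), tolerance = 1e-10)
  scaled <- weib(2.3, 3, 0)
  expect_equal(stratum_mean(scaled, 0.6, 2.1),
               3 * stratum_mean(base, 0.2, 0.7), tolerance = 1e-10)
  expect_equal(stratum_variance(scaled, 0.6, 2.1),
               9 * stratum_variance(base, 0.2, 0.7), tolerance = 1e-10)
})

test_that("narrow strata collapse onto their lower boundary", {
  for (dist in list(weib(2), gam3(2), unif01())) {
    expect_equal(stratum_mean(dist, 0.4, 1e-6), 0.4, tolerance = 1e-5)
    # true value is width^2/12 ~ 1e-13; cancellation noise caps the
    # achievable absolute accuracy near 1e-8 at this width
    expect_lt(stratum_variance(dist, 0.4, 1e-6), 1e-7)
  }
})

test_that("degenerate and invalid inputs are rejected", {
  expect_error(dist_spec("weibull3p", shape = -1, scale = 1), "positive")
  expect_error(dist_spec("weibull3p", shape = 1, scale = 0), "positive")
  expect_error(stratum_mean(weib(2), 50, 1e-12), "degenerate")
  expect_error(stratum_variance(weib(2), 50, 1e-12), "degenerate")
  expect_error(truncated_moment(weib(2), 5, 0, 1), "order <= 4")
  expect_error(truncated_moment(weib(2), 1.5, 0, 1), "integer")
})

test_that("profile MLE recovers Weibull parameters and flags degenerate data", {
  set.seed(123)
  x <- rweibull(3000, 2, 1) + 5
  fit <- fit_dist_mle(x, "weibull3p")
  expect_equal(fit$dist$shape, 2, tolerance = 0.1)
  expect_equal(fit$dist$scale, 1, tolerance = 0.1)
  expect_equal(fit$dist$location, 5, tolerance = 0.1)
  expect_gt(fit$ks_p_value, 0.05)
  expect_error(fit_dist_mle(rep(3, 100), "weibull3p"), "degenerate")
  expect_error(fit_dist_mle(1:5, "weibull3p"), "at least 10")
})

test_that("the KS statistic of a self-fit shrinks as the sample grows", {
  set.seed(99)
  dist <- gam3(2, 1.5, 0)
  d_small <- fit_dist_mle(strataDP:::.r_dist(dist, 150), "gamma3p")$ks_statistic
  d_large <- fit_dist_mle(strataDP:::.r_dist(dist, 4000), "gamma3p")$ks_statistic
  expect_lt(d_large, d_small)
  expect_lt(d_large, 0.02)
})
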