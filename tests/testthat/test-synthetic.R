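test_that("population generation is reproducible and leaves the RNG alone", {
  spec <- population_spec(
    N = 500,
    aux = list(weib(2, 1, 0), gam3(3, 0.5, 1)),
    link = link_model(intercept = 1, terms = c(x1 = 2, x2 = -1)),
    noise_sd = 0.5, seed = 42)
  a <- generate_population(spec)
  b <- generate_population(spec)
  expect_identical(a, b)
  expect_identical(dim(a), c(500L, 3L))
  expect_named(a, c("x1", "x2", "y"))
  set.seed(1); r1 <- runif(1)
  set.seed(1); invisible(generate_population(spec)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("generated moments match the specification closed forms", {
  spec <- population_spec(
    N = 5000,
    aux = list(weib(2, 1, 0), gam3(3, 0.5, 1)),
    link = link_model(terms = c(x1 = 1)), noise_sd = 1, seed = 7)
  pop <- generate_population(spec)
  for (i in 1:2) {
    d <- spec$aux[[i]]
    mu <- stratum_mean(d, -Inf, Inf)
    s2 <- stratum_variance(d, -Inf, Inf)
    x <- pop[[paste0("x", i)]]
    expect_lt(abs(mean(x) - mu), 3 * sqrt(s2 / 5000))
    expect_lt(abs(var(x) - s2), 3 * sd((x - mean(x))^2) / sqrt(5000))
  }
})

test_that("the weak-link population has essentially no predictive power", {
  pop <- generate_population(demo_spec("weak_link"))
  fit <- fit_link(pop, "y", c("x1", "x2"))
  expect_lt(fit$metrics$adj_r_squared, 0.01)
  expect_identical(nrow(pop), 5000L)
})

test_that("bootstrap resampling is row-wise, seeded and multinomial", {
  tab <- data.frame(x1 = 1:10, y = 101:110)
  one <- bootstrap_resample(tab[1, ], seed = 3)
  expect_true(all(one$x1 == 1))
  expect_identical(bootstrap_resample(tab, 9), bootstrap_resample(tab, 9))
  # rows stay intact: the (x1, y) pairing is preserved
  r <- bootstrap_resample(tab, 4)
  expect_true(all(r$y - r$x1 == 100))
  counts <- integer(10)
  for (s in 1:1000) {
    r <- bootstrap_resample(tab, s)
    counts <- counts + tabulate(r$x1, 10)
  }
  expected <- 1000 * 10 / 10
  sd_bin <- sqrt(10000 * 0.1 * 0.9)
  expect_true(all(abs(counts - expected) < 3 * sd_bin))
  expect_error(bootstrap_resample(tab[0, ]), "empty")
})

test_that("a generated population round-trips through the fitting layers", {
  spec <- demo_spec("anaemia_like")
  pop <- generate_population(spec)
  sc <- scale_variables(pop, c("x1", "x2"))
  f1 <- fit_dist_mle(sc$table$x1, "weibull3p")
  # scaled truth: parameters divide by the max-scaling factor
  expect_equal(f1$dist$shape, spec$aux[[1]]$shape, tolerance = 0.25)
  expect_gt(f1$ks_p_value, 0.05)
  fit <- fit_link(pop, "y", c("x1", "x2"))
  lmfit <- attr(fit, "lm")
  se <- summary(lmfit)$coefficients[, "Std. Error"]
  truth <- c(11, 0.02, 0.05)
  est <- c(fit$intercept, fit$terms$coefficient)
  expect_true(all(abs(est - truth) < 3 * se))
})
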