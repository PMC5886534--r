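test_that("a noiseless linear signal is recovered exactly", {
  df <- data.frame(x1 = seq(0, 1, length.out = 50))
  df$y <- 2 + 3 * df$x1
  fit <- suppressWarnings(fit_link(df, "y", "x1")) # lm warns on a perfect fit
  expect_equal(fit$intercept, 2, tolerance = 1e-8)
  expect_equal(fit$terms$coefficient, 3, tolerance = 1e-8)
  expect_equal(fit$metrics$rse, 0, tolerance = 1e-6)
  expect_equal(fit$metrics$adj_r_squared, 1, tolerance = 1e-8)
})

test_that("coefficients of a noisy two-variable model land within 3 SEs", {
  set.seed(11)
  N <- 5000
  df <- data.frame(x1 = runif(N, 0, 2), x2 = rweibull(N, 2, 1))
  df$y <- 1 + 0.8 * df$x1 - 0.5 * df$x2 + rnorm(N, 0, 1.5)
  fit <- fit_link(df, "y", c("x1", "x2"))
  lmfit <- attr(fit, "lm")
  se <- summary(lmfit)$coefficients[, "Std. Error"]
  expect_lt(abs(fit$intercept - 1), 3 * se[1])
  expect_lt(abs(fit$terms$coefficient[1] - 0.8), 3 * se[2])
  expect_lt(abs(fit$terms$coefficient[2] + 0.5), 3 * se[3])
  # metric conventions: multiple correlation and stats::AIC
  expect_equal(fit$metrics$correlation, sqrt(summary(lmfit)$r.squared))
  expect_equal(fit$metrics$aic, AIC(lmfit))
  expect_equal(fit$metrics$rse, summary(lmfit)$sigma)
})

test_that("rank-deficient designs and tiny samples are rejected with names", {
  df <- data.frame(x1 = 1:10, x2 = 2 * (1:10))
  df$y <- rnorm(10)
  expect_error(fit_link(df, "y", c("x1", "x2")), "collinear")
  expect_error(fit_link(df[1, ], "y", "x1"), "observations")
  expect_error(link_model(terms = c(x1 = 1, x1 = 2)), "once")
  expect_error(link_model(terms = c(`x1^3` = 1)), "parse")
})

test_that("link stratum variance follows the coefficient-weighted sum", {
  m <- link_model(terms = c(x1 = 2, x2 = 3))
  # unit means, conditional variances 0.04 and 0.01
  mom <- list(x1 = c(1, 1.04), x2 = c(1, 1.01))
  expect_equal(lambda_stratum_variance(m, mom), 4 * 0.04 + 9 * 0.01)
  m1 <- link_model(terms = c(x1 = 1))
  expect_equal(lambda_stratum_variance(m1, list(x1 = c(0.3, 0.3^2 + 0.05))), 0.05)
  # a zero quadratic coefficient degenerates to the linear answer
  mq0 <- link_model(terms = c(x1 = 1, `x1^2` = 0))
  mom4 <- list(x1 = c(0.5, 0.3, 0.2, 0.15))
  expect_equal(lambda_stratum_variance(mq0, mom4),
               lambda_stratum_variance(m1, mom4))
  expect_error(lambda_stratum_variance(m, list(x1 = c(1, 1.04))), "x2")
  expect_error(lambda_stratum_variance(link_model(terms = c(x1 = 1, `x1^2` = 2)),
                                       list(x1 = c(1, 2))), "order 4")
})

test_that("link variance ignores the intercept and is degree-2 homogeneous", {
  mom <- list(x1 = c(0.5, 0.35, 0.28, 0.25), x2 = c(1, 1.2))
  m <- link_model(intercept = 0, terms = c(x1 = 1.5, `x1^2` = -0.4, x2 = 0.7))
  m_shift <- link_model(intercept = 99, terms = c(x1 = 1.5, `x1^2` = -0.4, x2 = 0.7))
  expect_equal(lambda_stratum_variance(m, mom),
               lambda_stratum_variance(m_shift, mom))
  m_scaled <- link_model(terms = c(x1 = 3, `x1^2` = -0.8, x2 = 1.4))
  expect_equal(lambda_stratum_variance(m_scaled, mom),
               4 * lambda_stratum_variance(m, mom), tolerance = 1e-12)
})

test_that("quadratic link variance matches Monte Carlo on truncated draws", {
  set.seed(202)
  dist <- weib(2, 1, 0)
  lo <- 0.4; wid <- 0.8
  x <- strataDP:::.r_dist(dist, 4e5)
  x <- x[x >= lo & x <= lo + wid]
  b1 <- 1.3; b2 <- -0.6
  lam <- b1 * x + b2 * x^2
  mc_var <- var(lam)
  mc_se <- sd((lam - mean(lam))^2) / sqrt(length(x))
  m <- link_model(terms = c(x1 = b1, `x1^2` = b2))
  mom <- list(x1 = sapply(1:4, function(k) truncated_moment(dist, k, lo, wid)))
  expect_lt(abs(lambda_stratum_variance(m, mom) - mc_var), 3 * mc_se)
})
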