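#' Parametric distribution specification
#'
#' Constructs the specification of a parametric distribution used to model an
#' auxiliary variable (or the regression error) in an optimum-stratification
#' problem. Four families are supported: the three-parameter Weibull and Gamma
#' families used for right-skewed health-survey variables, a uniform reference
#' distribution, and the standard-normal regression error term.
#'
#' For `"weibull3p"` and `"gamma3p"` the support is `[location, Inf)`;
#' `shape` and `scale` must be positive. For `"uniform"` the `scale` and
#' `location` arguments hold the upper and lower endpoints `b` and `a`.
#' `"std_normal_error"` takes no parameters; its scale is applied externally
#' through the error-variance multiplier of the stratification objective.
#'
#' @param family one of `"weibull3p"`, `"gamma3p"`, `"uniform"`,
#'   `"std_normal_error"`.
#' @param shape positive shape parameter (Weibull `r`, Gamma `alpha`).
#' @param scale positive scale parameter `theta`; upper bound `b` for uniform.
#' @param location location parameter `gamma`; lower bound `a` for uniform.
#' @return an object of class `"dist_spec"`.
#' @examples
#' dist_spec("weibull3p", shape = 2, scale = 1, location = 0)
#' dist_spec("uniform", scale = 1, location = 0)
#' @export
dist_spec <- function(family = c("weibull3p", "gamma3p", "uniform", "std_normal_error"),
                      shape = NULL, scale = NULL, location = NULL) {
  family <- match.arg(family)
  if (family %in% c("weibull3p", "gamma3p")) {
    if (is.null(shape) || is.null(scale)) {
      stop("'shape' and 'scale' are required for family '", family, "'")
    }
    if (is.null(location)) location <- 0
    if (!is.finite(shape) || shape <= 0) stop("'shape' must be a positive real")
    if (!is.finite(scale) || scale <= 0) stop("'scale' must be a positive real")
  } else if (family == "uniform") {
    if (is.null(location)) location <- 0
    if (is.null(scale)) scale <- 1
    if (!is.finite(location) || !is.finite(scale) || scale <= location) {
      stop("uniform requires finite bounds with location (a) < scale (b)")
    }
    shape <- NULL
  } else { # std_normal_error
    shape <- NULL; scale <- NULL; location <- NULL
  }
  structure(list(family = family, shape = shape, scale = scale,
                 location = location),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  pars <- switch(x$family,
    weibull3p = sprintf("shape = %g, scale = %g, location = %g",
                        x$shape, x$scale, x$location),
    gamma3p   = sprintf("shape = %g, scale = %g, location = %g",
                        x$shape, x$scale, x$location),
    uniform   = sprintf("a = %g, b = %g", x$location, x$scale),
    std_normal_error = "(standard normal)")
  cat("<dist_spec> ", x$family, ": ", pars, "\n", sep = "")
  invisible(x)
}

.support_lower <- function(dist) {
  switch(dist$family,
         weibull3p = dist$location,
         gamma3p = dist$location,
         uniform = dist$location,
         std_normal_error = -Inf)
}

.support_upper <- function(dist) {
  switch(dist$family, uniform = dist$scale, Inf)
}

#' Probability density function
#'
#' Evaluates the density of a [dist_spec] at `x` (vectorized); 0 outside the
#' support.
#'
#' @param dist a [dist_spec].
#' @param x numeric vector of evaluation points.
#' @return nonnegative numeric vector of densities.
#' @examples
#' ddist(dist_spec("weibull3p", shape = 1, scale = 1), 0) # exponential at 0
#' @export
ddist <- function(dist, x) {
  stopifnot(inherits(dist, "dist_spec"))
  switch(dist$family,
    weibull3p = ifelse(x < dist$location, 0,
                       stats::dweibull(x - dist$location, dist$shape, dist$scale)),
    gamma3p   = ifelse(x < dist$location, 0,
                       stats::dgamma(x - dist$location, shape = dist$shape,
                                     scale = dist$scale)),
    uniform   = stats::dunif(x, dist$location, dist$scale),
    std_normal_error = stats::dnorm(x))
}

#' Cumulative distribution function
#'
#' @param dist a [dist_spec].
#' @param q numeric vector of quantile points.
#' @return numeric vector of cumulative probabilities.
#' @export
pdist <- function(dist, q) {
  stopifnot(inherits(dist, "dist_spec"))
  switch(dist$family,
    weibull3p = stats::pweibull(pmax(q - dist$location, 0), dist$shape, dist$scale),
    gamma3p   = stats::pgamma(pmax(q - dist$location, 0), shape = dist$shape,
                              scale = dist$scale),
    uniform   = stats::punif(q, dist$location, dist$scale),
    std_normal_error = stats::pnorm(q))
}

# Regularized upper incomplete gamma function Q(a, x) = Gamma(a, x) / Gamma(a).
.Q <- function(a, x) stats::pgamma(x, shape = a, lower.tail = FALSE)

# Cumulative unnormalized truncated moment: C_k(u) = int_{-Inf}^{u} x^k f(x) dx,
# moments taken about 0 (binomial expansion over the location shift where
# needed). Vectorized over u. These are the building blocks of every stratum
# quantity: over [l, u] the unnormalized k-th moment is C_k(u) - C_k(l), the
# stratum weight is the k = 0 case, and W^2 sigma^2 = U0*U2 - U1^2 needs no
# division by a possibly tiny weight.
.cum_utm <- function(dist, k, u) {
  stopifnot(k >= 0, k == round(k))
  switch(dist$family,
    weibull3p = .cum_utm_shifted(dist, k, u, .cum_utm_weibull0),
    gamma3p   = .cum_utm_shifted(dist, k, u, .cum_utm_gamma0),
    uniform   = {
      a <- dist$location; b <- dist$scale
      uu <- pmin(pmax(u, a), b)
      (uu^(k + 1) - a^(k + 1)) / ((k + 1) * (b - a))
    },
    std_normal_error = .cum_utm_normal(k, u))
}

# location-shifted families: E[X^k 1{X<=u}] with X = location + Z via binomial
# expansion; fk(dist, j, z) gives the cumulative j-th moment of the unshifted Z
# in terms of z = (u - location) / scale clipped to the support.
.cum_utm_shifted <- function(dist, k, u, fk) {
  z <- pmax((u - dist$location) / dist$scale, 0)
  out <- 0
  for (j in 0:k) {
    out <- out + choose(k, j) * dist$location^(k - j) * fk(dist, j, z)
  }
  out
}

# Weibull(r, theta) about its origin: int_0^{theta z} x^j f = theta^j *
# Gamma(1 + j/r) * [1 - Q(1 + j/r, z^r)].
.cum_utm_weibull0 <- function(dist, j, z) {
  a <- 1 + j / dist$shape
  dist$scale^j * gamma(a) * (1 - .Q(a, z^dist$shape))
}

# Gamma(alpha, theta) about its origin: int_0^{theta z} x^j f = theta^j *
# (Gamma(alpha + j) / Gamma(alpha)) * [1 - Q(alpha + j, z)].
.cum_utm_gamma0 <- function(dist, j, z) {
  a <- dist$shape + j
  dist$scale^j * exp(lgamma(a) - lgamma(dist$shape)) * (1 - .Q(a, z))
}

# Standard normal: I_k(u) = int_{-Inf}^u x^k phi(x) dx by the recursion
# I_k = -u^{k-1} phi(u) + (k-1) I_{k-2}, I_0 = Phi(u), I_1 = -phi(u).
.cum_utm_normal <- function(k, u) {
  Ikm2 <- stats::pnorm(u)              # I_0
  if (k == 0) return(Ikm2)
  phi_u <- stats::dnorm(u)
  # u^j * phi(u) -> 0 as |u| -> Inf; guard the 0 * Inf case explicitly
  upow <- function(j) ifelse(is.finite(u), u^j * phi_u, 0)
  Ikm1 <- -phi_u                       # I_1
  Ikm1[!is.finite(u)] <- 0
  if (k == 1) return(Ikm1)
  for (j in 2:k) {
    Ik <- -upow(j - 1) + (j - 1) * Ikm2
    Ikm2 <- Ikm1
    Ikm1 <- Ik
  }
  Ikm1
}

# Unnormalized truncated moment U_k over [lower, lower + width].
.utm <- function(dist, k, lower, width) {
  upper <- ifelse(is.infinite(width) & width > 0, Inf, lower + width)
  .cum_utm(dist, k, upper) - .cum_utm(dist, k, lower)
}

.check_width <- function(width) {
  if (any(!is.na(width) & width < 0)) stop("'width' must be nonnegative")
}

#' Stratum weight
#'
#' Probability mass of a stratum `[lower, lower + width]` under a
#' distribution, computed in closed form: the difference of Weibull survival
#' functions, of regularized incomplete gamma functions (Gamma family), of
#' normal CDFs (error term), or of linear CDFs (uniform). Boundaries below the
#' support are clipped to the support, where the density vanishes, so the
#' result is exact.
#'
#' @param dist a [dist_spec].
#' @param lower lower stratum boundary.
#' @param width nonnegative stratum width (may be `Inf`).
#' @return probability in `[0, 1]`.
#' @examples
#' stratum_weight(dist_spec("weibull3p", 2, 1), 0.5, 0.5) # exp(-.25) - exp(-1)
#' @export
stratum_weight <- function(dist, lower, width) {
  stopifnot(inherits(dist, "dist_spec"))
  .check_width(width)
  w <- .utm(dist, 0, lower, width)
  pmin(pmax(w, 0), 1)
}

#' Conditional stratum mean
#'
#' Mean of the variable conditional on falling inside the stratum
#' `[lower, lower + width]`, from the closed-form truncated first moment. For
#' the shifted (three-parameter) families the location is added back so the
#' result is the conditional mean of the original variable.
#'
#' @inheritParams stratum_weight
#' @return the conditional mean.
#' @export
stratum_mean <- function(dist, lower, width) {
  m <- truncated_moment(dist, 1, lower, width)
  m
}

#' Conditional stratum variance
#'
#' Variance of the variable conditional on the stratum, computed through the
#' numerically stable product form `W^2 sigma^2 = U0*U2 - U1^2` in terms of
#' unnormalized truncated moments `U_k`, avoiding division by a tiny stratum
#' weight until the final step. Tiny negative values (roundoff) are clipped
#' to 0.
#'
#' @inheritParams stratum_weight
#' @return nonnegative conditional variance.
#' @export
stratum_variance <- function(dist, lower, width) {
  stopifnot(inherits(dist, "dist_spec"))
  .check_width(width)
  u0 <- .utm(dist, 0, lower, width)
  if (any(u0 <= 0)) stop("degenerate stratum: zero probability mass")
  u1 <- .utm(dist, 1, lower, width)
  u2 <- .utm(dist, 2, lower, width)
  w2v <- u0 * u2 - u1^2
  # Each U_k is a difference of cumulative moments C_k of order up to ~1, so
  # its absolute roundoff is on the scale of the C_k values, not of U_k; the
  # negativity tolerance must reflect that cancellation scale.
  upper <- ifelse(is.infinite(width) & width > 0, Inf, lower + width)
  Cmag <- function(k) abs(.cum_utm(dist, k, upper)) + abs(.cum_utm(dist, k, lower))
  tol <- 1e-12 * (Cmag(0) * Cmag(2) + Cmag(1)^2 + .Machine$double.xmin)
  if (any(w2v < -tol)) {
    stop("numerical inconsistency: negative stratum variance")
  }
  pmax(w2v, 0) / u0^2
}

#' Conditional truncated moment
#'
#' Raw conditional moment `E[X^k | X in stratum]` in closed form, for orders
#' `k <= 4` (the quadratic regression link needs conditional moments up to
#' order 4). Location-shifted families are handled by binomial expansion of
#' `((X - location) + location)^k`.
#'
#' @inheritParams stratum_weight
#' @param order nonnegative integer moment order, at most 4.
#' @return the conditional raw moment.
#' @seealso [quadrature_moment()] for the numeric-integration oracle.
#' @export
truncated_moment <- function(dist, order, lower, width) {
  stopifnot(inherits(dist, "dist_spec"))
  .check_width(width)
  if (order != round(order) || order < 0) stop("'order' must be a nonnegative integer")
  if (order > 4) {
    stop("closed-form moments implemented for order <= 4; use quadrature_moment()")
  }
  u0 <- .utm(dist, 0, lower, width)
  if (order == 0) return(rep(1, length(u0)))
  if (any(u0 <= 0)) stop("degenerate stratum: zero probability mass")
  .utm(dist, order, lower, width) / u0
}

#' Conditional moment by adaptive quadrature
#'
#' The same quantity as [truncated_moment()], computed by adaptive numeric
#' integration of `x^k f(x)` over the stratum. Serves as the independent
#' oracle for every closed form; any moment order is supported.
#'
#' @inheritParams truncated_moment
#' @param rel.tol relative accuracy requested from [stats::integrate()].
#' @return the conditional raw moment.
#' @export
quadrature_moment <- function(dist, order, lower, width, rel.tol = 1e-10) {
  stopifnot(inherits(dist, "dist_spec"), length(lower) == 1, length(width) == 1)
  .check_width(width)
  lo <- max(lower, .support_lower(dist))
  hi <- min(lower + width, .support_upper(dist))
  if (hi <= lo) stop("degenerate stratum: zero probability mass")
  quad <- function(f) {
    # back off the tolerance if the integrator hits its roundoff limit
    for (tol in c(rel.tol, 1e2 * rel.tol, 1e4 * rel.tol)) {
      r <- tryCatch(stats::integrate(f, lo, hi, rel.tol = tol, abs.tol = tol),
                    error = function(e) e)
      if (!inherits(r, "error")) return(r$value)
    }
    stop("quadrature failed on [", lo, ", ", hi, "]: ", conditionMessage(r))
  }
  f0 <- quad(function(x) ddist(dist, x))
  if (f0 <= 0) stop("degenerate stratum: zero probability mass")
  if (order == 0) return(1)
  quad(function(x) x^order * ddist(dist, x)) / f0
}

#' Maximum-likelihood fit of a skewed three-parameter family
#'
#' Fits a three-parameter Weibull or Gamma distribution to a sample by
#' profile maximum likelihood: the location parameter is profiled on
#' `(-Inf, min(sample) - eps]` (keeping the likelihood finite) with the
#' shape/scale MLE computed by an inner quasi-Newton step at each candidate
#' location. A Kolmogorov-Smirnov statistic against the fitted CDF is
#' reported; because the parameters are estimated from the same sample the
#' KS p-value is approximate and anti-conservative.
#'
#' @param sample numeric vector, at least 10 values with positive spread.
#' @param family `"weibull3p"` or `"gamma3p"`.
#' @return a list of class `"dist_fit"` with elements `dist` (the fitted
#'   [dist_spec]), `logLik`, `ks_statistic`, `ks_p_value` and `n`.
#' @examples
#' x <- rweibull(200, 2, 1) + 5
#' fit_dist_mle(x, "weibull3p")
#' @export
fit_dist_mle <- function(sample, family = c("weibull3p", "gamma3p")) {
  family <- match.arg(family)
  sample <- as.numeric(sample)
  if (length(sample) < 10) stop("need at least 10 observations")
  rng <- diff(range(sample))
  if (rng <= 0) stop("degenerate data: sample has no spread")
  eps <- 1e-6 * rng
  xmin <- min(sample)

  nll2p <- function(par, shifted) { # par = (log shape, log scale)
    sh <- exp(par[1]); sc <- exp(par[2])
    d <- suppressWarnings(if (family == "weibull3p") {
      stats::dweibull(shifted, sh, sc, log = TRUE)
    } else {
      stats::dgamma(shifted, shape = sh, scale = sc, log = TRUE)
    })
    if (any(!is.finite(d))) return(1e10)
    -sum(d)
  }
  fit2p <- function(gam) {
    shifted <- sample - gam
    m <- mean(shifted); v <- stats::var(shifted)
    start <- if (family == "weibull3p") {
      # method-of-moments-flavoured start via the CV -> shape relation
      cv <- sqrt(v) / m
      r0 <- max(0.5, min(10, cv^-1.086))
      c(log(r0), log(m / gamma(1 + 1 / r0)))
    } else {
      c(log(max(m^2 / v, 1e-3)), log(max(v / m, 1e-12)))
    }
    o <- stats::optim(start, nll2p, shifted = shifted, method = "BFGS",
                      control = list(maxit = 500))
    o
  }
  prof <- function(gam) fit2p(gam)$value
  lo <- xmin - 2 * rng
  hi <- xmin - eps
  og <- stats::optimize(prof, c(lo, hi), tol = eps)
  gam <- og$minimum
  inner <- fit2p(gam)
  if (inner$convergence != 0) {
    stop("MLE did not converge (optim code ", inner$convergence, ")")
  }
  dist <- dist_spec(family, shape = exp(inner$par[1]),
                    scale = exp(inner$par[2]), location = gam)
  ks <- suppressWarnings(stats::ks.test(sample, function(q) pdist(dist, q)))
  structure(list(dist = dist, logLik = -inner$value,
                 ks_statistic = unname(ks$statistic),
                 ks_p_value = ks$p.value, n = length(sample)),
            class = "dist_fit")
}

#' @export
print.dist_fit <- function(x, ...) {
  cat("Maximum-likelihood fit (n = ", x$n, ")\n", sep = "")
  print(x$dist)
  cat(sprintf("  logLik = %.3f, KS D = %.4f, approx. p = %.4f\n",
              x$logLik, x$ks_statistic, x$ks_p_value))
  cat("  (KS p-value is anti-conservative: parameters were estimated",
      "from the sample)\n")
  invisible(x)
}
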