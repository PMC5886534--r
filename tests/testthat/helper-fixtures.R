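# Shared fixtures: small parametric problems built in code.

weib <- function(shape, scale = 1, location = 0) {
  dist_spec("weibull3p", shape = shape, scale = scale, location = location)
}

gam3 <- function(shape, scale = 1, location = 0) {
  dist_spec("gamma3p", shape = shape, scale = scale, location = location)
}

unif01 <- function() dist_spec("uniform", scale = 1, location = 0)

unif_problem <- function(L, npts = 500, ...) {
  strat_problem(list(unif01()), y0 = 0, d = 1, L = L, npts = npts, ...)
}

# a two-auxiliary problem with an error term, exercising every component type
mixed_problem <- function(L, npts = 400) {
  strat_problem(
    list(list(dist = weib(2, 0.5), beta = 1.5),
         list(dist = gam3(3, 0.2), beta = -0.8)),
    y0 = 0, d = 1.5, L = L, error_scale = 0.6, npts = npts)
}

# random single-auxiliary problems for oracle sweeps
random_problem <- function(L, npts = 300) {
  if (runif(1) < 0.5) {
    dist <- weib(runif(1, 0.8, 3.5), runif(1, 0.5, 2), runif(1, 0, 0.5))
  } else {
    dist <- gam3(runif(1, 0.8, 4), runif(1, 0.2, 1), runif(1, 0, 0.5))
  }
  y0 <- dist$location
  d <- dist$scale * runif(1, 2, 4)
  strat_problem(list(list(dist = dist, beta = runif(1, 0.5, 2))),
                y0 = y0, d = d, L = L, npts = npts)
}
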