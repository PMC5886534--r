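#' Parametric stratification problem
#'
#' Bundles everything the boundary optimizer needs: the common (scaled)
#' boundary domain `[y0, y0 + d]`, one component per auxiliary variable
#' (its fitted distribution and its link coefficients), an optional
#' standard-normal error component with a variance multiplier, the number of
#' strata `L`, and the grid resolution of the width search.
#'
#' All components are evaluated at the same cut points of the common domain;
#' in the intended workflow every variable has been scaled by its maximum
#' first so that the domains are commensurate.
#'
#' @param components a list; each element is `list(dist = <dist_spec>,
#'   beta = <numeric>)` where `beta[k]` is the coefficient of `x^k`
#'   (length 1 for a linear term, length 2 when a quadratic term is present).
#'   A bare `dist_spec` is promoted to a unit linear coefficient.
#' @param y0 lower end of the boundary domain.
#' @param d positive total range to be divided into strata.
#' @param L number of strata (positive integer).
#' @param error_scale optional positive multiplier of the truncated
#'   standard-normal error variance (`NULL` for no error component). Use 1
#'   for the unit-variance construction, or the regression RSE to propagate
#'   the fitted residual scale.
#' @param npts number of grid divisions of `[y0, y0 + d]`; the grid step is
#'   `d / npts`. Capped at 20000.
#' @param min_width smallest admissible stratum width; defaults to one grid
#'   step, which rules out empty strata (set 0 for the fully literal
#'   `l_h >= 0` constraint).
#' @return an object of class `"strat_problem"`.
#' @examples
#' p <- strat_problem(list(dist_spec("uniform", scale = 1)), y0 = 0, d = 1, L = 2)
#' @export
strat_problem <- function(components, y0, d, L, error_scale = NULL,
                          npts = 1000, min_width = NULL) {
  if (inherits(components, "dist_spec")) components <- list(components)
  stopifnot(is.list(components), length(components) >= 1)
  components <- lapply(components, function(cm) {
    if (inherits(cm, "dist_spec")) cm <- list(dist = cm, beta = 1)
    stopifnot(inherits(cm$dist, "dist_spec"), is.numeric(cm$beta),
              length(cm$beta) %in% 1:2)
    cm
  })
  if (!is.finite(d) || d <= 0) stop("'d' must be a positive real")
  if (L < 1 || L != round(L)) stop("'L' must be a positive integer")
  if (!is.null(error_scale) && (!is.finite(error_scale) || error_scale <= 0)) {
    stop("'error_scale' must be positive or NULL")
  }
  npts <- as.integer(npts)
  if (npts < L) stop("'npts' must be at least L")
  if (npts > 20000) stop("'npts' is capped at 20000; coarsen the grid and refine")
  delta <- d / npts
  if (is.null(min_width)) min_width <- delta
  if (min_width < 0) stop("'min_width' must be nonnegative")
  if (L * min_width > d + 1e-9 * d) {
    stop("infeasible: L * min_width exceeds the total range d")
  }
  structure(list(components = components, y0 = y0, d = d, L = as.integer(L),
                 error_scale = error_scale, npts = npts, delta = delta,
                 min_width = min_width),
            class = "strat_problem")
}

#' @export
print.strat_problem <- function(x, ...) {
  cat("<strat_problem> domain [", format(x$y0, digits = 6), ", ",
      format(x$y0 + x$d, digits = 6), "], L = ", x$L,
      ", grid step = ", format(x$delta, digits = 4), "\n", sep = "")
  for (i in seq_along(x$components)) {
    cm <- x$components[[i]]
    cat(sprintf("  component %d: beta = (%s), ", i,
                paste(format(cm$beta, digits = 4), collapse = ", ")))
    print(cm$dist)
  }
  if (!is.null(x$error_scale)) {
    cat("  error component: std normal x", format(x$error_scale, digits = 4), "\n")
  }
  invisible(x)
}

# W^2 * Var(sum_k beta_k X^k | stratum) for one component, from unnormalized
# truncated moments: U0 * sum_{i,j} b_i b_j U_{i+j} - (sum_k b_k U_k)^2.
# Vectorized over (lower, width).
.component_w2v <- function(cm, lower, width) {
  deg <- length(cm$beta)
  U <- lapply(0:(2 * deg), function(k) .utm(cm$dist, k, lower, width))
  A <- 0
  for (k in seq_len(deg)) A <- A + cm$beta[k] * U[[k + 1]]
  B <- 0
  for (i in seq_len(deg)) for (j in seq_len(deg)) {
    B <- B + cm$beta[i] * cm$beta[j] * U[[i + j + 1]]
  }
  U[[1]] * B - A^2
}

# Sum of all components' W^2 sigma^2 contributions (error included).
.w2v_total <- function(problem, lower, width) {
  tot <- 0
  for (cm in problem$components) tot <- tot + .component_w2v(cm, lower, width)
  if (!is.null(problem$error_scale)) {
    err <- list(dist = dist_spec("std_normal_error"), beta = 1)
    tot <- tot + problem$error_scale^2 * .component_w2v(err, lower, width)
  }
  tot
}

#' Per-stratum objective
#'
#' The contribution `phi_h` of one stratum to the stratification objective
#' `sum_h W_h sigma_h`: the square root of the summed `W^2 sigma^2` terms of
#' every auxiliary component (weighted by squared link coefficients) plus the
#' truncated-normal error term. Each `W^2 sigma^2` is evaluated at the same
#' cut points through the stable product form `U0*U2 - U1^2`, so no division
#' by a vanishing stratum weight occurs; an (essentially) empty stratum
#' contributes 0.
#'
#' @param problem a [strat_problem].
#' @param lower lower boundary of the stratum (vectorized).
#' @param width nonnegative stratum width (vectorized).
#' @return nonnegative value(s) of `phi_h`.
#' @examples
#' p <- strat_problem(list(dist_spec("uniform", scale = 1)), 0, 1, L = 2)
#' stratum_objective(p, 0, 0.5) # 0.5 * (0.5 / sqrt(12))
#' @export
stratum_objective <- function(problem, lower, width) {
  stopifnot(inherits(problem, "strat_problem"))
  .check_width(width)
  tol <- 1e-9 * problem$d
  if (any(lower < problem$y0 - tol | lower + width > problem$y0 + problem$d + tol)) {
    stop("stratum outside the boundary domain [y0, y0 + d]")
  }
  sqrt(pmax(.w2v_total(problem, lower, width), 0))
}

#' Total objective for a full boundary set
#'
#' Evaluates `sum_h phi_h` over the `L` strata induced by a set of interior
#' boundaries of the domain, together with the per-stratum breakdown.
#'
#' @param problem a [strat_problem].
#' @param boundaries numeric vector of interior boundaries (possibly empty
#'   for `L = 1`), nondecreasing, inside `[y0, y0 + d]`.
#' @return a list with `total` (the summed objective) and `phi`
#'   (per-stratum contributions).
#' @export
total_objective <- function(problem, boundaries) {
  stopifnot(inherits(problem, "strat_problem"))
  boundaries <- as.numeric(boundaries)
  if (is.unsorted(boundaries)) stop("boundaries must be nondecreasing")
  tol <- 1e-9 * problem$d
  if (length(boundaries) &&
      (min(boundaries) < problem$y0 - tol ||
       max(boundaries) > problem$y0 + problem$d + tol)) {
    stop("boundaries outside the domain [y0, y0 + d]")
  }
  cuts <- c(problem$y0, boundaries, problem$y0 + problem$d)
  phi <- stratum_objective(problem, cuts[-length(cuts)], diff(cuts))
  list(total = sum(phi), phi = phi)
}

# Cumulative unnormalized moments of every component at all grid points
# g_j = y0 + j * delta, j = 0..npts. Returned as a list of matrices
# (rows = moment order 0..2*deg, cols = grid points); the error component is
# appended last when present. Each entry is computed by the closed form at
# the grid point directly, so differences are exact (no error accumulation).
.grid_cums <- function(problem) {
  g <- problem$y0 + problem$delta * (0:problem$npts)
  g[length(g)] <- problem$y0 + problem$d  # guard against fp drift at the top
  comps <- problem$components
  if (!is.null(problem$error_scale)) {
    comps <- c(comps, list(list(dist = dist_spec("std_normal_error"),
                                beta = 1, is_error = TRUE)))
  }
  cums <- lapply(comps, function(cm) {
    deg <- length(cm$beta)
    t(vapply(0:(2 * deg), function(k) .cum_utm(cm$dist, k, g),
             numeric(length(g))))
  })
  list(grid = g, comps = comps, cums = cums)
}

# phi over grid intervals: starts, ends are 0-based grid indices (vectors of
# equal length). Uses the precomputed cumulative table gc.
.phi_idx <- function(problem, gc, starts, ends) {
  tot <- 0
  for (ci in seq_along(gc$comps)) {
    cm <- gc$comps[[ci]]
    C <- gc$cums[[ci]]
    deg <- length(cm$beta)
    U <- lapply(0:(2 * deg), function(k) C[k + 1, ends + 1] - C[k + 1, starts + 1])
    A <- 0
    for (k in seq_len(deg)) A <- A + cm$beta[k] * U[[k + 1]]
    B <- 0
    for (i in seq_len(deg)) for (j in seq_len(deg)) {
      B <- B + cm$beta[i] * cm$beta[j] * U[[i + j + 1]]
    }
    w2v <- U[[1]] * B - A^2
    if (!is.null(cm$is_error)) w2v <- problem$error_scale^2 * w2v
    tot <- tot + w2v
  }
  sqrt(pmax(tot, 0))
}
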