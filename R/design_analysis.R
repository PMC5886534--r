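#' Profile the objective over the number of strata
#'
#' Solves the boundary problem for every strata count `L = 1..L_max`
#' (one forward DP pass serves all of them) and tabulates the objective
#' `sum(W_h sigma_h)` together with the variance of the stratified mean,
#' `V = objective^2 / n`. The profile is the basis of the elbow analysis
#' for choosing the number of strata.
#'
#' @param problem a [strat_problem]; its `L` is ignored in favour of the
#'   range.
#' @param L_max largest strata count to profile (>= 2).
#' @param n total sample size used for the variance column.
#' @return a data frame of class `"strata_profile"` with columns `L`,
#'   `objective`, `variance`, plus attribute `"designs"` (the traced designs).
#' @export
strata_profile <- function(problem, L_max, n) {
  stopifnot(inherits(problem, "strat_problem"))
  if (L_max < 2) stop("'L_max' must be at least 2")
  if (n <= 0) stop("'n' must be positive")
  pr <- problem
  pr$L <- as.integer(L_max)
  if (pr$L * pr$min_width > pr$d) stop("infeasible: L_max * min_width > d")
  tables <- .dp_tables(pr, L_max = pr$L)
  designs <- vector("list", L_max)
  obj <- numeric(L_max)
  for (L in seq_len(L_max)) {
    widths <- .dp_trace(tables, L)
    cuts <- pr$y0 + pr$delta * cumsum(widths)
    dsn <- .make_design(pr, utils::head(cuts, -1))
    designs[[L]] <- dsn
    obj[L] <- dsn$total
  }
  out <- data.frame(L = seq_len(L_max), objective = obj,
                    variance = obj^2 / n)
  attr(out, "designs") <- designs
  attr(out, "n") <- n
  class(out) <- c("strata_profile", "data.frame")
  out
}

#' Suggest a strata count from a profile (advisory)
#'
#' Two documented heuristics for reading the elbow off a strata-count
#' profile. `"threshold"` returns the first `L` whose relative variance
#' improvement when moving to `L + 1` falls below `threshold` (default 10%);
#' if the improvement never falls below the threshold, the largest profiled
#' `L` is returned with a warning. `"curvature"` returns the `L` maximizing
#' the discrete second difference of the log-variance. Both are advisory:
#' the choice of `L` ultimately trades precision against survey cost, which
#' is outside this model.
#'
#' @param profile a `"strata_profile"` (or any data frame with `L` and
#'   `variance` columns), at least 3 rows.
#' @param method `"threshold"` or `"curvature"`.
#' @param threshold relative-improvement cutoff for the threshold rule.
#' @return a single suggested strata count.
#' @export
suggest_elbow <- function(profile, method = c("threshold", "curvature"),
                          threshold = 0.10) {
  method <- match.arg(method)
  stopifnot(is.data.frame(profile), nrow(profile) >= 3)
  V <- profile$variance
  L <- profile$L
  if (method == "threshold") {
    imp <- 1 - V[-1] / V[-length(V)]   # improvement when moving from L to L+1
    hit <- which(imp < threshold)
    if (!length(hit)) {
      warning("improvement never falls below the threshold; returning L_max")
      return(L[length(L)])
    }
    return(L[hit[1]])
  }
  lv <- log(V)
  d2 <- diff(lv, differences = 2)     # indexed at L[2..(K-1)]
  L[which.max(d2) + 1]
}

#' @export
plot.strata_profile <- function(x, ...) {
  graphics::plot(x$L, x$variance, type = "b", pch = 19,
                 xlab = "number of strata L",
                 ylab = "V(stratified mean)", ...)
  invisible(x)
}

#' Cumulative square-root-frequency boundaries
#'
#' The classical Dalenius-Hodges rule: an equal-width histogram of the
#' sample is formed, the square roots of the bin frequencies are accumulated,
#' and boundaries are placed at the bin edges nearest to equal increments of
#' the cumulative square-root total. A widely used approximate stratifier;
#' here it serves as a comparison baseline.
#'
#' @param sample numeric sample of the stratification variable.
#' @param L number of strata.
#' @param n_bins number of histogram bins (>= L).
#' @return numeric vector of `L - 1` interior boundaries.
#' @export
cum_sqrt_f_boundaries <- function(sample, L, n_bins = 30) {
  sample <- as.numeric(sample)
  if (diff(range(sample)) <= 0) stop("degenerate sample: no spread")
  if (n_bins < L) stop("'n_bins' must be at least L")
  if (L < 2) return(numeric(0))
  edges <- seq(min(sample), max(sample), length.out = n_bins + 1)
  counts <- graphics::hist(sample, breaks = edges, plot = FALSE)$counts
  csf <- cumsum(sqrt(counts))
  total <- csf[n_bins]
  bounds <- numeric(L - 1)
  prev <- 0L
  for (h in seq_len(L - 1)) {
    target <- total * h / L
    cand <- seq.int(prev + 1L, n_bins - (L - 1L - h) - 1L)
    i <- cand[which.min(abs(csf[cand] - target))]
    bounds[h] <- edges[i + 1L]
    prev <- i
  }
  bounds
}

#' Geometric-progression boundaries
#'
#' The Gunning-Horgan rule for positively skewed populations: boundaries in
#' geometric progression between the range endpoints, `k_h = a * r^h` with
#' `r = (b/a)^(1/L)`.
#'
#' @param a positive lower endpoint of the range.
#' @param b upper endpoint, greater than `a`.
#' @param L number of strata.
#' @return numeric vector of `L - 1` interior boundaries.
#' @examples
#' geometric_boundaries(1, 16, 4) # 2, 4, 8
#' @export
geometric_boundaries <- function(a, b, L) {
  if (!is.finite(a) || a <= 0) stop("the geometric rule requires a > 0")
  if (!is.finite(b) || b <= a) stop("'b' must exceed 'a'")
  if (L < 2) return(numeric(0))
  r <- (b / a)^(1 / L)
  a * r^seq_len(L - 1)
}

#' Relative efficiency of the DP boundaries
#'
#' Percent efficiency of the dynamic-programming solution over a competing
#' stratification, `100 * objective_other / objective_dp`; values above 100
#' favour the DP boundaries.
#'
#' @param objective_other positive objective achieved by the other method.
#' @param objective_dp positive objective achieved by the DP method.
#' @return efficiency in percent.
#' @export
efficiency <- function(objective_other, objective_dp) {
  if (any(objective_other <= 0) || any(objective_dp <= 0)) {
    stop("objectives must be positive")
  }
  100 * objective_other / objective_dp
}

#' Compare DP boundaries with the classical baselines
#'
#' Evaluates the cum-sqrt(f) and geometric boundaries under the same
#' parametric objective as the DP solution, for a range of strata counts,
#' and tabulates objectives and efficiencies. Boundaries falling outside the
#' problem domain are clipped to it. An externally computed objective (for
#' example from a Lavallee-Hidiroglou/Kozak implementation) can be supplied
#' per `L` through `external`.
#'
#' @param problem a [strat_problem] (its `L` is ignored).
#' @param sample the observed stratification variable on the problem's
#'   (scaled) domain, used by the data-based baselines.
#' @param L_range strata counts to compare.
#' @param n_bins histogram bins for the cum-sqrt(f) rule.
#' @param refine refinement factor applied to the DP solution.
#' @param external optional named numeric vector of externally computed
#'   objectives, names = strata counts.
#' @return a data frame with one row per `L`: the DP, cum-sqrt(f) and
#'   geometric objectives and the DP efficiencies (percent).
#' @export
compare_methods <- function(problem, sample, L_range = 2:6, n_bins = 30,
                            refine = 10, external = NULL) {
  stopifnot(inherits(problem, "strat_problem"))
  lo <- problem$y0; hi <- problem$y0 + problem$d
  clip <- function(b) pmin(pmax(b, lo + problem$min_width),
                           hi - problem$min_width)
  rows <- lapply(L_range, function(L) {
    pr <- problem; pr$L <- as.integer(L)
    dp <- refine_design(pr, dp_solve(pr), factor = refine)
    bc <- sort(clip(cum_sqrt_f_boundaries(sample, L, n_bins)))
    bg <- if (min(sample) > 0) sort(clip(geometric_boundaries(min(sample),
                                                              max(sample), L)))
          else NULL
    obj_c <- total_objective(pr, bc)$total
    obj_g <- if (is.null(bg)) NA_real_ else total_objective(pr, bg)$total
    data.frame(L = L, dp = dp$total, cum_sqrt_f = obj_c, geometric = obj_g,
               eff_cum_sqrt_f = efficiency(obj_c, dp$total),
               eff_geometric = if (is.na(obj_g)) NA_real_
                               else efficiency(obj_g, dp$total))
  })
  out <- do.call(rbind, rows)
  if (!is.null(external)) {
    out$external <- external[as.character(out$L)]
    out$eff_external <- ifelse(is.na(out$external), NA_real_,
                               efficiency(out$external, out$dp))
  }
  out
}
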