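#' Neyman allocation (real-valued)
#'
#' Distributes a total sample of size `n` across strata proportionally to
#' the Neyman terms `W_h * sigma_h` (any nonnegative weights may be passed;
#' in the parametric workflow the per-stratum objective `phi_h` plays this
#' role).
#'
#' @param terms nonnegative per-stratum weights, at least one positive.
#' @param n positive total sample size.
#' @return real-valued allocations summing to `n`.
#' @examples
#' neyman_allocate(c(0.2, 0.1), 300) # 200, 100
#' @export
neyman_allocate <- function(terms, n) {
  terms <- as.numeric(terms)
  if (any(!is.finite(terms)) || any(terms < 0)) {
    stop("allocation terms must be finite and nonnegative")
  }
  if (sum(terms) <= 0) stop("degenerate allocation: all terms are zero")
  if (n <= 0) stop("'n' must be positive")
  n * terms / sum(terms)
}

# Largest-remainder (Hamilton) rounding of nonnegative reals to integers
# summing to n, restricted to the index set `active`. Deterministic: ties on
# the fractional part go to the lower index.
.largest_remainder <- function(reals, n) {
  fl <- floor(reals)
  rem <- n - sum(fl)
  if (rem > 0) {
    ord <- order(-(reals - fl), seq_along(reals))
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  as.integer(fl)
}

#' Integerize and bound an allocation
#'
#' Rounds real-valued Neyman allocations to integers summing exactly to `n`
#' (largest-remainder rule), then enforces the per-stratum bounds
#' `1 <= n_h <= N_h`: any stratum exceeding its population size is clamped
#' at `N_h` with the excess re-allocated proportionally among the unclamped
#' strata, and any stratum below 1 is raised to 1 with the deficit taken
#' from the largest allocations. Both passes terminate in at most `L`
#' iterations.
#'
#' @param reals real allocations (e.g. from [neyman_allocate()]) summing
#'   to `n`.
#' @param n total integer sample size.
#' @param N_h integer stratum population sizes, each at least 1.
#' @return a list of class `"allocation"` with integer `n_h`, `N_h`, and
#'   logical `clamped` flags.
#' @examples
#' integerize_and_bound(c(200, 100), 300, N_h = c(150, 1000)) # 150, 150
#' @export
integerize_and_bound <- function(reals, n, N_h) {
  reals <- as.numeric(reals)
  L <- length(reals)
  N_h <- as.integer(round(N_h))
  stopifnot(length(N_h) == L)
  if (any(N_h < 1)) stop("every stratum must contain at least one unit")
  if (abs(sum(reals) - n) > 1e-6 * max(n, 1)) {
    stop("real allocations must sum to n")
  }
  if (n > sum(N_h)) stop("infeasible: n exceeds the population size")
  if (n < L) stop("infeasible: n < L cannot give every stratum one unit")

  n_h <- .largest_remainder(reals, n)
  clamped <- rep(FALSE, L)
  # upper bounds: clamp and redistribute among unclamped strata
  for (it in seq_len(L)) {
    over <- n_h > N_h
    if (!any(over)) break
    clamped <- clamped | over
    fixed <- sum(N_h[clamped])
    n_h[clamped] <- N_h[clamped]
    free <- !clamped
    if (!any(free)) break
    w <- reals[free]
    if (sum(w) <= 0) w <- rep(1, sum(free))
    n_h[free] <- .largest_remainder((n - fixed) * w / sum(w), n - fixed)
  }
  # lower bounds: raise to 1, take the deficit from the largest allocations
  while (any(n_h < 1)) {
    i <- which(n_h < 1)[1]
    n_h[i] <- n_h[i] + 1L
    donors <- which(n_h > 1 & n_h - 1L >= 1L & seq_len(L) != i)
    j <- donors[which.max(n_h[donors])]
    n_h[j] <- n_h[j] - 1L
  }
  if (sum(n_h) != n) stop("internal error: allocation does not sum to n")
  structure(list(n_h = n_h, N_h = N_h, clamped = clamped), class = "allocation")
}

#' @export
print.allocation <- function(x, ...) {
  df <- data.frame(stratum = seq_along(x$n_h), N_h = x$N_h, n_h = x$n_h,
                   clamped = x$clamped)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Attach Neyman sample sizes to a stratification design
#'
#' Computes integer stratum sample sizes for a solved design: allocations
#' proportional to the per-stratum objective `phi_h` (the parametric
#' `W_h * sigma_h` term), rounded and bounded by `1 <= n_h <= N_h` with
#' `N_h = round(N * W_h)`. When several auxiliary distributions give
#' different stratum weights for the same boundaries, the component named by
#' `weight_component` defines `N_h` (default: the first).
#'
#' @param design a `"strat_design"`.
#' @param n total sample size.
#' @param N population size.
#' @param weight_component index of the component whose stratum weights
#'   define `N_h`.
#' @return the design with an `allocation` element filled in.
#' @export
allocate <- function(design, n, N, weight_component = 1) {
  stopifnot(inherits(design, "strat_design"))
  W <- design$component_stats[[weight_component]]$weight
  N_h <- pmax(1L, as.integer(round(N * W / sum(W))))
  reals <- neyman_allocate(design$phi, n)
  design$allocation <- integerize_and_bound(reals, n, N_h)
  design
}
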