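# Forward dynamic program over discretized stratum widths.
#
# Stage k = stratum index, state d_k = grid width already allotted to the
# first k strata. Phi_k(d_k) = min over the k-th width l_k of
# phi_k(y0 + d_k - l_k, l_k) + Phi_{k-1}(d_k - l_k); Phi_1(d_1) = phi_1(d_1).
# The per-interval objectives phi(start, end) are shared across stages and
# strata counts, so they are precomputed once from closed-form cumulative
# truncated moments at the grid points.

.dp_tables <- function(problem, L_max = problem$L) {
  m <- problem$npts
  if (m > 5000) {
    stop("grid too fine for the exact DP (npts > 5000); solve coarse and refine")
  }
  wsteps <- max(0L, as.integer(ceiling(problem$min_width / problem$delta - 1e-9)))
  if (L_max * wsteps > m) stop("infeasible: L * min_width exceeds the range")
  gc <- .grid_cums(problem)
  # phi_end[[j]]: phi over [g_s, g_j] for s = 0..j (last entry is width 0)
  phi_end <- vector("list", m)
  for (j in seq_len(m)) {
    phi_end[[j]] <- .phi_idx(problem, gc, 0:j, rep.int(j, j + 1L))
  }
  Phi <- matrix(Inf, nrow = L_max, ncol = m + 1)
  Larg <- matrix(NA_integer_, nrow = L_max, ncol = m + 1)
  # stage 1: the whole state is one stratum
  Phi[1, 1] <- if (wsteps == 0L) 0 else Inf
  Larg[1, 1] <- 0L
  for (j in seq_len(m)) {
    if (j >= wsteps) {
      Phi[1, j + 1] <- phi_end[[j]][1]
      Larg[1, j + 1] <- j
    }
  }
  if (L_max >= 2) {
    for (k in 2:L_max) {
      smin <- (k - 1L) * wsteps
      jmin <- k * wsteps
      if (jmin == 0L) {  # all-zero-width prefix admissible
        Phi[k, 1] <- 0; Larg[k, 1] <- 0L
      }
      for (j in seq_len(m)) {
        if (j < jmin) next
        s <- smin:(j - wsteps)
        cand <- phi_end[[j]][s + 1L] + Phi[k - 1, s + 1L]
        mn <- min(cand)
        if (!is.finite(mn)) next
        pick <- max(which(cand == mn))  # largest s <=> smallest width l_k
        Phi[k, j + 1] <- mn
        Larg[k, j + 1] <- j - s[pick]
      }
    }
  }
  list(Phi = Phi, Larg = Larg, wsteps = wsteps, m = m, gc = gc)
}

.dp_trace <- function(tables, L, j = tables$m) {
  widths <- integer(L)
  for (k in L:1) {
    l <- tables$Larg[k, j + 1]
    if (is.na(l)) stop("infeasible state encountered during backward trace")
    widths[k] <- l
    j <- j - l
  }
  widths
}

# Assemble a strat_design from interior boundaries (original, continuous).
.make_design <- function(problem, boundaries, method = "dp") {
  res <- total_objective(problem, boundaries)
  cuts <- c(problem$y0, boundaries, problem$y0 + problem$d)
  L <- length(cuts) - 1
  lowers <- cuts[-length(cuts)]
  widths <- diff(cuts)
  comp_stats <- lapply(problem$components, function(cm) {
    W <- stratum_weight(cm$dist, lowers, widths)
    mu <- rep(NA_real_, L); v <- rep(NA_real_, L)
    ok <- W > 1e-12
    if (any(ok)) {
      mu[ok] <- truncated_moment(cm$dist, 1, lowers[ok], widths[ok])
      u0 <- .utm(cm$dist, 0, lowers[ok], widths[ok])
      u1 <- .utm(cm$dist, 1, lowers[ok], widths[ok])
      u2 <- .utm(cm$dist, 2, lowers[ok], widths[ok])
      v[ok] <- pmax((u0 * u2 - u1^2) / u0^2, 0)
    }
    list(weight = W, mean = mu, variance = v)
  })
  structure(list(problem = problem, L = L, boundaries = boundaries,
                 widths = widths, phi = res$phi, total = res$total,
                 component_stats = comp_stats, method = method,
                 allocation = NULL),
            class = "strat_design")
}

#' Solve the stratification problem by dynamic programming
#'
#' Runs the forward width-recursion on the problem's grid and traces the
#' optimum backwards to recover the optimum stratum boundaries (OSB). The
#' returned objective is the exact global optimum over boundary placements on
#' the grid; [refine_design()] sharpens it on a finer local grid.
#'
#' @param problem a [strat_problem].
#' @return an object of class `"strat_design"`: interior `boundaries`,
#'   stratum `widths`, per-stratum objective `phi`, their sum `total`, and
#'   per-component stratum weights/means/variances.
#' @examples
#' p <- strat_problem(list(dist_spec("uniform", scale = 1)), 0, 1, L = 2)
#' dp_solve(p) # boundary 0.5, objective 1 / (2 * sqrt(12))
#' @export
dp_solve <- function(problem) {
  stopifnot(inherits(problem, "strat_problem"))
  tables <- .dp_tables(problem)
  widths <- .dp_trace(tables, problem$L)
  cuts <- problem$y0 + problem$delta * cumsum(widths)
  boundaries <- utils::head(cuts, -1)
  design <- .make_design(problem, boundaries)
  if (abs(design$total - tables$Phi[problem$L, tables$m + 1]) >
      1e-9 * max(design$total, 1e-12)) {
    warning("traced objective differs from DP table value beyond tolerance")
  }
  design
}

#' Exhaustive grid search (test oracle)
#'
#' Enumerates every admissible placement of the interior boundaries on the
#' problem's grid and returns the global grid optimum. Exponential in `L`,
#' hence restricted to `L <= 3`; it exists to validate [dp_solve()].
#'
#' @param problem a [strat_problem] with `L <= 3`.
#' @return a `"strat_design"`.
#' @export
brute_force <- function(problem) {
  stopifnot(inherits(problem, "strat_problem"))
  L <- problem$L
  if (L > 3) stop("brute_force is limited to L <= 3")
  m <- problem$npts
  if (m > 2000) stop("brute_force is limited to npts <= 2000")
  ws <- max(0L, as.integer(ceiling(problem$min_width / problem$delta - 1e-9)))
  gc <- .grid_cums(problem)
  if (L == 1) return(.make_design(problem, numeric(0), method = "brute_force"))
  best <- Inf; best_idx <- NULL
  if (L == 2) {
    j <- ws:(m - ws)
    tot <- .phi_idx(problem, gc, rep.int(0L, length(j)), j) +
           .phi_idx(problem, gc, j, rep.int(m, length(j)))
    i <- which.min(tot)
    best_idx <- j[i]
  } else {
    for (j1 in ws:(m - 2L * ws)) {
      j2 <- (j1 + ws):(m - ws)
      tot <- .phi_idx(problem, gc, rep.int(0L, length(j2)), rep.int(j1, length(j2))) +
             .phi_idx(problem, gc, rep.int(j1, length(j2)), j2) +
             .phi_idx(problem, gc, j2, rep.int(m, length(j2)))
      i <- which.min(tot)
      if (tot[i] < best) {
        best <- tot[i]
        best_idx <- c(j1, j2[i])
      }
    }
  }
  boundaries <- problem$y0 + problem$delta * best_idx
  .make_design(problem, boundaries, method = "brute_force")
}

#' Locally refine a coarse solution on a finer grid
#'
#' Sharpens a grid solution by cyclic coordinate descent: each interior
#' boundary in turn is re-optimized over a window of +/- 2 coarse grid steps
#' around its current position, discretized at `delta / factor`, holding the
#' other boundaries fixed. Every accepted move strictly decreases the total
#' objective, so the refined objective is never worse than the coarse one;
#' with `factor = 1` a DP solution (already the grid optimum) is returned
#' unchanged.
#'
#' @param problem the [strat_problem] the design was solved on.
#' @param design a `"strat_design"` from [dp_solve()] or [brute_force()].
#' @param factor integer subdivision factor of the coarse grid step.
#' @param max_sweeps safety cap on full coordinate sweeps.
#' @return a refined `"strat_design"`.
#' @export
refine_design <- function(problem, design, factor = 10, max_sweeps = 25) {
  stopifnot(inherits(problem, "strat_problem"), inherits(design, "strat_design"))
  factor <- max(1L, as.integer(factor))
  L <- design$L
  if (L == 1) return(design)
  cuts <- c(problem$y0, design$boundaries, problem$y0 + problem$d)
  fine <- problem$delta / factor
  for (sweep in seq_len(max_sweeps)) {
    moved <- FALSE
    for (i in 2:L) {  # interior cut indices within `cuts`
      lo <- cuts[i - 1] + problem$min_width
      hi <- cuts[i + 1] - problem$min_width
      cand <- cuts[i] + seq(-2 * problem$delta, 2 * problem$delta, by = fine)
      cand <- unique(c(cuts[i], cand[cand >= lo - 1e-12 & cand <= hi + 1e-12]))
      if (length(cand) <= 1) next
      val <- stratum_objective(problem, cuts[i - 1], cand - cuts[i - 1]) +
             stratum_objective(problem, cand, cuts[i + 1] - cand)
      cur <- val[1]
      k <- which.min(val)
      if (val[k] < cur - 1e-15 * max(cur, 1)) {
        cuts[i] <- cand[k]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  out <- .make_design(problem, cuts[2:L], method = paste0(design$method, "+refine"))
  if (out$total > design$total + 1e-12 * max(design$total, 1)) {
    # cannot happen: the current cut is always among the candidates
    return(design)
  }
  out
}

#' @export
print.strat_design <- function(x, digits = 4, ...) {
  cat("Optimum stratification (", x$method, "), L = ", x$L, "\n", sep = "")
  cat("  domain: [", format(x$problem$y0, digits = digits), ", ",
      format(x$problem$y0 + x$problem$d, digits = digits), "]\n", sep = "")
  if (length(x$boundaries)) {
    cat("  boundaries:", paste(format(x$boundaries, digits = digits),
                               collapse = ", "), "\n")
  }
  cat("  objective sum(W_h sigma_h) =", format(x$total, digits = 6), "\n")
  if (!is.null(x$allocation)) {
    cat("  sample sizes n_h:", paste(x$allocation$n_h, collapse = ", "),
        " (n =", sum(x$allocation$n_h), ")\n")
  }
  invisible(x)
}

#' @export
summary.strat_design <- function(object, ...) {
  cuts <- c(object$problem$y0, object$boundaries,
            object$problem$y0 + object$problem$d)
  df <- data.frame(stratum = seq_len(object$L),
                   lower = utils::head(cuts, -1), upper = cuts[-1],
                   width = object$widths, phi = object$phi)
  for (i in seq_along(object$component_stats)) {
    cs <- object$component_stats[[i]]
    df[[paste0("W", i)]] <- cs$weight
    df[[paste0("mean", i)]] <- cs$mean
    df[[paste0("var", i)]] <- cs$variance
  }
  if (!is.null(object$allocation)) {
    df$N_h <- object$allocation$N_h
    df$n_h <- object$allocation$n_h
  }
  structure(list(table = df, total = object$total, L = object$L),
            class = "summary.strat_design")
}

#' @export
print.summary.strat_design <- function(x, ...) {
  cat("Stratification design, L =", x$L, "\n")
  print(x$table, row.names = FALSE, digits = 5)
  cat("Total objective:", format(x$total, digits = 6), "\n")
  invisible(x)
}
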