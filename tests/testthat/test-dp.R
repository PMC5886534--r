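test_that("the uniform problem has its known analytic optimum", {
  p2 <- unif_problem(L = 2, npts = 1000)
  d2 <- dp_solve(p2)
  expect_equal(d2$boundaries, 0.5, tolerance = p2$delta)
  expect_equal(d2$total, 1 / (2 * sqrt(12)), tolerance = 1e-3)
  p1 <- unif_problem(L = 1)
  d1 <- dp_solve(p1)
  expect_length(d1$boundaries, 0)
  expect_equal(d1$total, 1 / sqrt(12), tolerance = 1e-6)
})

test_that("the DP solution equals the exhaustive grid optimum", {
  set.seed(17)
  for (rep in 1:6) {
    L <- sample(2:3, 1)
    p <- random_problem(L, npts = 250)
    dsol <- dp_solve(p)
    bsol <- brute_force(p)
    expect_equal(dsol$total, bsol$total, tolerance = 1e-10)
    expect_equal(dsol$boundaries, bsol$boundaries, tolerance = p$delta + 1e-12)
  }
})

test_that("the traced solution is Bellman-consistent", {
  p <- mixed_problem(L = 4)
  tables <- strataDP:::.dp_tables(p)
  widths <- strataDP:::.dp_trace(tables, p$L)
  # dropping the last stratum must reproduce the stage-(L-1) table value
  state <- p$npts - widths[p$L]
  sub_widths <- strataDP:::.dp_trace(tables, p$L - 1, j = state)
  expect_equal(sum(sub_widths), state)
  cuts <- c(p$y0, p$y0 + p$delta * cumsum(sub_widths))
  sub_total <- sum(stratum_objective(p, head(cuts, -1), diff(cuts)))
  expect_equal(sub_total, tables$Phi[p$L - 1, state + 1], tolerance = 1e-12)
  # and the full total decomposes as Phi_{L-1}(state) + phi_L(last stratum)
  expect_equal(tables$Phi[p$L - 1, state + 1] +
                 stratum_objective(p, p$y0 + p$delta * state,
                                   p$d - p$delta * state),
               tables$Phi[p$L, p$npts + 1], tolerance = 1e-12)
})

test_that("the optimal objective is nonincreasing in the strata count", {
  for (p in list(unif_problem(8, npts = 400), mixed_problem(8))) {
    prof <- strata_profile(p, L_max = 8, n = 100)
    expect_true(all(diff(prof$objective) <= 1e-12))
  }
})

test_that("degenerate grids and strata counts still solve", {
  # d = 2 * delta, L = 2: the unique feasible point has both widths = delta
  p <- strat_problem(list(unif01()), 0, 1, L = 2, npts = 2)
  d <- dp_solve(p)
  expect_equal(d$widths, c(0.5, 0.5))
  expect_error(strat_problem(list(unif01()), 0, 1, L = 5, npts = 3), "at least L")
})

test_that("solutions are deterministic across repeated solves", {
  p <- mixed_problem(L = 3)
  d1 <- dp_solve(p)
  d2 <- dp_solve(p)
  expect_identical(d1$boundaries, d2$boundaries)
  expect_identical(d1$total, d2$total)
})

test_that("halving the grid step changes the objective only at O(delta)", {
  p_coarse <- strat_problem(list(weib(2)), 0, 3, L = 3, npts = 100)
  p_fine <- strat_problem(list(weib(2)), 0, 3, L = 3, npts = 200)
  p_finest <- strat_problem(list(weib(2)), 0, 3, L = 3, npts = 800)
  o1 <- dp_solve(p_coarse)$total
  o2 <- dp_solve(p_fine)$total
  o3 <- dp_solve(p_finest)$total
  expect_lte(o3, o2 + 1e-12)
  expect_lte(o2, o1 + 1e-12)
  expect_lt(abs(o2 - o3), max(abs(o1 - o3), 1e-9))
})

test_that("local refinement sharpens but never worsens a solution", {
  p <- strat_problem(list(unif01()), 0, 1, L = 2, npts = 20) # delta = 0.05
  coarse <- dp_solve(p)
  fine <- refine_design(p, coarse, factor = 50)
  expect_lte(fine$total, coarse$total + 1e-12)
  expect_equal(fine$boundaries, 0.5, tolerance = 0.001)
  same <- refine_design(p, coarse, factor = 1)
  expect_equal(same$boundaries, coarse$boundaries)
  expect_equal(same$total, coarse$total)
  pw <- random_problem(3, npts = 200)
  cw <- dp_solve(pw)
  rw <- refine_design(pw, cw, factor = 10)
  expect_lte(rw$total, cw$total + 1e-12)
})
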