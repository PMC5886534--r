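---
title: "Parametric optimum stratification: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric optimum stratification: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strataDP)
```

## The estimation problem

A population of N units is to be stratified into L groups so that the mean
of a study variable $y$ can be estimated precisely from a stratified random
sample of total size $n$. Ignoring the finite-population correction, the
variance of the stratified mean under Neyman allocation is

$$V(\bar y_{st}) = \frac{\big(\sum_{h=1}^{L} W_h \sigma_{hy}\big)^2}{n},$$

with $W_h$ the stratum weight and $\sigma_{hy}$ the within-stratum standard
deviation of $y$. Minimizing $\sum_h W_h\sigma_{hy}$ over the boundary
positions is therefore the whole design problem.

Because $y$ is unobserved at the design stage, we assume the regression
model $y = \lambda(x_1,\dots,x_p) + \varepsilon$ with $\lambda$ a polynomial
of degree at most two in auxiliary variables whose marginal distributions
can be estimated, and $\varepsilon$ a homoscedastic normal error
uncorrelated with $\lambda$. Then
$\sigma^2_{hy} = \sigma^2_{h\lambda} + \sigma^2_{h\varepsilon}$, and with
mutually independent auxiliaries the per-stratum objective becomes

$$\phi_h = \sqrt{\textstyle\sum_i \beta_i^2 W_{hx_i}^2\sigma^2_{hx_i}
  + W_{h\varepsilon}^2 \sigma^2_{h\varepsilon}},$$

every factor a truncated moment of a parametric distribution between the
common cut points $(y_{h-1}, y_h)$.

Two modelling assumptions deserve emphasis. First, summing
$\beta_i^2\sigma^2_{hx_i}$ treats the auxiliaries as uncorrelated within
strata; real covariates (iron and folate, say) are usually correlated, and
the objective then misstates $\sigma^2_{h\lambda}$ by the omitted
covariance terms. We follow the standard construction and flag rather than
fix this. Second, all variables are max-scaled onto a common axis before
any boundary search, so a single set of cut points can be applied to every
component; boundaries are rescaled for reporting only.

## Closed-form truncated moments

For a three-parameter Weibull (shape $r$, scale $\theta$, location
$\gamma$), substituting $z = ((x-\gamma)/\theta)^r$ turns every truncated
raw moment about the location into a difference of regularized upper
incomplete gamma functions $Q(a, x)$:

$$\int_{l}^{u} (x-\gamma)^k f(x)\,dx
  = \theta^k\,\Gamma(1 + k/r)\,\big[Q(1+k/r, z_l) - Q(1+k/r, z_u)\big],$$

and analogously with $Q(\alpha + k, \cdot)$ and
$\Gamma(\alpha+k)/\Gamma(\alpha)$ for the Gamma family (whose truncated
moment identities we derived and verified against quadrature, as they are
rarely printed). The location is added back by binomial expansion, so
`stratum_mean()` is the conditional mean of the original variable — this
restores exact location equivariance, which the common form of the
truncated-mean formula (stated about the shifted origin) silently drops.
The standard-normal error term uses the $\Phi$/$\varphi$ recursion
$I_k = -u^{k-1}\varphi(u) + (k-1) I_{k-2}$, equivalent to the erf-difference
expressions for its stratum weight and truncated variance. Moments up to
order four are provided in closed form because a quadratic link needs
conditional moments of $x$ up to $x^4$.

Numerical choices:

* All stratum quantities are assembled from *unnormalized* truncated
  moments $U_k = \int_l^u x^k f\,dx$, and the objective uses the product
  form $W^2\sigma^2 = U_0 U_2 - U_1^2$ (for a quadratic link,
  $U_0\sum b_ib_jU_{i+j} - (\sum b_kU_k)^2$). No division by a vanishing
  stratum weight ever occurs; an empty stratum contributes exactly 0.
* $U_k$ is computed as a difference of cumulative closed forms evaluated at
  the two endpoints. The cancellation this implies is tolerated explicitly:
  negative $W^2\sigma^2$ values within a tolerance proportional to the
  cancelling magnitudes are clipped to zero, anything beyond raises an
  error. In practice the absolute noise floor is ~1e-9 for strata narrower
  than ~1e-6 of the scale; everywhere else the closed forms agree with
  adaptive quadrature to better than 1e-8 relative (this is asserted over a
  shape/scale/location sweep in the test suite).
* Boundaries below a distribution's support are clipped to the support,
  where the density vanishes, so the clip is exact rather than an error —
  the width search routinely visits such boundaries.

`quadrature_moment()` implements the same quantities by adaptive
integration and serves as the independent oracle in every test of the
closed forms; it is never used by the solver itself.

## The width dynamic program

With widths $l_h = y_h - y_{h-1}$ and $\sum_h l_h = d$, the objective is
separable and the grid optimum is found by the forward recursion
$\Phi_k(d_k) = \min_{l_k} [\phi_k(l_k) + \Phi_{k-1}(d_k - l_k)]$ with
$\Phi_1(d_1) = \phi_1(d_1)$, followed by a backward trace. Design
parameters, all exposed on `strat_problem()`:

* **Grid.** Default 1000 divisions of $[y_0, y_0+d]$ ($\delta = d/1000$),
  hard-capped at 20000; the exact DP refuses grids beyond 5000 points
  (its cost is $O(L\,(d/\delta)^2)$ evaluations). Per-interval objectives
  are shared across stages and across strata counts, so one forward pass
  prices all $L \le L_{max}$ — `strata_profile()` exploits this.
* **Minimum width.** Defaults to one grid step, which keeps every stratum
  non-empty so the allocation bound $n_h \ge 1$ is attainable; set 0 for
  the fully literal $l_h \ge 0$ constraint.
* **Tie-breaking.** Among equal-value widths the smallest $l_k$ is taken,
  making the output deterministic.
* **Refinement.** `refine_design()` re-optimizes each boundary by cyclic
  coordinate descent over a window of ±2 coarse steps at $\delta/f$
  (default $f = 10$), accepting only strict improvements — the refined
  objective can never be worse, and with $f = 1$ a DP solution is returned
  unchanged.

`brute_force()` (exhaustive enumeration, $L \le 3$) exists purely as the
oracle for the DP; on every tested problem the two agree to 1e-10 in
objective on a shared grid.

## Allocation

Neyman sample sizes are proportional to $\phi_h$, which equals
$W_h\sigma_{hy}$ under the model. The real allocation is rounded by the
largest-remainder rule (deterministic; ties on the fractional part go to
the lower stratum index), then the bounds $1 \le n_h \le N_h$ are enforced:
over-capacity strata are clamped with the excess redistributed
proportionally among the rest, deficits are raised to one unit at the
expense of the largest allocation. On exhaustive small instances the result
is within one unit swap of the variance-proxy minimizer; we assert the
one-swap property, not exact optimality, since largest-remainder rounding
does not in general minimize $\sum (W_h\sigma_h)^2/n_h$.

$N_h$ is not observable from a purely parametric problem; it is taken as
$N W_h$ using the stratum weights of the *first* listed component by
default (`weight_component` selects another). When auxiliaries have
different fitted distributions this choice matters and is reported with the
design.

## The error term's scale

The parametric construction uses a *standard* normal error component, even
though a fitted link typically has residual standard error well above 1.
Both conventions are available through `error_mode`: `"unit"` (default)
reproduces the standard construction exactly, `"rse"` multiplies the
truncated-normal variance by the fitted RSE². The default favours
comparability of the objective across models over literal variance
bookkeeping; the mode is recorded in the fit. Model-comparison metrics
follow the common R conventions: multiple correlation $\sqrt{R^2}$,
$RSE = \sqrt{SSE/(n-p-1)}$, and AIC as `stats::AIC()` computes it for a
Gaussian likelihood (the constant includes the $2\pi$ term; only AIC
differences are ever meaningful).

## Choosing the number of strata

For an (approximately) uniform variable, $V(\bar y_{st})$ falls as $1/L^2$;
the profile produced by `strata_profile()` makes the empirical decay
visible and `suggest_elbow()` offers two advisory read-outs: the first $L$
whose relative variance improvement drops below a threshold (default 10%;
a 25% threshold reproduces the conventional "around 7 strata" reading on
$1/L^2$-like decays), and the maximizer of the discrete second difference
of the log-variance. Neither accounts for survey cost, which is the real
arbiter and outside this model.

## Baselines and fairness of comparison

`cum_sqrt_f_boundaries()` implements the cumulative-√f rule (default 30
equal-width bins — the binning is a genuine free parameter) and
`geometric_boundaries()` the geometric-progression rule, which requires a
strictly positive range start. `compare_methods()` evaluates *all* methods
under the same parametric objective at their respective boundaries, so the
comparison is apples-to-apples; efficiencies are always computed from
full-precision objectives, not from rounded table entries. A
Lavallée–Hidiroglou/Kozak baseline is not reimplemented — established
implementations exist elsewhere — but externally computed objectives can be
fed into the same table.

## Synthetic populations

`generate_population()` draws independent parametric auxiliaries and
$y = \lambda(x) + \varepsilon$; `bootstrap_resample()` resamples rows with
replacement at the original size. This emulates exactly the structure the
method assumes — independent skewed auxiliaries, polynomial link,
homoscedastic normal noise — and deliberately nothing more: no
auxiliary-auxiliary correlation, no heteroscedasticity, no measurement
error, no outlier contamination. Passing tests on these populations
therefore validate the machinery under the model's own assumptions; they
do not certify behaviour when those assumptions fail. The packaged
`demo_spec()` fixtures are labelled emulations: `"anaemia_like"`
(N = 724, two skewed auxiliaries, adjusted R² around 10%) mimics the
moderately-correlated micronutrient-survey regime, `"weak_link"`
(N = 5000, adjusted R² of order 1e-4) the near-uncorrelated simulated
regime.

## Maximum-likelihood fitting

Three-parameter families are fitted by profiling the location on
$(-\infty, \min(x) - \varepsilon]$ with $\varepsilon = 10^{-6}\times$range
(keeping the log-likelihood finite), a golden-section search outside and a
BFGS shape/scale fit inside. The KS statistic is computed against the
fitted CDF; because the parameters come from the same sample the p-value
is anti-conservative and is reported as approximate. Family `"auto"` picks
Weibull or Gamma by log-likelihood and retains the loser for inspection.

## Problem sizes used in validation

The shipped tests solve grids of 250-1000 points with $L \le 8$,
populations of 724-5000 units, quadrature sweeps of ~240 parameter
combinations, and exhaustive allocation instances with $n \le 30$ — sizes
at which every oracle (quadrature, enumeration, Monte Carlo) is itself
fast and trustworthy. The solver comfortably handles finer grids; the
two-stage solve-then-refine path is the intended way to get
sub-grid-precision boundaries at survey scale.

## Known limitations

* Correlated auxiliaries bias $\sigma^2_{h\lambda}$ (see above).
* Heteroscedastic errors $V(\varepsilon\mid x)$ varying with $x$ are out
  of scope; only the homoscedastic construction is implemented.
* The link is polynomial of degree ≤ 2; higher degrees would need
  truncated moments beyond order 4 (the quadrature oracle already supports
  them).
* The geometric baseline is undefined for ranges starting at or below 0.
* KS p-values after estimation are anti-conservative; treat them as
  goodness-of-fit descriptions, not tests.
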