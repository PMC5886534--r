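# strataDP

Optimum stratum boundaries and sample sizes for stratified surveys, by
dynamic programming over stratum widths.

## The problem

Stratified random sampling gains precision when strata are internally
homogeneous in the study variable *y* (haemoglobin level, disease burden,
expenditure, ...). At the design stage *y* is unobserved, so the strata must
be built from auxiliary variables *x*₁, ..., *x*ₚ (iron, folate, prior-survey
measurements) that are linked to *y* through a regression

  y = λ(x₁, ..., xₚ) + ε,  ε ~ N(0, σ²), homoscedastic,

with λ a polynomial of degree ≤ 2. Health-survey auxiliaries are typically
right-skewed and are modelled here by three-parameter Weibull or Gamma
distributions (shape r, scale θ, location γ), fitted by profile maximum
likelihood and checked with a Kolmogorov–Smirnov statistic.

Under Neyman allocation the variance of the stratified mean is
V(ȳ_st) = (Σₕ Wₕσₕ)² / n, so the optimum stratum boundaries (OSB)
y₁ ≤ ... ≤ y_{L−1} minimize

  Σₕ φₕ,  φₕ = sqrt( Σᵢ βᵢ² Wₕᵢ² σₕᵢ² + Wₕε² σₕε² ),

where Wₕᵢ and σₕᵢ² are the stratum weight and conditional variance of the
i-th auxiliary over stratum h, available in closed form through regularized
incomplete gamma functions (Weibull/Gamma) and erf differences (the error
term). Writing widths lₕ = yₕ − yₕ₋₁ with Σlₕ = d makes the objective
separable, and the exact grid optimum is found by a forward
dynamic-programming recursion

  Φₖ(dₖ) = min_{lₖ} [ φₖ(lₖ) + Φₖ₋₁(dₖ − lₖ) ],  Φ₁(d₁) = φ₁(d₁),

with a backward trace for the boundaries, followed by local refinement below
the grid step. Stratum sample sizes are then nₕ ∝ φₕ, rounded to integers
summing to n and bounded by 1 ≤ nₕ ≤ Nₕ.

The package also provides the classical cum-√f (Dalenius–Hodges) and
geometric (Gunning–Horgan) baseline stratifiers, strata-count profiling with
elbow heuristics, and a synthetic-population generator for validation.

## Worked example

```r
library(strataDP)

# a synthetic micronutrient-survey population: two skewed auxiliaries,
# a weak linear link to a haemoglobin-like response (N = 724)
pop <- generate_population(demo_spec("anaemia_like"))

fit <- optStrata(y ~ x1 + x2, pop, L = 2:4, n = 500)
fit
#> Optimum stratification by dynamic programming
#>   auxiliaries: x1, x2
#>     x1 ~ weibull3p (KS D = 0.0156, p ~ 0.994)
#>     x2 ~ gamma3p (KS D = 0.0195, p ~ 0.945)
#>   link: RSE 1.5180 | Adj R^2 0.0899 | AIC 2664.02 (error mode: unit)
#>   L = 2: OSB = {9.73}, objective = 0.0732845
#>   L = 3: OSB = {8.66, 11.23}, objective = 0.0508933
#>   L = 4: OSB = {8.18, 9.87, 12.25}, objective = 0.039042
```

Each auxiliary was max-scaled, fitted with the better of the Weibull/Gamma
families (both KS p-values are comfortably nonsignificant), and the linear
link was estimated by least squares. For each L the reported OSB are on the
study-variable scale and the objective is Σ Wₕσₕ — the variance of the
stratified mean under Neyman allocation is its square over n. The objective
falls as L grows; `plot(fit)` shows the strata-count profile and
`suggest_elbow(fit$profile)` flags where further strata stop paying.

```r
summary(fit, L = 4)
#>  stratum   lower   upper  width       phi       W1 ...  N_h n_h
#>        1  6.7975  8.1808 1.3833 0.0091616 0.164426      244 138
#>        2  8.1808  9.8737 1.6929 0.0091718 0.150401      223 138
#>        3  9.8737 12.2496 2.3758 0.0092610 0.116235      172 139
#>        4 12.2496 17.7763 5.5267 0.0114476 0.057476       85  85
#> Total objective: 0.039042
```

The per-stratum table shows boundaries, each component's stratum weight,
conditional mean and variance, and the bounded Neyman allocation (stratum 4
is clamped at its population size N_h = 85; the excess was redistributed, so
the nₕ still sum to 500). `coef(fit, L = 4)` returns the boundaries;
`predict(fit, newdata)` assigns units to strata.

The same workflow runs from a JSON/YAML config via `run_stratification()`
or the thin CLI wrapper `inst/scripts/stratify.R`.

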