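---
title: "Monthly age patterns of under-5 mortality: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monthly age patterns of under-5 mortality: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(underfive)
```

This vignette is the package's own account of its methods: the estimation
model and its assumptions, the parameters that matter and why they default
to what they do, what the synthetic data emulate (and do not), and the
numerical decisions taken where several defensible choices existed.

## 1. Direct estimation from birth histories

All dates are century-month codes (CMC = 12·(year − 1900) + month), the
convention of full-birth-history surveys, and all age arithmetic is in
completed months. A child contributes one person-month of exposure to the
age × calendar-year cell of every completed month it lived inside the
estimation window; the month of death contributes **half** a person-month
plus one death; the interview (censoring) month contributes nothing; ages
at or beyond 60 months are out of scope. Three conventions deserve
explanation:

* **Half-month death exposure.** The monthly rate-to-probability
  conversion `q = (m/12)/(1 + m/24)` is derived by assuming deaths are
  uniform within each one-month interval, which implies the average decedent
  lives half the month. Giving the death month half a person-month keeps the
  exposure rule and the conversion formula mutually consistent. (Full-month
  exposure would bias `m` downward by up to `q/2` relatively.)
* **Year attribution.** A calendar month belongs to the year containing its
  first day. This is deterministic and independent of record order.
* **Zero-exposure cells are missing, not zero.** A cell with no exposure
  carries no information; its rate is `NA` and the smoother gives it zero
  weight rather than treating it as a zero rate. This matters structurally:
  a window of `w` years cannot observe age `x` months in its first years
  (those children were born before the window), so the early-year columns
  of the grid always have empty old-age cells.

The conversion `q = (m/12)/(1 + m/24)` is exact, monotone, satisfies
`q < m/12`, and is invertible as `m = 12q/(1 − q/2)`. It reaches `q = 1` at
`m = 24` deaths per person-year; a cell can exceed that bound only in the
pathological case where a death carries almost no exposure (e.g. a single
death with only its own half month in the cell), and the package clamps
such cells just below `q = 1` when building life tables. Summary rates are
`NMR = q[0]`, `IMR = 1 − Π_{x=0}^{11} p[x]`, `U5MR = 1 − Π_{x=0}^{59} p[x]`
with `p = 1 − q`; they nest by construction.

Records whose reported death age implies a death after the interview are
impossible and are rejected with a count. Sampling weights are accepted but
off by default: survey reports rarely state whether weights entered rate
estimation, so both modes are provided and the unweighted one is the
default.

## 2. Calibration to external rates

Direct FBH estimates suffer survivor bias (dead mothers cannot report) and
truncation bias (women age out of eligibility), so the monthly survival
schedule is calibrated to external reference rates. The band factors are

* neonatal: `f_nmr = (1 − nmr*) / ₁p₀`,
* postneonatal: `f_pmr = [(1 − imr*)/(1 − nmr*)] / ₁₁p₁`,
* child: `f_cmr = [(1 − u5mr*)/(1 − imr*)] / ₅₉p₁₂`,

where `ₐpₓ` is the observed probability of surviving from month `x` to
`x + a` and starred quantities are targets. The reference definition fixes
`f` only at band level; how the factor is spread **within** a band is a
design choice. We spread it uniformly on the log-survival scale — each of a
band's `w` monthly `p` values is multiplied by `f^(1/w)` — because that
preserves the within-band age shape exactly (all p-ratios unchanged) and
achieves exact band matching in one step. If a month's adjusted `p` would
reach 1 it is capped at `1 − 1e−9` and the residual factor is redistributed
over the band's other months; the result is flagged. After calibration the
recomputed NMR/IMR/U5MR equal the targets to 1e−12 (enforced by tests over
randomized tables). The per-band measurement error is `d_M = 1 − f_M`.
Years without a target are left uncalibrated and flagged; downstream stages
may still use them.

## 3. P-spline smoothing

Observed (or calibrated-expected) deaths are modelled as Poisson,
`D ~ Poi(E/12 · μ)`, with `log μ` expanded on equally spaced B-splines
(cubic, default one knot per 2 age-months and per 2 years) and an order-2
difference penalty on the coefficients; the offset is the log of exposure
in person-years, so the fitted scale is the annualized hazard. The 2-D
basis is the Kronecker product of the marginal bases and the penalty the
Kronecker sum `λ_age (I ⊗ D'D) + λ_year (D'D ⊗ I)`. Fitting is by
penalized IRWLS, converged when `max |Δα| < 1e−8` (cap 200 iterations;
non-convergence is flagged, never silent). The grid here is only 60 × a few
decades, so dense linear algebra is used; array-algebra shortcuts for huge
grids are unnecessary at this size.

Smoothing parameters are chosen by BIC
(`deviance + log(n_cells_with_exposure) · effective dimension`), with ties
broken toward the smoother fit. BIC is preferred over AIC because the grids
are small and the downstream Lee–Carter step benefits from a conservative
(smoother) surface. Known limits anchor the implementation: as `λ → ∞` an
order-2 penalty collapses the fit onto the Poisson-GLM straight line in
the coordinate; as `λ → 0` with a rich basis the fit interpolates the
observed counts. Both are enforced by tests, as is agreement with an
independent tensor-product P-spline fit (mgcv) on a simulated surface.

Following the method's ordering, smoothing is applied **after**
calibration: the calibrated rates re-enter the Poisson likelihood as
expected deaths `D* = m_cal · E/12` with the observed exposure. IRWLS is
indifferent to non-integer counts.

## 4. Limited-data Lee–Carter model

The smoothed log surface is decomposed as
`log m[x,t] = a[x] + b[x]·k_t + e[x,t]`: `a` is the age mean over observed
years, and the first singular triplet of the row-centered matrix gives `b`
(rescaled to sum to 1) and `k` (then summing to 0 automatically, since the
centered rows are orthogonal to the constant vector). Goodness of fit is
`ve = s₁²/Σ s_j²`. The variant implemented tolerates gapped year series and
requires only 3 observed years. Design choices:

* **No second-stage re-estimation of `k`.** The classic refinement re-fits
  `k_t` to match observed death counts; here the model is fit to smoothed,
  calibrated rates, so the SVD-stage `k` is used directly.
* **Degenerate inputs return flags.** A constant surface yields uniform
  `b`, `k ≡ 0`, `ve` reported as 1, and a `degenerate` flag — never a
  silent failure. Likewise an all-equal `k` series yields zero innovation
  variance with a flag.
* **`ve` is quoted on the calibrated, pre-smoothing surface** in the
  pipeline (the smoothed surface is nearly rank-deficient by construction,
  so its `ve` flatters the model); both values are reported.

`k` is forecast as a random walk with drift. With observation years
`t_1 < … < t_T` (possibly gapped), the drift estimate is the endpoint slope
`ĉ = (k_T − k_1)/(t_T − t_1)` — which is also the maximum-likelihood
estimate for this model under unequal spacing, since the increment
likelihood is Gaussian with mean `c·h_i` and variance `σ²·h_i` — and
`σ̂²` is the mean square of the spacing-standardized, drift-adjusted
increments `(k_{i+1} − k_i − ĉ·h_i)/√h_i`, with divisor `T − 2` (the
`T − 1` increments lose one degree of freedom to the drift). Three
bound widths at horizon `h` use nested variance components:

* **narrow** — process only: `σ̂²h`;
* **unbiased** — adds drift-estimation uncertainty `σ̂²h²/(t_T − t_1)`;
* **wide** — adds a fitting-error term `e_σ²/Σb²`, the `k`-scale variance
  implied by projecting the age-period residual onto the `b` direction
  (generalized-least-squares projection). The exact decomposition used by
  the original limited-data variant is not fully specified in public
  sources; this three-component reading is the package's documented
  contract, and the nesting narrow ⊆ unbiased ⊆ wide holds by construction.

Intervals are Gaussian on the `k` scale (default 95%) and transformed
monotonically to rates; because `b ≥ 0` (up to SVD noise) the mapping is
monotone per age and the per-indicator min/max of the two endpoint
transforms is taken. A Monte-Carlo alternative was considered and rejected
as default: the monotone transform is deterministic, reproducible, and
adequate at these horizon lengths.

## 5. Indicators and SDG classification

The decline is `D = 1 − r_end/r_start` and the annual rate of reduction
`ARR = 100·[1 − (1 − D)^{1/t}]` percent per year — the constant yearly
proportional decline equivalent to the observed total. Period lengths are
calendar-year differences (1990–2017 = 27 years). ARR composes across
concatenated periods and is invariant to common rescaling of the rates;
both are tested properties. The SDG-3 thresholds (NMR 12, U5MR 25 per
1,000) are compared inclusively (`≤`) at per-1,000 scale without rounding.
Classification defaults to median forecasts; an option uses the upper
interval bound for a conservative reading. Lowering any forecast never
moves a country to a later category (tested monotonicity).

## 6. What the synthetic generator emulates — and what it does not

The generator is the generative twin of the decomposition above:
`m[x,t] = exp(a_x + b_x k_t + e_xt)` with `k_t` a random walk with drift
anchored to sum to zero. Defaults are fixed once as study conditions:

| parameter | default | rationale |
|---|---|---|
| ages, years | 0–59 months, 1990–2017 | the under-5 range and reference period |
| `a_x` | `log(0.58·e^{−0.45x} + 0.010)` | NMR ≈ 48, IMR ≈ 130, U5MR ≈ 165 per 1,000 at `k = 0`; steep neonatal-to-child decline typical of early-1990s sub-Saharan Africa |
| `b_x` | `∝ 0.5 + x/59` | loadings rising with age: neonatal mortality declines slowest, the central empirical regularity in the region |
| `k_drift` | −1.8 / year | with mean `b = 1/60`, ≈ 3% yearly decline in rates, the regional pace (ARR ≈ 3.2%) |
| `k_sigma`, `e_sigma` | 0.15, 0.05 | period shocks and age-period noise at magnitudes that leave > 90% of log-surface variation to the first component |
| `n_women`, births/woman | 8,000, Poisson(6) | a typical national survey and the region's historical fertility; ≈ 50,000 children |
| window | 25 years | the maximal usable retrospective depth of birth-history data |
| weights | ≡ 1 (dispersion 0) | weighting is a config flag, default off |

Survivor bias removes a mother with probability `1 − (1 − s)^d` given `d`
dead children (drawn after the survival pass, so biased and unbiased runs
share one pre-bias record stream); heaping rewrites deaths at 10–14 months
to exactly 12 months with the configured probability. Fertility timing is
uniform over the window — the generator reproduces *exposure structure*,
not demographic birth-spacing realism. It also does not emulate two-stage
cluster sampling geometry, multi-survey pooling, recall displacement beyond
the 12-month heap, or correlated mortality within families. Passing tests
therefore demonstrate correctness of the estimation chain under the stated
generative model, not robustness to every real-data pathology.

## 7. Numerical choices and problem sizes

Convergence and exactness tolerances: IRWLS `1e−8` on coefficients;
calibration exactness `1e−12`; rate-conversion round trip `1e−12`; rank-1
recovery `1e−10`. Ties in BIC selection break toward larger λ. Degenerate
variance, capped probabilities, non-convergence, and rejected records all
surface as flags, warnings, or logged lines in the pipeline run log.

The test and pipeline problem sizes — 50 replicate surfaces for recovery
checks, ~50,000 children for the end-to-end consistency check, 60 × 25
grids, survey-scale cell exposures of ~1,200 person-months — were chosen so
that Monte-Carlo error is small relative to the tested effects while a full
suite run completes in well under a minute; they are package choices, not
statements about any external data set.

## 8. Known limitations

* Calibration bands are fixed (0, 1–11, 12–59 months); finer external
  constraints cannot be absorbed.
* The Lee–Carter fit is single-country, both sexes combined, first
  component only; coherent multi-country or cause-specific extensions are
  out of scope.
* Forecast intervals are Gaussian on the period index; rate-scale
  asymmetry enters only through the monotone transform.
* The smoother assumes conditionally independent Poisson counts;
  overdispersion from family clustering is not modelled.
* Early window years necessarily lack old-age cells (truncation); those
  columns rely on the smoother's interpolation and are excluded from the
  pre-smoothing `ve`.
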