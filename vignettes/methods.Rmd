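---
title: "Methods: modelling elephant-driven tourism and the cost of poaching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling elephant-driven tourism and the cost of poaching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the visitation model and its assumptions, the economic valuation, the
anti-poaching cost model, what the synthetic-data generator does and does
not emulate, and the numerical and design choices that were genuinely open.

## The visitation model

Average annual tourist visits $V_i$ at protected area (PA) $i$ are modelled
on the natural-log scale:

$$\log V_i \sim \mathrm{Normal}(\mu_i, \sigma), \qquad
\mu_i = \mathbf{x}_i^\top\boldsymbol\beta + (\beta_D + \beta_{DF} F_i)\, d_i$$

with fixed covariates $\mathbf{x}_i$ = (intercept, log area, forest, lion,
attractiveness, log surrounding population, log travel time, log national
income) and latent elephant density $d_i$ (animals km⁻²). Log
transformation of visits and of the scale covariates keeps the predictors
commensurate and the residuals approximately normal; density and the 1–5
attractiveness score enter untransformed, and this choice is deliberate:
the semi-elasticity interpretation ($100(e^{\beta_D}-1)$ percent more
visits per additional elephant km⁻²) and the linear scaling of small
density changes only make sense with density on its natural scale.

### Density as a latent quantity

Elephant population estimates carry heterogeneous uncertainty:

* **sd-form** — the census reports mean and standard deviation; the model
  uses $d_i \sim \mathrm{Normal}(m_i/a_i,\, s_i/a_i)\,T(0,)$ with $a_i$
  the censused area. Truncation at zero reflects that densities cannot be
  negative.
* **range-form** — `range_to_normal()` reads the reported range as a 95%
  interval of a normal: mean at the midpoint, $sd = (hi-lo)/(2 \times
  1.959964)$.
* **no uncertainty** — the sd is a model parameter centred on the
  empirical line $sd = 192 + 0.122\,m$ with residual scale
  $\sigma_{imp}$; $\sigma_{imp}$ is itself estimated from the records that
  do report an sd (half-Normal(0, 500) prior). Fixing the line's intercept
  and slope while estimating only its residual scale mirrors how the
  relation is used: as a strong, externally established regression, not
  something to re-learn from weakly informative visit data.
* **no elephants** — $d_i$ is fixed at exactly 0; there is no observation
  model and the record still informs the fixed-covariate coefficients.
  Records whose reported sd is numerically zero (e.g. a degenerate range)
  are likewise treated as exactly observed, avoiding infinite precisions.

### Priors, sampling and diagnostics

Coefficients get Normal(0, 10²) priors *on the standardized scale* (scale
covariates are internally centred and scaled for sampler stability;
coefficients are transformed back before reporting), and $\sigma$ a
half-Normal(0, 5): both are vague relative to coefficient magnitudes of
order 1. Sampling uses JAGS with the `glm` module loaded (block updates of
the conjugate linear part roughly triple the effective sample size of the
density coefficients at no extra cost). Half of the warmup budget is spent
in the adaptive phase and half as plain burn-in. Chains are seeded
deterministically from the configuration seed, so identical configurations
give bit-identical draws.

Convergence is assessed by split-$\widehat R$ (each chain halved, the usual
between/within variance ratio over the half-chains) with threshold 1.01,
and by effective sample size (coda's spectral estimator) with a floor of
400 — enough for stable 2.5%/97.5% quantiles. Parameters with zero
posterior variance (densities fixed at 0) are excluded. The default
`mcmc_scale = "test"` (4 chains × 1,000 + 1,000) is a smoke scale: on
216-PA tables the slow-mixing density coefficient typically needs roughly
10,000 sampling iterations per chain to pass both thresholds, and
`mcmc_scale = "paper"` (4 × 25,000 + 25,000) reproduces the published
sampling effort. A failed convergence check never raises; it is reported
with `pass = FALSE` so pipelines can decide.

## Counterfactual and valuation

One year of poaching at decline rate $r_i$ moves density from $d_i$ to
$d_i(1-r_i)$. Both arms of the counterfactual hold all other covariates at
their fitting-sample means on the transformed scale (the PA's own forest
flag drives the interaction term), and both use the censused mean density
for the baseline arm — the two arms differ *only* by the decline factor,
so the loss is driven entirely by the posterior of $(\beta_D + \beta_{DF}
F_i)$. Predicted visits per draw are $e^{\mu}$, the median of the
log-normal predictive; losses are differences of posterior medians, floored
at zero (a PA whose habitat-specific density effect is negative would
otherwise gain visits from poaching; the floor is logged).

Monetisation draws, independently per PA and per replicate, a per-visit
direct spend from an Exponential distribution (maximum-likelihood rate =
1/mean of the expenditure estimates) and a total-impact multiplier from a
Normal truncated below at 1 (a total-impact multiplier under 1 would imply
negative indirect spending). Indirect/induced loss is `direct ×
(multiplier − 1)`, which makes direct and indirect losses additive into a
total — the convention that makes separately reported direct and
"additional" indirect losses coherent. A closed-form oracle
(`expected_loss_oracle()`, using the analytic truncated-normal mean)
verifies the simulation in the test suite; it is never used in place of
it. The default 100,000 replicates put the Monte Carlo standard error of
the means well below 1%.

In regional summaries the package reports *means* with 2.5%/97.5% quantile
intervals for direct, indirect and total losses, and the total is the
per-draw sum of the other two. Published regional tables of this kind can
contain total-benefit columns that are not the sum of their direct and
indirect columns (plausibly medians of a skewed sum); this package does not
attempt to reproduce such a column and documents the mean convention here.

## Anti-poaching costs and ROI

The only quantitative anchor for effective anti-poaching spending is a
1980s cross-country regression valid for populations above 1,000 animals,
summarised by one calibration point: zero population decline at $215 km⁻²
in 1981 USD, equal to $565 km⁻² in 2016 USD. Inflation is a configured
scalar (565/215 ≈ 2.628), not a CPI lookup, removing an external-data
dependency while matching the printed endpoint. Because the original
regression's shape is not reproducible from the calibration point alone,
the package adopts an explicit one-parameter log-spend response anchored at
it:

$$g(s) = b \,(\log s - \log 565), \qquad s(g) = 565\, e^{g/b}$$

with $b$ (`slope_b`, default 0.05 per unit log-spend) configurable and the
round trip $g \to s \to g$ exact. The default says: a ~5% annual decline
implies spending about $e^{-1} \approx 37\%$ of benchmark — a deliberately
moderate response; users with better cost data can supply
`current_spend_km2` directly, which takes precedence. The shortfall is
$\max(0, 565 - s)\times$ area, restricted to PAs above the 1,000-animal
threshold where the benchmark is valid (smaller PAs are skipped with a
message, not an error). Regional ROI is $100(\text{benefit} -
\text{cost})/\text{cost}$ with benefits the regional mean total losses at
those same PAs. ROI figures computed this way from simulated means need
not match published figures computed from internal simulation
distributions; the arithmetic itself is exact and tested.

## What the synthetic generator emulates — and what it does not

`generate_pa_table()` reproduces the *design* of the fitting data: 216
elephant PAs plus 54 elephant-free PAs with visits, 164 visited PAs in
total, uncertainty forms assigned in the proportions 43% sd / 12% range /
45% missing, exactly 58 PAs above 1,000 reported elephants, reported sds on
the line $192 + 0.122 \times$ mean (Gaussian jitter, sd 25, floored at 1),
and visits generated from the log-linear model at the *latent* density.
Covariate marginals are declared, not inferred: area and the other scale
covariates log-uniform over realistic ranges (10–10⁴ km²; 10³–10⁶ people;
30–3,000 minutes; $500–20,000 PPP), forest Bernoulli(0.25), lion
Bernoulli(0.6), attractiveness uniform on 1–5, density uniform on (0, 2)
km⁻² where present. Default coefficients use the magnitudes a cross-site
tourism model of this kind estimates for the density, forest, interaction,
lion and attractiveness terms, with moderate values for the scale
covariates and an intercept chosen so the median generated PA receives on
the order of 2,000 visits a year; residual sd defaults to 1.5, giving
visits spanning roughly four orders of magnitude across PAs.

One structural choice matters for testing: the latent true population is
drawn as a zero-truncated normal *about the reported mean*, i.e. the
generator samples truth conditional on the report under the same symmetric
measurement relation the model assumes. This is the simulation-based
calibration construction — generate from the model's own joint
distribution — and it is what makes credible-interval coverage on
generated tables a meaningful test (observed coverage of the density
coefficient is ≥ 90% over 50 replicates in the acceptance suite). The
alternative (fix the truth, truncate noisy observations at zero) breaks
the symmetry at small populations, where the sd line's 192-animal
intercept dominates, and would test a model the package does not claim to
be.

Consequently, passing tests show that the *pipeline is correct under its
own assumptions*; they do not show that real censuses follow a symmetric
normal error law, that real covariates are log-uniform, or that real
spatial correlation (absent here) is ignorable. Two visible artefacts of
the synthetic world: observed-vs-predicted R² on generated tables is high
(≈ 0.9), because weakly constrained latent densities partially absorb
residual noise — real-data fits of this model class report R² near 0.44 —
and regional ROI patterns depend entirely on the generator's uniform
poaching-rate and region assignments, not on real geography.

The within-site generator (`generate_within_site_panel()`) emulates a
56-year single-park series — area and GDP growing smoothly, density
recovering from ~0.1 to ~2 km⁻² — for the reduced model of visits on log
area, log GDP and density, with defaults matching the coefficient
magnitudes such a panel yields (density effect 0.67, residual sd 0.38).

## Numerical choices and degenerate inputs

* Truncated-normal draws use the inverse-CDF construction with a guard for
  extreme truncation; `sd = 0` collapses to the max of mean and the bound.
* PA tables are serialised at 17 significant digits so read–write round
  trips are bit-stable.
* Imputed population sds are truncated below at 1 animal inside the model,
  bounding precisions.
* Visits ≤ 0, lo > hi ranges, both sd- and range-form present, decline
  rates outside [0, 1) and missing covariates are rejected with the PA id
  and field named; category-I rows are dropped (with a count) at read
  time, the single choke point for that filter.
* Zero-variance posterior columns are excluded from diagnostics rather
  than reported as R̂ = NaN.

## Problem sizes used by the test suite

Unit tests run the sampler on 30–100-PA tables with 2 chains × a few
hundred iterations, where recovery and reproducibility are already
decisive; the acceptance suite uses full 270-record tables — 50 replicate
fits at the 4 × 1,000 + 1,000 test scale for coverage, and 100,000-draw
valuations against the closed-form oracle. The `"paper"` MCMC scale is
exercised through configuration tests and available for full-scale runs.

## Known limitations

* The measurement-error law, covariate marginals and region assignments of
  the synthetic world are declared conveniences, not estimates.
* The cost model's slope is a configured assumption; only its calibration
  point is externally anchored.
* No spatial random effects, no density dependence in the poaching
  projection (one-year horizon only), no alternative likelihoods: the
  model family is fixed, matching the analysis it implements.
* Poaching decline rates are consumed as given; the demographic conversion
  from carcass-ratio indices (PIKE) to population growth is upstream of
  this package.
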