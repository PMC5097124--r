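# poachval

Tourism losses and anti-poaching returns for African elephant protected
areas.

Elephant poaching removes one of the strongest draws for nature-based
tourism in sub-Saharan Africa, but the economic cost of that loss — and how
it compares with what it would take to stop the killing — is rarely
quantified. `poachval` implements a continental benefit–cost analysis for
conservation scientists and ecological economists: it models annual tourist
visits to protected areas (PAs) as a function of elephant density, predicts
how poaching-driven density declines reduce visits, converts lost visits
into lost tourism spending, and compares those losses with the anti-poaching
spending shortfall at PAs with large elephant populations.

## The model

Annual visits \(V_i\) at PA \(i\) follow a log-linear regression with an
errors-in-variables treatment of elephant density:

```
log V_i = b0 + b_A log A_i + b_D d_i + b_F F_i + b_DF d_i F_i + b_L L_i
          + b_N s_i + b_P log P_i + b_T log T_i + b_G log G_i + e_i,
e_i ~ Normal(0, sigma)
```

where \(A_i\) is PA area (km²), \(F_i\) forest cover, \(L_i\) lion
presence, \(s_i\) a 1–5 attractiveness score, \(P_i\) surrounding
population, \(T_i\) travel time from the nearest city, \(G_i\) national
income (PPP), and \(d_i\) the *latent* elephant density (km⁻²). Density is
never observed exactly: each censused population reports a mean and either a
standard deviation, a range (read as a 95% interval of a normal), or no
uncertainty at all. The model treats \(d_i\) as a zero-truncated normal
about the reported mean with the reported sd (both divided by the censused
area); missing sds are imputed *inside* the model from the strong empirical
line `sd = 192 + 0.122 × mean`, whose residual scale is learned from the
populations that do report an sd. The joint posterior is sampled by MCMC
(JAGS), with split-R̂ ≤ 1.01 and effective-sample-size checks.

Downstream of the fit:

* **Counterfactual** — per-PA visits are predicted at the censused density
  and at `density × (1 − poaching rate)`, covariates held at their means;
  the visit loss is the difference of posterior-predictive medians.
* **Valuation** — lost visits are monetised by Monte Carlo (100,000
  replicates): per-visit direct spend ~ Exponential (MLE from expenditure
  estimates), total-impact multiplier ~ Normal truncated at 1; indirect
  loss is `direct × (multiplier − 1)`.
* **Return on investment** — for PAs with > 1,000 elephants, current
  spending implied by the population decline is compared with the $565 km⁻²
  (USD 2016; $215 km⁻² in 1981) benchmark that historically stabilised
  large populations; ROI = 100 × (benefits − costs) / costs.

A synthetic-data generator (`generate_pa_table()`) reproduces the study
design — 216 elephant PAs plus 54 elephant-free visited PAs, 164 with
visits, 43%/12%/45% sd/range/missing uncertainty, 58 PAs above 1,000
elephants — so the full pipeline is testable without the original survey
data.

## Worked example

```r
library(poachval)

pa  <- generate_pa_table(synthetic_params(seed = 1))   # $pa + $truth tables
est <- generate_spend_estimates(seed = 1)
cfg <- pipeline_config(
  mcmc = list(chains = 4, warmup_iters = 10000, sampling_iters = 10000,
              seed = 1),
  valuation = list(n_draws = 100000, seed = 1))
report <- run_pipeline(pa$pa, est, cfg)
print(report)
```

which prints (about half a minute on one core):

```
== Elephant tourism-loss pipeline report ==
records: 270 (164 with visits, 216 with elephants, 58 > 1,000 elephants)
Convergence: PASS (max R-hat 1.0061 vs 1.01; min ESS 622 vs 400)

Posterior coefficient summary (analysis scale):
                parameter   mean     sd   q2.5    q97.5   ess rhat
1               intercept  8.997 1.5229  5.992 11.96738 21788 1.00
2                log_area -0.347 0.0805 -0.504 -0.18515 13277 1.00
3        elephant_density  1.570 0.1793  1.252  1.95393   622 1.01
...
Aggregate annual visit loss from poaching: 44,138 visits
Direct losses:   $9.04M (95% CI $6.62M-$12.12M)
Indirect losses: $17.47M (95% CI $12.43M-$24.18M)
```

The generator's true density coefficient is 1.55, recovered here as 1.57
with a 95% credible interval (1.25, 1.95); `effect_size_percent(1.55)`
converts such a coefficient into the headline semi-elasticity — a 371%
increase in visits per additional elephant km⁻² — and
`marginal_visits(1883, 1.55, 0.1)` ≈ 699 extra annual visits per
0.1 km⁻² at a median-sized PA. The report also carries the per-PA
counterfactual, regional valuation/cost/ROI tables and the convergence
report; `render_report(report, "json", "out/")` writes them to disk.

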