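# canopymatch

Quasi-experimental estimation of the causal effect of new mining
developments on deforestation.

Mines are not placed at random: they appear near roads, towns and
accessible terrain — the same things that drive deforestation. Naive
comparisons of forest loss near and far from mines therefore confound the
mine's effect with the drivers of its placement. `canopymatch` implements
the full counterfactual pipeline for separating the two, for analysts
evaluating the deforestation footprint of extractive industry:

- **Canopy-weighted loss metric** — converts fine-resolution tree-cover and
  loss-year rasters into yearly *tree canopy area lost* (m²) per 1 km²
  pixel, so clearing a hectare of dense forest counts more than a hectare
  of sparse woodland; a forest mask (≥ 10% cover at the ~0.5 ha block
  scale) and an unweighted "forest area lost" variant are included.
- **Study design** — treated pixels from mining leases buffered by 25 km
  (10/50 km as sensitivity), control candidates carved from exploration
  leases minus all mine footprints and buffers, systematic lattice
  subsampling, forest and region filters, and a pre-treatment-outcome flag.
- **Statistical matching** — propensity-score matching (1–1 nearest
  neighbour, no replacement, 0.25 SD caliper, common support, exact on
  categoricals), coarsened exact matching, and random-draw controls, with
  standardised-mean-difference balance reports.
- **Outcome model** — a Bayesian zero-inflated negative binomial regression
  of matched pixel-years: per-year treatment contrasts, covariates, yearly
  Matérn spatial fields with penalised-complexity priors
  (P(range > 50 km) = 0.95) and an iid pixel effect, sampled by Hamiltonian
  Monte Carlo over a reduced-rank field representation. The model is

  log μ_it = xᵢᵀβ + γ_t + δ_t·treated_i + u_t(s_i) + v_i,  y_it ~ ZINB(μ_it, k, π)

  and the reported estimand is the posterior difference in expected canopy
  loss, (1−π)μ, between treated and control pixels, per year and
  aggregated, with 80%/95% highest-posterior-density intervals.
- **Diagnostics** — posterior predictive checks, simulated quantile
  residuals, and residual variograms with permutation envelopes.
- **Synthetic landscapes** — a generator with confounded mine placement,
  spatially autocorrelated clearing hazards, block-level zero inflation and
  an injectable treatment effect, so the whole pipeline is testable against
  known ground truth without any external download.

## Worked example

Simulate a landscape with a known treatment effect (θ = 0.8 on the
clearing log-odds inside the buffered mine), run the pipeline, and read off
the per-mine treatment effect:

```r
library(canopymatch)

cfg <- landscape_config(extent = c(30000, 30000), n_years = 10, seed = 42,
                        lease_counts = c(lml = 1, lel = 8, ssl = 1),
                        buffer_distance = 3000, baseline_logit = -4.2,
                        n_regions = 1, treatment_multiplier = 0.8)
run <- run_study(cfg, buffer_m = 3000, ssl_buffer = 1000,
                 subsample_scheme = "2x2", draws = 1500, warmup = 700,
                 confounders = c("mean_treecover", "sd_treecover",
                                 "slope", "pre_loss"))
run$mines[[1]]$ate
#>   year  mean hpd80_lo hpd80_hi hpd95_lo hpd95_hi unit
#> 1    1 21760     7506    30938   3650.7    39494   m2
#> 2    2 22646     8279    35822   1045.2    45734   m2
#> 3    3 19517     4522    30363   -699.5    46578   m2
#> 4    4 20751     4681    28551   3090.2    48895   m2
#> 5    5 16951     3165    24441  -2082.2    47785   m2
#> 6  all 20325     8360    29300   7178.0    40409   m2
```

Treated pixels lost on average ~20,000 m² (2 ha) more canopy per pixel-year
than their matched controls, every year since activation; the aggregated
80% HPD interval [8,360, 29,300] m² excludes zero, so the injected effect
is detected. With `treatment_multiplier = 0`, the same pipeline reports
intervals covering zero at the nominal rates (`no_effect_80` in the
report), reproducing the decision rule used to declare "no evidence of
excess deforestation". `autoplot()` methods draw the interval plot, the
balance (love) plot, the residual QQ and the variogram;
`sensitivity_suite()` reruns everything under the five alternative
matching/buffer configurations and tabulates the results side by side.

Individual stages are ordinary functions over tibbles — the pipe-friendly
path is `canopy_loss_metric() |> assemble_study_frame() |> fit_propensity()
|> psm_match() |> prepare_response() |> fit_outcome_model() |>
estimate_ate()` — and `tidy()`/`glance()` summarise fitted models.

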