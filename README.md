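# fiprisk

Probabilistic dietary risk assessment of fipronil residues in food, for
exposure scientists and regulatory toxicologists who need a reproducible,
fully scriptable alternative to point-estimate (deterministic) risk
characterization. The package implements the complete chain:

1. **Censored-residue reconstruction.** Surveillance programs report mostly
   non-detects (censoring rates above 95% for fipronil). For each food
   category the concentration is modelled as lognormal with geometric mean
   GM, geometric standard deviation GSD and an *inferred* reporting limit RL:
   detects contribute lognormal densities, each non-detect contributes the
   lognormal CDF at RL. Priors follow the data
   (GM ~ Normal(max(Y)/2, max(Y)/4), RL ~ Normal(min(Y), min(Y)/5),
   ln GSD ~ Normal(ln 4, ln 2)); sampling is multi-chain adaptive Metropolis
   with the Gelman–Rubin R̂ < 1.1 convergence rule. Categories with a single
   detect are augmented with one extra value at the detection limit.
2. **Population exposure simulation.** A demographically stratified
   population (ages 0–100 × sex, at least 10 individuals per stratum) is
   allocated by largest-remainder rounding; body weights and per-category
   food intakes are drawn from truncated normals, residues from the fitted
   posterior lognormals, and the aggregate dose is
   `sum_i intake_i [g/day] × residue_i [mg/kg] / (1000 × bodyweight [kg])`
   in mg/kg/day, under a general-population (LB) and a consumer-only (UB)
   intake scenario.
3. **Bayesian benchmark dose (BMD) modelling.** Eight standard dichotomous
   models (Logistic, LogLogistic, Probit, LogProbit, Quantal linear,
   Multistage 2nd order, Weibull, Dichotomous Hill) are fitted by MCMC to
   dose–incidence data; the BMD at 10% extra risk,
   `(p(d) − p(0)) / (1 − p(0)) = 0.10`, is inverted in closed form per draw,
   and the per-model posteriors are averaged with posterior model weights
   (Schwarz approximation on the posterior-average log likelihood).
4. **Probabilistic reference dose.** Animal BMD draws are converted to a
   human HD50 via allometric scaling, `HD50 = BMD × (BW_a/BW_h)^(1−b) / A`
   with `b ~ N(0.7, 0.0243)` and interspecies factor
   `A ~ Lognormal(GM 1, GSD 1.95)`, then to the target human dose HDMI
   (incidence I = 1%, magnitude M = 10% extra risk) by dividing by `10^F`,
   `F ~ Lognormal(GM 0.746, GSD 1.5935)`. The pRfD is the lower 5th
   percentile of the HDMI distribution.
5. **Risk characterization.** Hazard quotients HQ = exposure / reference
   against both the deterministic ADI (NOAEL 0.019 / SF 100 =
   0.0002 mg/kg/day) and the pRfD, with exceedance counts by age group and
   sex.

A synthetic-data module generates residue datasets, demographics, body
weights, intakes and dose-response tables with the statistical structure the
analysis assumes, so the entire pipeline is testable without access to the
original Taiwanese databases.

## Worked example

Reconstruct a root-and-stem-vegetable (RV) style residue distribution from
heavily censored synthetic data:

```r
library(fiprisk)

rv  <- fipronil_residue_summary()[8, ]          # 1760 samples, 44 detects
cal <- calibrate_gm_gsd_to_spec(rv)             # lognormal matching the summary
ds  <- generate_residue_dataset(rv$n_total, cal$gm, cal$gsd,
                                category = "RV", seed = 1)
fit <- fit_censored_lognormal(augment_single_detect(ds),
                              mcmc = mcmc_settings(n_chains = 4,
                                                   n_iter = 25000, seed = 1))
print(fit)
#> Censored lognormal fit [RV] (marginalized likelihood)
#>   53 detects, 1707 non-detects; DL = 0.002 ppm
#>   posterior medians: GM = 3.03e-05 ppm, GSD = 9.47, RL = 0.00204 ppm
#>   arithmetic moments: mean_est = 0.0003952, std_est = 0.006589 ppm
#>   max R-hat = 1.004 (converged)
```

The posterior medians recover a distribution whose censoring fraction and
detected-sample moments match the surveillance summary; `mean_est`/`std_est`
parameterize the lognormal used for residue draws in the exposure simulation
(`sample_posterior_residues()`, `run_exposure_scenario()`).

Derive the probabilistic reference dose from the published convulsion
dose-response data (doses 0–12.68 mg/kg/day, incidences 0/50 … 5/50):

```r
fits     <- fit_dichotomous_models(fipronil_convulsion_data())
weights  <- compute_model_weights(fits)
round(weights, 3)
#>        Logistic     LogLogistic          Probit       LogProbit   QuantalLinear
#>           0.202           0.102           0.202           0.083           0.201
#>     Multistage2         Weibull DichotomousHill
#>           0.074           0.096           0.039
averaged <- model_average_bmd(fits, weights, n_draws = 1e5, seed = 2)
hdmi     <- derive_prfd(averaged, seed = 3)
print(hdmi)
#> Probabilistic reference dose derivation (mg/kg/day)
#> Protection-direction percentiles:
#>                    BMD   HD50    HDMI
#> Median          14.400 3.1240 0.51690
#> 90th percentile  7.784 1.0560 0.09141
#> 95th percentile  6.190 0.7738 0.04959
#> 99th percentile  2.247 0.3264 0.01258
#> pRfD (lower 5th percentile of HDMI): 0.0496 mg/kg/day
```

The two-parameter models each carry about 20% of the posterior weight, the
three-parameter models about 7–10%, the four-parameter Hill model about 4%.
The pRfD of ~0.05 mg/kg/day says that, accounting for point-of-departure,
allometric, interspecies and human-variability uncertainty, a chronic dose
below this level keeps at least 99% of the population below a 10% extra risk
of the critical neurotoxic effect with 95% confidence. It is roughly 250-fold
above the deterministic ADI (`derive_adi(0.019, 100)` = 2e-4 mg/kg/day).

`run_full_assessment(run_config(...))` chains all five stages from CSV inputs
to JSON/CSV outputs with per-stage seeds derived from one master seed;
`write_synthetic_bundle()` emits a complete synthetic input set.

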