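---
title: "Methods: probabilistic dietary risk assessment with left-censored residues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic dietary risk assessment with left-censored residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fiprisk)
```

# The problem

Chronic dietary risk from a pesticide is the ratio of a population's
aggregate daily dose to a health reference value. Both sides of that ratio
are uncertain. On the exposure side, residue surveillance data for fipronil
are dominated by non-detects (censoring above 95% in most food categories),
so the concentration distribution below the detection limit must be
reconstructed, not substituted. On the reference-value side, a single NOAEL
divided by a fixed safety factor hides how much of the margin is
point-of-departure uncertainty versus interspecies or human variability.
`fiprisk` treats both sides probabilistically and propagates every stage by
Monte Carlo.

# Censored-residue model

For a food category with detected concentrations $y_1,\dots,y_{N_{obs}}$
(ppm) and $N_{cen}$ non-detects, the model is

$$\ln y \sim \mathrm{Normal}(\ln GM,\ \ln GSD), \qquad
\Pr(\text{non-detect}) = \Phi\!\left(\frac{\ln RL - \ln GM}{\ln GSD}\right),$$

with the reporting limit $RL$ treated as a parameter: surveillance labs
flag "< DL" based on an operational threshold that need not equal the nominal
detection limit, and detects slightly below the nominal DL do occur. Priors
are data-dependent, following common practice for reconstruction from
summary-dominated data: $GM \sim N(\max Y/2, \max Y/4)$ truncated to
$(0,\infty)$; $RL \sim N(\min Y, \min Y/5)$ truncated to $(0, \min Y]$
(a reporting limit above an observed detect would be contradictory);
$\ln GSD \sim N(\ln 4, \ln 2)$, centred on the geometric spread of the
pooled detected samples (~4). The lognormal prior on GSD is read as
location/scale on the log scale, the natural parameterization for a
positive, multiplicative quantity; prior *scale* arguments are standard
deviations, not variances, throughout.

Two likelihood modes are available. The default **marginalized** mode adds
$N_{cen} \cdot \ln \Phi(\cdot)$ once — the censored contribution in closed
form. The **latent** mode instead carries one latent concentration per
non-detect, constrained below $RL$ by a scaled-logistic transform; it
reproduces the marginalized posterior (the latent variables integrate out
exactly) at far higher cost for heavily censored categories (1,716 extra
parameters for root-and-stem vegetables), and exists for fidelity with the
explicit-imputation formulation and for posterior draws of the non-detect
values themselves. The equivalence is asserted by a test on a 60-sample
dataset.

GSD is parameterized as $\exp(\exp(u))$, i.e. constrained above 1: the
lognormal scale $\ln GSD$ must be positive, and with prior mass centred at 4
the bound is never active in practice.

Each fit reports the derived arithmetic moments
$\text{mean} = GM\,e^{(\ln GSD)^2/2}$ and
$\text{sd} = \text{mean}\sqrt{e^{(\ln GSD)^2}-1}$, averaged over retained
draws (`mean_est`, `std_est`). These — not the posterior medians — feed the
exposure stage, matching the convention of defining the predictive residue
lognormal by its posterior-mean arithmetic moments.

## Sampling and convergence

All posteriors are sampled by multi-chain adaptive random-walk Metropolis on
an unconstrained scale (log, log-log, or scaled-logit transforms with exact
Jacobians). During warmup the global proposal scale adapts by Robbins–Monro
toward 30% acceptance and the per-parameter scales track the empirical
spread of recent draws; after warmup the kernel is fixed, so retained draws
come from a valid Markov chain. Defaults: 4 chains × 25,000 iterations for
residue fits, 3 chains × 50,000 for dose-response fits, last 50% of each
chain retained and pooled. Convergence is the Gelman–Rubin potential scale
reduction factor below 1.1 on every monitored parameter (computed on the
natural scale); non-convergent fits are returned flagged, never silently
re-run, and downstream samplers refuse flagged fits.

# Exposure simulation

Individuals are allocated to age (0–100) × sex strata proportionally to
population counts by largest-remainder rounding (ties broken by stratum
order), then raised to a minimum of 10 per populated stratum with
compensating reductions from the largest strata — totals are exact and the
default population of 200,000 accommodates 202 strata × 10. Body weight is
drawn per stratum from a truncated normal on
$[\max(0.5, \mu - 4\sigma), \mu + 4\sigma]$ kg and category intakes from
truncated normals on $[0, \mu + 6\sigma]$ g/day: the sources state truncated
normals without bounds, and non-negativity is the operative constraint; the
4–6 SD caps only remove physically meaningless extremes. Truncated-normal
sampling is by inverse CDF (exact, no rejection). The aggregate dose is

$$D_j = \frac{\sum_i \text{intake}_{ij}\ [\text{g/day}] \times
\text{residue}_{ij}\ [\text{mg/kg}]}{1000 \times BW_j\ [\text{kg}]}
\quad [\text{mg/kg/day}],$$

where the 1000 converts grams of food to kilograms — division, not
multiplication, which is what reproduces exposures in the
$10^{-6}$–$10^{-5}$ mg/kg/day range for these residue levels. One residue
and one intake draw per individual per category, independent across
categories (chronic-average interpretation, no correlation structure), under
a general-population (LB) and consumer-only (UB) intake scenario.

# Dose-response and model averaging

The eight standard dichotomous forms are parameterized as in mainstream BMD
software (background $g$, plateau $v$ for the Hill model, intercept $a$ and
slope/power terms); at dose zero the log-dose models return the background.
The benchmark dose solves extra risk
$(p(d) - p(0))/(1 - p(0)) = \mathrm{BMR}$ (default 0.10) in closed form for
every model; a numeric bracketed root-finder (`uniroot`, relative tolerance
1e-10) is kept as an independent cross-check and the two agree to 1e-8 in
the test suite. Draws whose curve cannot attain the BMR (zero slope, or Hill
plateau $v \le \mathrm{BMR}$) have no benchmark dose; they are excluded from
the BMD posterior and their fraction is recorded on the fit object.

## Priors

The default `weakly_informative` scheme is: uniform priors on backgrounds
and dose-scaled rate parameters over their bounds; Normal(0, 2) on intercept
parameters $a$ (the standard weakly-informative scale on a logit/probit
axis); Lognormal(0, 0.5) on the dimensionless shape parameters — the
log-dose slopes of LogLogistic, LogProbit and Dichotomous Hill and the
Weibull power. The rationale for the last group: under a flat prior these
models place substantial posterior volume on near-flat curves (slope → 0),
which the five-group design cannot distinguish from genuinely shallow
curves, and there the benchmark dose diverges *exponentially*
($BMD = e^{(\text{logit}(0.1)-a)/b}$), producing posterior BMD draws of
$10^5$–$10^{10}$ mg/kg/day that no dose-response datum supports. A median-1
prior with 90% interval (0.44, 2.3) removes that degenerate region while
leaving the data-identified range untouched. Dose-scaled rates (quantal
linear and Weibull $b$, multistage $b_1, b_2$) are left uniform because
their scale depends on the dose units and the prior volume near zero is
negligible there. A fully `uniform` scheme is available as a configuration
switch for sensitivity analysis.

## Posterior model weights

The reference web implementations of Bayesian BMD averaging do not publish
their weight formula, so the package makes its own choice and exposes it.
The default is a Schwarz-type marginal-likelihood approximation with fit
measured by the **posterior-average** log likelihood:
$w_m \propto \exp(\bar\ell_m - \tfrac{k_m}{2}\ln n)$, with $n$ the number of
dose groups. Measuring fit at the posterior average rather than the maximum
makes the weight robust to a flexible model fitting noise in a single dose
group (the convulsion data are non-monotone: 3/50 at 0.059 then 1/50 at
1.27 mg/kg/day, a pattern the four-parameter Hill model can chase); each
extra parameter costs a factor $\sqrt{n}$. On a five-group design with
near-equal fits this yields roughly 20% per two-parameter model, 8–10% per
three-parameter model and 4% for the Hill model — the dimension-graded
pattern familiar from published model-averaged BMD analyses. Alternatives
(`bic_max`, Laplace–Metropolis `laplace`, `pseudo_bma`) are one argument
away. Averaging itself is mixture sampling: model index by weight, then a
BMD draw from that model's posterior.

# Probabilistic reference dose

Per averaged BMD draw, the chain samples an allometric exponent
$b \sim N(0.7, 0.0243)$ and interspecies TK/TD factor
$A \sim \mathrm{Lognormal}(GM\,1, GSD\,1.95)$, giving
$HD_{50} = BMD \cdot (BW_a/BW_h)^{1-b} / A$, then a human-variability value
$F \sim \mathrm{Lognormal}(GM\,0.746, GSD\,1.5935)$ applied as
$HDMI = HD_{50} / 10^{F}$. Three conventions deserve note:

* **$F$ is the log10 of the variability factor.** Its geometric mean 0.746
  corresponds to a median factor of $10^{0.746} \approx 5.6$ for protecting
  all but 1% of the population — the WHO/IPCS approximate probabilistic
  tabulation for incidence 0.01. Dividing by $F$ itself (median < 1) would
  *increase* the dose and invert the protection ordering, so the exponent
  reading is forced.
* **Animal body weight** is not part of the published parameter set; the
  package default is 0.35 kg (adult male rat), under which
  $(0.35/70)^{0.3} = 0.204$. It is an explicit, required configuration
  value, and the acceptance tests report the sensitivity of the pRfD over
  $BW_a \in [0.25, 0.5]$ kg (the scaling enters as $(BW_a/70)^{1-b}$, about
  a 23% span across that range).
* **Percentiles are protection-direction**: the "90th/95th/99th percentile"
  rows of the summary table are the lower 10th/5th/1st percentiles of each
  distribution — the values get *smaller* down the table. The pRfD is the
  lower 5th percentile of HDMI (95% one-sided confidence). The divide
  convention for the GM-1 interspecies factor is distributionally
  irrelevant but fixed for reproducibility.

The uncertainty decomposition reports each component's share of the total
variance of $\ln HDMI$: $\ln BMD$ (point of departure),
$(1-b)\ln(BW_a/BW_h)$ (allometric), $-\ln A$ (interspecies) and
$-F\ln 10$ (human variability). Shares are nonnegative and sum to one by
construction; human variability carries the largest share in the default
chain, which the acceptance suite asserts.

# Risk characterization

$HQ = $ exposure / reference, with the scalar pRfD (not the full HDMI
distribution) as the probabilistic reference, and the deterministic
ADI $= 0.019/100$ mg/kg/day as comparator. HQ exactly 1 counts as a
non-exceedance (a measure-zero event under continuous exposure).
Exceedance counts partition exactly across age-group and sex summaries.

# Synthetic data: what it emulates and what it does not

The generators reproduce the *statistical structure* the pipeline assumes:
lognormal residues censored at 0.002 ppm with category summaries matching
the published surveillance table (calibration solves
$\Pr(Y < DL) = 1 - n_{detect}/n_{total}$ exactly and the conditional mean
above the DL exactly, by 1-D root finding in $\ln GSD$ — with three summary
targets and two parameters the conditional SD is over-determined and is
reported as a diagnostic; with zero censoring the unconditional moments are
matched instead); a smooth age pyramid with logistic body-weight growth
(birth 3.3 kg to adult means 70/58 kg, SD 15% of the mean); intake means
spanning 5–80 g/day with consumer-only means always at least the
general-population means; binomial dose-response draws from any model curve
with the truth attached for recovery tests. Every generator is a pure
function of (specification, seed).

They do **not** emulate: year-to-year survey structure, item-level (versus
category-level) resolution, intake correlations across categories or with
body weight, regional or seasonal variation, or the actual Taiwanese
demographic pyramid and consumption estimates. Passing tests therefore
demonstrate that the *methods* recover known truth under the assumed
structure at realistic censoring rates — not that the absolute exposure
levels equal those computable only from the original consumption and
demographic databases. For that reason the exposure stage is validated by
exact identities (moment round trips, linearity, degenerate draws,
allocation exactness, closed-form tails) rather than by reproducing
published population means.

# Problem sizes and numerical choices

Default production sizes: residue fits 4 × 25,000 iterations (an option up
to 50,000); dose-response fits 3 × 50,000 with the last 25,000 per chain
retained; 100,000 model-averaged BMD draws in the reference-dose chain; the
test suite uses 4,000–15,000-iteration fits and populations of a few
thousand, sizes at which every posterior here is well mixed (R̂ < 1.01 for
the 2–4-parameter models). Calibration root-finding is to 1e-9; moment
round trips hold to 1e-9 relative; BMD closed forms match the numeric
root-finder to 1e-8. Per-stage seeds are derived deterministically from one
master seed and a stage label, so independent stages have independent
streams and reruns are bit-for-bit identical. Degenerate inputs are handled
explicitly: zero SD gives point masses (truncated normal, lognormal,
residue sampler), zero-slope curves return `NA` benchmark doses, empty draw
vectors raise errors.

# Known limitations

* The censored model assumes a single detection limit per category;
  interval-censored or multi-DL data are out of scope.
* Arithmetic-moment summaries (`mean_est`, `std_est`) of very heavily
  censored categories inherit the heavy right tail of the lognormal — the
  posterior-mean arithmetic mean can sit far above the posterior-median
  concentration. This is a property of the convention, not a bug, but users
  comparing to substitution estimators should compare full distributions.
* Posterior model weights are approximation-scheme dependent; the package's
  default reproduces the dimension-graded pattern of published analyses,
  but no locally computable scheme is guaranteed to match a specific web
  service's unpublished estimator exactly.
* The exposure model is chronic-average: no usual-intake modelling, no
  processing factors, no acute (within-day) assessment.
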