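---
title: "Model and methods: cost-effectiveness of sintilimab plus IBI305 versus sorafenib in unresectable HCC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decision problem

First-line sintilimab (a PD-1 inhibitor) combined with IBI305 (a
bevacizumab biosimilar) improves overall and progression-free survival
over sorafenib monotherapy in unresectable hepatocellular carcinoma, at
a substantially higher acquisition price. `hccea` implements the full
economic evaluation of that trade-off from the Chinese payer
perspective: a three-state Markov cohort model driven by parametric
survival extrapolation, evaluated at list prices and under Medicare
(national basic medical insurance) pricing, with one-way, threshold and
probabilistic sensitivity analyses. All monetary values are 2021 US
dollars (CNY 6.34/USD); the decision threshold is three times China's
2021 GDP per capita, $38,334 per quality-adjusted life year (QALY).

```{r}
library(hccea)
bundle <- load_config()      # packaged Table-1 inputs
run_scenarios(bundle)
```

## Survival model

Overall survival (OS) and progression-free survival (PFS) of each arm
are represented by parametric distributions from six candidate
families: exponential, Weibull, gamma, log-normal, log-logistic and
Gompertz (`surv_dist()`); time is measured in months throughout. The
packaged configuration carries the fitted curves directly:

| Arm | Endpoint | Family | Parameters | Median (months) |
|---|---|---|---|---|
| sintilimab + IBI305 | OS  | log-normal | meanlog 2.763, sdlog 0.971 | 15.8 |
| sintilimab + IBI305 | PFS | log-normal | meanlog 1.60, sdlog 1.03 | 5.0 |
| sorafenib | OS  | log-logistic | shape 1.68, scale 10.57 | 10.6 |
| sorafenib | PFS | log-normal | meanlog 1.115, sdlog 0.781 | 3.0 |

The implied medians reproduce the trial's reported medians, which fixes
the time unit as months. When users bring their own digitized
Kaplan-Meier coordinates, the fitting path is: repair the digitized
points (`clean_curve()`), reconstruct pseudo-individual patient data
against the numbers-at-risk table (`reconstruct_ipd()`, the Guyot
interval algorithm with deterministic uniform censoring placement, so
reconstruction needs no seed), fit all six families by right-censored
maximum likelihood (`fit_mle()`, backed by `flexsurv`), and rank by
AIC, then BIC, then canonical family order (`rank_fits()`).

```{r}
fit_table(fit_families(simulate_ipd(
  surv_dist("lognormal", meanlog = 1.60, sdlog = 1.03),
  n = 500, censoring = "administrative", t_max = 24, seed = 1)))
```

## Cohort model

Three states: stable disease (SD, progression-free on first-line
treatment), progressive disease (PD) and death. The whole cohort starts
in SD; progression is irreversible and death absorbing. Cycles are 21
days (0.6899 months at 30.4375 days/month); the horizon is 10 years,
giving `ceiling(120 / 0.6899) = 174` whole cycles.

Transition probabilities are time-dependent conditional-survival
ratios, `tp(t) = 1 - S(t)/S(t - u)` for the cycle ending at `t`
(`cycle_transition_prob()`), floored at zero, capped at one, and
absorbing once the curve's tail underflows (the denominator is clamped
at 1e-12).

The per-cycle matrix treats the two exits from SD as competing risks:

* SD → death with the OS conditional probability `tp_os`;
* SD → PD with `min(tp_pfs, 1 - tp_os)`;
* SD → SD with the remainder;
* PD → death with `tp_os`; PD → PD with `1 - tp_os`.

Because both alive states shed exactly `tp_os` to death each cycle, the
cohort's cumulative death fraction telescopes onto `1 - OS(t)` exactly
(this identity is asserted to 1e-10 in the test suite), so the model
never leaves the fitted OS curve no matter how the alive mass is split.
The split itself cannot be read off published survival curves; we chose
the competing-exits form over the partitioned-survival form
(`SD → PD = tp_pfs - tp_os`, which pins SD occupancy to the PFS curve)
because the published cost totals identify the discounted time spent in
SD — the difference between the list-price and insured-price totals of
an arm equals the per-cycle price difference times exactly that
quantity — and those implied values (10.1 cycles for the combination
arm, 4.4 for sorafenib) sit close to the competing-exits occupancy
(8.6 / 4.9) and far from the partitioned-survival one (11.6 / 5.9).
Under competing exits SD occupancy telescopes over
`1 - tp_os - min(tp_pfs, 1 - tp_os)`, which approximates the product
`PFS(t) · OS(t)` rather than `PFS(t)` alone.

### Costs, utilities, adverse events

While in SD the cohort pays drug acquisition (sintilimab + IBI305, or
sorafenib), administration (intravenous regimen only; oral sorafenib
carries none), follow-up ($59.20) and laboratory ($157.50) per cycle.
In PD both arms pay second-line regorafenib at its insured price
($800.28/cycle) plus follow-up and laboratory. The configuration
exposes a `subsequent_treatment` proportion per arm; the default is 1.0
for both arms — the uniform second-line assumption the source analysis
states it adopted to neutralize the asymmetric post-progression
treatment mix observed in the trial (the trial-reported uptakes, 29%
and 47%, remain available for scenario analysis by editing the YAML).
Back-solving the published totals supports the uniform reading: the
implied PD per-cycle outlay (~$950–985 in both arms) matches full-price
regorafenib plus disease management, not the proportion-weighted
variant (~$450–600).

Utilities are 0.76 (SD) and 0.68 (PD) QALY/year. Grade 3-4 adverse
events enter as one-time expected flows at model start:
`sum(incidence × cost)` and `sum(incidence × disutility)`. The arm
profiles follow the running-text incidences (combination: hypertension
14%, decreased platelet count 8%; sorafenib: palmar-plantar
erythrodysaesthesia 12%, hypertension 6%, decreased platelet count 3%),
the only AE set for which every event has a printed cost and
disutility. AEs are configuration data, so alternative mappings are a
YAML edit away.

### Discounting and half-cycle correction

Costs, QALYs and life-years are discounted at 5% per year with the
continuous-equivalent per-cycle factor `(1.05)^(-t/12)` (`t` in
months). With the half-cycle correction (default), cycle-`k` flows use
the mean of start- and end-of-cycle occupancy and are discounted at the
cycle midpoint — the trapezoid rule on the occupancy curves. Annual-step
discounting differs by under half a percent at this horizon.

## Sensitivity analyses

**One-way (tornado), `one_way()`.** Every cost, utility and
adverse-event input is varied by ±20% around base, one at a time, and
the ICER recomputed at each bound. The default set merges sintilimab
and IBI305 into a single regimen-cost parameter (scaled jointly via the
`costs.sb_drugs` binding), since the combination is priced as one
regimen; the probabilistic analysis samples them separately. Fitted
survival parameters carry no published ranges and are excluded from
both the tornado and the PSA — a known limitation: parameter
uncertainty in the extrapolated curves is not propagated.

**Threshold price reduction, `threshold_price_reduction()`.** Bisection
on a multiplier applied to the combination's drug-acquisition costs
until the ICER meets the willingness-to-pay threshold within $1/QALY;
reported as one minus the multiplier. A `scale = "all"` switch also
scales the administration cost.

**Probabilistic (PSA), `run_psa()`.** Each of the 20 ranged inputs is
sampled independently: gamma for costs, beta for probabilities and
utilities, beta on the magnitude (then negated) for disutilities, all
moment-matched to mean = base and sd = (high − low)/3.92, reading the
configured bounds as a 95% interval. Draws are generated
parameter-by-parameter in a documented fixed order from one seeded
stream, so runs are bit-reproducible. Because survival curves are fixed
across draws, state occupancy is identical for every draw; per-draw
totals are computed from each arm's precomputed discounted occupancy
accumulators, which is algebraically identical to re-running the cohort
per draw (asserted to 1e-9 in the tests) and makes 10,000 draws a
matter of seconds. `ceac()` and `ce_plane()` project the draws onto the
acceptability curve and the incremental cost-effectiveness plane.

## Synthetic data and what the tests show

No patient-level trial data are public, so the validation suite is
built on synthetic data: `simulate_ipd()` draws censored samples from
any of the six families by inverse-CDF sampling; `digitize_km()`
emulates manual curve extraction (points placed at evenly spaced
cumulative-drop quantiles — denser where the curve moves — with
optional truncated-Gaussian jitter on the survival axis);
`random_model_config()` generates valid random two-arm configurations
for property tests. Round-trip tests (simulate → KM → digitize →
reconstruct → refit) verify the reconstruction and fitting machinery:
exact recovery on uncensored step data, and a maximum KM deviation
under 0.02 for a 100-point noise-free digitization of a 500-patient
censored curve. With jitter of sd 0.01 the deviation is dominated by
the noise itself (≈ 0.02–0.03), which bounds what digitization-based
reproduction can promise about real extracted curves. The generators
emulate independent censoring and marginal curves only; they do not
reproduce patient-level PFS/OS correlation (the cohort model needs only
the marginals) or digitization biases that are systematic rather than
random (axis miscalibration).

## Numerical choices

* Survival tails are clamped at 1e-12 before division; exhausted curves
  make transitions absorbing rather than erroring.
* Bisection tolerances: $1/QALY for the threshold search (200-iteration
  cap); AIC ties broken by BIC, then by the fixed family order
  exponential < Weibull < gamma < log-normal < log-logistic < Gompertz.
* Maximum-likelihood fitting uses `flexsurv`'s deterministic
  data-derived starting values; no random restarts, so fits are
  reproducible without a seed. Zero event times (possible in digitized
  data) are nudged to half the smallest positive time before fitting.
* Beta moment-matching falls back to uniform(low, high) with a warning
  when the implied variance is infeasible on the unit interval.
* All inputs are carried at full printed precision (e.g. $1644.5916);
  rounding happens only at presentation.

## Reproduced results

With the packaged configuration the model reproduces the published
evaluation within the tolerances the conventions warrant (costs within
about 3%, QALYs within 0.05): combination-arm totals of roughly
$43.3k/1.28 QALYs versus $26.3k/0.92 QALYs at list prices (ICER ≈
$48.2k/QALY), $41.4k versus $23.2k under Medicare pricing (ICER ≈
$51.6k/QALY), a ~31% required price reduction at the threshold, and a
probability of cost-effectiveness at $38,334/QALY well under 2%. The
exact figures printed by the installed package are produced by
`run_scenarios()`, `threshold_price_reduction()` and `run_psa()` as
shown above, and by `scripts/acceptance.R` in the repository.

## Known limitations

* The transition split between progression and death from SD is a
  modelling choice constrained, but not uniquely determined, by the
  published totals.
* No distributional uncertainty on the fitted survival curves enters
  the sensitivity analyses.
* Second-line treatment is a uniform per-cycle cost while in PD; no
  treatment-duration caps or time-varying costs.
* The model works in 2021 USD; no re-inflation utilities are provided.
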