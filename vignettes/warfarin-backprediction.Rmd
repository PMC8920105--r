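---
title: "Back-predicting warfarin pharmacokinetics from routine INR monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Back-predicting warfarin pharmacokinetics from routine INR monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warfinr)
library(dplyr)
```

## The problem

Warfarin has a narrow therapeutic window and is monitored through the
prothrombin-time international normalized ratio (PT-INR), not through plasma
concentrations. Individual pharmacokinetic (PK) parameters — maximum
concentration $C_{max}$, elimination rate $k$, clearance $CL$ and volume of
distribution $V_d$ — are therefore rarely measured directly in routine care.
`warfinr` inverts a steady-state PK-PD model of the dose–INR relationship to
*back-predict* those parameters from nothing more than a patient's clinic
record: visit dates, INR values and prescribed maintenance doses. Around that
core it provides the standard anticoagulation-quality indices and a
cohort-level analysis (outlier classification, group comparisons,
correlations), plus a synthetic-cohort generator so the whole workflow is
testable end to end without patient data.

## The steady-state model

The model works on a transformed pharmacodynamic response

$$f(\mathrm{INR}) = b\,\mathrm{INR}^{p} - a,
\qquad a = 3.36,\; b = 4.368,\; p = 0.383,$$

a strictly increasing power law whose constants are fixed calibrated values
of the validated inbuilt model this package re-implements (`pd_constants()`
lets you override them, loudly). At steady state under repeated dosing of
$D$ mg every $\tau$ hours the transformed response satisfies

$$\frac{1}{f} \;=\; -\frac{m\,CL/V_d}{k^{2}}
\left(1-\frac{k\tau/24}{1-e^{-k\tau/24}}\right)
\;-\;\frac{m}{k}\,
\ln\!\frac{D/V_d}{C_{max}\left(1-e^{-(CL/V_d)\,\tau/24}\right)},$$

and the predicted INR is $f^{-1}$ applied to that value
(`steady_state_inr()`). The dosing interval is entered in hours and divided
by 24 throughout, which is the only unit convention consistent with $k$ in
day$^{-1}$ and $CL$ in L/day. Solving the same equation for $D$ gives a
closed-form maintenance-dose equation for a target INR
(`dose_for_target_inr()`); the two are exact algebraic inverses, which the
test suite verifies to $10^{-8}$ relative error on a thousand randomized
parameter sets.

Three numerical notes:

* The model's published concentration equation is character-for-character
  its INR equation, evidently a typesetting duplication; `steady_state_cs()`
  is therefore a documented alias of `steady_state_inr()` and no separate
  concentration formula is invented.
* The PD slope constant $m$ appears in the equations but has no published
  calibrated value. It defaults to $m = 1$; because the simulator and the
  estimator share the same $m$, every round-trip and recovery property holds
  for any positive value.
* The model is only physiologic on the dose branch where $1/f > 0$. Past
  that branch the reciprocal changes sign and, in a band of doses, $f$ falls
  below $-a$ where the inverse transform is undefined. All domain failures
  carry the name of the failing sub-expression (`log-argument`,
  `reciprocal`, `transform-offset`) so batch fitting can penalize rather
  than crash. Note also that $k$ is a first-order rate constant (day$^{-1}$)
  even where reports quote it with concentration-style units.

## MAP estimation and what is identifiable

`fit_individual()` recovers $\theta = (C_{max}, k, CL, V_d)$ by maximising a
normal posterior, equivalently minimising

$$\sum_j \frac{\big(f(\mathrm{INR}_j) - f_{pred,j}(\theta)\big)^2}{\sigma_{res}^2}
+ \sum_p \frac{(\theta_p-\mu_p)^2}{\sigma_p^2},$$

penalised nonlinear least squares on the transformed scale with independent
normal priors, the standard Bayesian-feedback formulation of therapeutic
drug monitoring. Residuals are modelled on the $f$ scale because the model
is linear in $\ln D$ there, which keeps them approximately homoscedastic;
the default residual SD $\sigma_{res} = 0.1$ corresponds roughly to a 5 %
INR assay CV at INR 2.5. The default priors are the population
distributions $C_{max}\,5.8\,(0.4)$ mg/L, $k\,1\,(0.1)$ day$^{-1}$,
$CL\,2.1\,(0.2)$ L/day, $V_d\,7.6\,(0.2)$ L.

The prior is not decoration. With all visits at one dosing interval the
dose-to-INR map has the form $1/f = \alpha - (m/k)\ln D$: the data identify
the slope $m/k$ and the intercept $\alpha$, and even with varying intervals
at most $\{k,\ CL/V_d,\ C_{max}V_d\}$ are identifiable. The transformation
$(C_{max}, CL, V_d) \to (cC_{max}, CL/c, V_d/c)$ leaves every prediction
unchanged — an exact likelihood ridge that only the prior resolves. Two
consequences shape the tests:

* *Noise-free closed loop.* Exact recovery of the full quadruple from
  noise-free data is only a well-posed demand when the prior is centred on
  the individual truth (the objective is then zero at truth and positive
  elsewhere). The closed-loop suite does exactly that and recovers every
  parameter to $10^{-4}$ relative.
* *Population recovery.* With the population prior, individual estimates are
  shrunk along the ridge, but because the synthetic truths are drawn from
  the same population, the shrinkage is unbiased at the cohort level: the
  cohort means of the estimates recover the population means to well within
  5 %, which is the headline experiment (220 patients, 8 visits, 5 % noise).

Optimisation is bounded quasi-Newton (`L-BFGS-B` with positivity boxes) from
three deterministic starts — prior mean, mean $+1$ SD, mean $-1$ SD — keeping
the best objective, first on ties. A line-search abort at an
already-optimal point (L-BFGS-B code 52) is accepted as converged when
another start corroborates the same objective or the numerical gradient has
vanished. Each fit reports the condition number of a finite-difference
Hessian at the optimum as a ridge-severity diagnostic. Visits with INR
outside (0.5, 10) or dose outside (0.5, 20] mg are screened out before
fitting as physiologically implausible; all remaining visits are used by
default, with `last_n` available to restrict to the most recent ones.

## Anticoagulation quality indices

* **WSI** — last observed INR divided by the dose (mg) recorded at that same
  final visit. "Last dose" is read as the per-administration dose at the
  final visit, not a weekly total. Low WSI suggests warfarin resistance.
* **TTR** — Rosendaal linear interpolation between consecutive INR
  measurements, reported as percent of monitored person-time inside the
  therapeutic range (default 2–3; 2.5–3.5 selectable for mechanical-valve
  indications). Inter-visit gaps over 56 days (configurable) are treated as
  unmonitored and excluded from both numerator and denominator. Control is
  classified good at TTR $\ge$ 65 % — the boundary value itself is good.
* **INR variability** — per consecutive pair,
  $v_i = (\Delta\mathrm{INR}_i)^2/\Delta t_i \cdot
  \overline{\mathrm{INR}}_i$; the statistic is
  $\sigma = \sqrt{\operatorname{mean}_i v_i}$ and its base-10 log is the
  log-INR variability. The aggregation order across pairs (average, then
  square root, then log) is a package decision where the verbal definition
  is ambiguous. A patient whose INR never changes has $\sigma = 0$; the log
  is returned as a flagged $-\infty$ sentinel and the patient is excluded
  from composite-measure standardisation with a warning rather than letting
  $-\infty$ poison the Z-scores.
* **WCM** — $z(\text{log-INR variability}) - z(\mathrm{TTR})$ with cohort
  Z-scores, so higher means worse control and the cohort mean is zero by
  construction. Published uses of the measure are ambiguous about both the
  combination and its direction, so the opposite sign convention is
  selectable (`convention = "higher_better"`); the default is documented
  rather than asserted as the original.
* **Liver weight** — $218 + 12.3\cdot\text{weight(kg)} + 51\cdot[\text{male}]$
  grams, an anthropometric regression used as a covariate for the
  correlation analysis.

## Cohort analysis

`classify_outliers()` fits a normal reference band per PK parameter and
flags patients outside mean $\pm\, z\,$SD with $z = 1.96$ (a 95 % band)
computed from the cohort being classified. The uniform rule is two-sided
for all four parameters; `sided = "lower"`/`"upper"` reproduces per-parameter
one-sided conventions where a report used them. Group comparisons use the
two-sided Mann-Whitney U test for numeric variables and the Pearson
chi-square test (no continuity correction) for categorical ones;
correlations are Pearson with two-sided p-values. No multiplicity
correction is applied to any decision, matching common practice for this
kind of descriptive cohort analysis, but a Holm-adjusted column is emitted
alongside every raw p-value. The age-stratified summary bins age at
65/75/85 by default (young, middle-aged and older, elderly, very elderly);
the boundaries are configurable because the conventional labels do not fix
them.

## The synthetic cohort: what it emulates and what it does not

`simulate_cohort()` generates the study conditions the analysis assumes:
220 patients; age 66.6 (13.4) years truncated at 18 and body weight 75.2
(18.1) kg truncated at 35 kg (adult anticoagulation clinic); 1:1
male:female; 61.8 % on potentially interacting co-medication; true PK
quadruples drawn from the population distributions above as
truncated-positive normals (lognormal selectable — the published summaries
do not fix the family). Each patient contributes 8 visits with uniform
20–40-day gaps, a total follow-up of roughly 200–300 days. Titration is
emulated by drawing a target INR from U(2, 3), redrawing it at each visit
with probability 0.3, prescribing the model-exact dose for the current
target rounded to 0.5 mg tablets, and observing the model INR at the
rounded dose under 5 % CV lognormal noise. The redraw probability and visit
structure are synthetic-only devices that create the within-patient dose
variation identifiability needs; the noise CV is an assumption (real INR
assay error structure is not reported) exposed in the config.

The generator deliberately does *not* emulate: adherence lapses, drug–drug
interaction effects on the PK truths, covariate dependence of parameters
(age, weight and co-medication are drawn independently of the PK truths),
pharmacogenomic strata, or non-steady-state excursions after dose changes.
Passing tests therefore demonstrate that the estimation machinery inverts
the model correctly under the model's own assumptions — not that the model
describes any particular real population. Consistently with that, the
simulated quality indices (WSI, log-INR variability) need not match
clinic-observed magnitudes, since those depend on behaviour the generator
does not model.

## Problem sizes and determinism

The package's standard experiments are sized for interactive use: the
headline recovery experiment uses the full 220-patient design (a few
seconds of fitting), the noise-free closed loop 20 patients, property
sweeps 50–1000 random draws, and Monte-Carlo checks of the outlier rule
$10^5$ draws. Every stochastic step runs through a single user-supplied
seed (`withr::with_seed`), and `run_pipeline()` with a fixed seed
regenerates its report bundle byte-identically, which the suite asserts
file by file.

## A short tour

```{r tour, eval = FALSE}
cfg <- pipeline_config(seed = 1, generator = cohort_config(n_patients = 50))
report <- run_pipeline(cfg, out_dir = "warfinr-report")
glance(report)                 # cohort means/SDs of parameters and indices
report$recovery                # estimates vs generator truth
glance(report$outliers$c_max)  # the 1.96-SD band and counts
autoplot(report)               # parameter histograms
```

## Known limitations

* Point (MAP) estimates only; no posterior sampling, so parameter
  uncertainty is summarised only through the prior/curvature diagnostic.
* The likelihood ridge means individual $C_{max}$, $CL$ and $V_d$ are
  prior-informed; treat individual values with care and cohort summaries as
  the reliable output.
* Steady-state only: visits shortly after a dose change violate the model's
  central assumption and are not detected automatically.
* No covariate adjustment of PK parameters and no enantiomer-specific
  (S-/R-warfarin) modelling.
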