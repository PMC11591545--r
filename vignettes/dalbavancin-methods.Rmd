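---
title: "Methods: population pharmacokinetics and dose-regimen simulation for long-interval dalbavancin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacokinetics and dose-regimen simulation for long-interval dalbavancin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Dalbavancin's terminal half-life of roughly two weeks makes it attractive for
long-term suppressive therapy of infections whose source cannot be removed,
such as ventricular assist device (VAD) driveline infections. Designing a
long-interval outpatient regimen requires three ingredients: a population
pharmacokinetic (PK) model of the drug in the target population, a
pharmacodynamic target linking free-drug exposure to effect against the
pathogen, and Monte Carlo simulation of candidate regimens against the
distribution of pathogen susceptibilities. `dalbapop` implements this whole
chain, together with a synthetic-cohort generator that makes every stage
testable without patient data.

## Structural model

Total serum concentrations follow a mammillary two-compartment model with
zero-order intravenous infusion input: clearance `CL` (L/h), central volume
`V1` (L), inter-compartmental clearance `Q` (L/h) and peripheral volume `V2`
(L). The micro constants are `k10 = CL/V1`, `k12 = Q/V1`, `k21 = Q/V2`; the
hybrid rate constants `alpha > beta` are the roots of
`s^2 - (k10+k12+k21)s + k10*k21 = 0`, computed with the numerically stable
form `beta = k10*k21/alpha`. Concentrations and AUCs are evaluated in closed
form — biexponential kinetics during and after each infusion, superposed over
all dose events — so population simulation and estimation share one exact,
fully vectorized code path. The test suite verifies the analytic solution
against high-accuracy ODE integration (relative error below 1e-6) and the
AUC against composite-trapezoid quadrature.

The shipped typical parameters for the VAD population are `CL = 0.050` L/h,
`V1 = 6.5` L, `Q = 0.476` L/h (fixed to a literature value rather than
estimated, because three samples per subject cannot inform four structural
parameters), and `V2 = 15.4` L, giving a terminal half-life of about 320 h
and a steady-state volume `V1 + V2 = 21.9` L.

`Q = 0` is accepted as an explicit one-compartment limit (the beta phase
coefficient is zeroed); it is used by the model-comparison harness and in
degenerate-limit tests, not as a production path. A three-compartment
structure is out of scope for estimation.

## Statistical model and estimation

Inter-individual variability (IIV) is log-normal: individual parameters are
`theta * exp(eta)` with `eta ~ N(0, omega^2)` independently per parameter.
The `omega` values are **standard deviations of the log-scale random
effects** (the Monolix/SAEM convention), not variances — misreading them as
variances would change every downstream number. The shipped values are
`omega_CL = 0.230`, `omega_V1 = 0.260`, `omega_V2 = 0.410`, with none on the
fixed `Q`. Residual error is proportional, `y = f(1 + b*eps)` with
`b = 0.100`; constant and combined error models are implemented for model
exploration but proportional is the default.

`fit_popmodel()` maximizes the marginal likelihood by SAEM. The E-step runs
a short Metropolis chain per subject (one independence kernel drawn from the
conditional prior plus two random-walk kernels whose scale is adapted toward
a 30% acceptance rate during burn-in); all subjects are updated in parallel
through the vectorized analytic model. The M-step updates fixed effects by
least squares on stochastically approximated sufficient statistics, which
makes covariate coefficients exact one-step updates. The schedule is 500
exploratory iterations (step size 1, with simulated annealing that lets the
variance components shrink by at most 5% per iteration) followed by 200
smoothing iterations with step size `1/k`; a relative-drift check over the
final iterations flags non-convergence as a warning on the returned object
rather than a silent success. Small floors on `omega` (1e-3) and `b` (1e-6)
keep the chain alive when a variance component collapses, e.g. in noise-free
degenerate tests. Subjects are internally ordered by subject ID, so
estimates are invariant to the row order of the input data, and all draws
derive from one seed argument.

Free structural parameters always carry IIV in this implementation; a
parameter can be removed from estimation entirely by fixing it (as `Q` is).
This matches the model actually used here and keeps the M-step closed-form.

Initial values default to published dalbavancin estimates from other
populations (CL 0.057 L/h, V1 10 L, V2 10 L) precisely so that recovery
experiments never start at the values the data were generated from.

### Likelihood, information criteria, standard errors

`log_likelihood()` estimates each subject's marginal likelihood by
importance sampling (default N = 10,000) around the empirical-Bayes
conditional distribution, with the proposal SD inflated by 1.3 and floored
at 10% of the prior SD to guard against collapsed conditionals; the Monte
Carlo SE of the OFV is reported. `AIC = OFV + 2P` and
`BIC = OFV + log(n_subjects) * P` count free typical values, covariate
coefficients, IIV SDs and error parameters — a fixed `Q` is excluded. The
suite checks the importance-sampling OFV against an 80-node Gauss–Hermite
quadrature on a one-random-effect toy (agreement well within 0.1).

`standard_errors()` differentiates a common-random-numbers version of the
importance-sampling OFV (same standard-normal draws reused at every
parameter displacement, so the objective is smooth) with central finite
differences (relative step 5e-3) to obtain the observed Fisher information;
positive parameters are differentiated on the log scale, which makes the
reported RSE (100·SE/estimate) invariant to unit rescaling. A singular
information matrix raises an error that recommends the bootstrap path.
`condition_ratio()` reports the max/min eigenvalue ratio of the estimate
correlation matrix as an overparameterization flag.

### BQL handling

Observations below the quantification limit (12.5 mg/L total, 1 mg/L
unbound) are replaced by QL/2 — an explicit, separate step
(`impute_bql()`) with a returned report, never an implicit part of the fit.
The strict rule is `dv < QL`; values exactly at the limit are kept. The
censored-likelihood (M3) treatment is deliberately out of scope to keep
results comparable with the QL/2 convention used for this drug's sparse
data. Note one arithmetic consequence: a recorded value *below QL/2* is
raised to QL/2 by this rule; that is inherent to the convention.

### Covariate search

Candidate effects (weight, BSA, age, CrCl, albumin) enter as power models on
the median-normalized covariate, `theta * (cov/median)^beta` — linear in
`beta` on the log scale, so the SAEM M-step stays closed-form. Forward
inclusion requires an OFV drop > 3.84 (chi-squared, 1 df, p < 0.05), backward
elimination retains an effect only if removal costs > 6.63 (p < 0.01); every
tested step is logged. All compared OFVs share one Monte Carlo seed so model
comparison is not polluted by independent sampling noise. The functional
form is this package's choice; the thresholds are the standard stepwise
values.

## Simulation, PTA and CFR

`sample_population()` draws virtual individuals from the population model
(10,000 by default in the acceptance analyses); per-task substreams are
derived deterministically from one master seed, so adding a regimen to an
analysis never perturbs another's draws.

The PK/PD index is the free AUC of the **last 24 h before redosing**
divided by MIC, a conservative choice for suppressive therapy because it
measures the trough of exposure. Targets for *S. aureus*: fAUC24/MIC
> 27.1 (stasis), > 53.3 (1-log kill), > 111.1 (2-log kill), with strict
inequality. Protein binding enters as a deterministic scalar per scenario
(93, 96, 97, 98, 99%): free = `(1 - pb/100) * total`. It is not a
per-individual random variable, mirroring the scenario-analysis design.

Steady state is approximated by explicitly simulating 6 cycles rather than
by closed-form accumulation, keeping one code path for irregular cycles
such as 1500 mg on day 1 + day 8 every 6 weeks. For regimens with several
doses per cycle the free tail AUC is evaluated before *every* scheduled
redosing of the evaluation cycle and the minimum is reported — the worst
interval governs, which is the conservative reading; for all six studied
regimens this coincides with the cycle-end interval. A `cycle` argument
reproduces first-course behaviour. Whether the original analysis evaluated
the first course or steady state is not stated; steady state is the default
here because accumulation is material at a 320-h half-life (it raises the
q3w tail AUC by roughly half), and it is the exposure a patient on
long-term therapy actually experiences.

Residual error is **not** applied inside PTA exposures — PTA uses
model-predicted individual profiles, the standard practice; noise is applied
only when emulating observations (synthetic cohorts, VPC).

PTA at MIC m is the percentage of individuals with `fAUC24/m > target`;
exposures are computed once per population and the threshold comparison is
vectorized over the MIC grid (EUCAST doubling dilutions 0.016–2 mg/L). CFR
weights the PTA curve by a MIC frequency distribution, with exact grid
matching (no interpolation; mismatches raise an error listing the missing
MICs). The packaged *S. aureus* distribution is a clearly labelled
synthetic snapshot shaped like the public wild-type distribution (mass at
0.03–0.06 mg/L, 6.6% at the 0.125 ECOFF); it is a configuration input read
from CSV, never hard-coded, and any current EUCAST export can be
substituted. PTA and CFR are "desirable" at >= 90%.

## The synthetic cohort generator

`generate_cohort()` emulates the study that motivated this package:

* 13 subjects, 1500 mg as a 0.5-h infusion on day 1 and day 8 of a 6-week
  cycle. Day *n* maps to start time `(n-1)*24` h. The infusion duration is
  not documented for the original cohort; 0.5 h is the default (consistent
  with sampling "30 min after the end of the infusion" for a short
  infusion) and is configurable.
* Exactly one engineered subject with CrCl < 30 mL/min receives the reduced
  1000 mg dose, mirroring the cohort's single renally impaired patient.
* Three samples per subject: end of infusion + 30 min on day 1 (t = 1 h),
  pre-dose trough on day 8 (t = 168 h, immediately before the second dose),
  and the pre-redosing trough at week 6 (t = 1008 h, immediately before the
  next cycle). The source description places the second dose on "day 8" but
  the trough on "day 7 before redosing"; these are reconciled as one
  instant, t = 168 h, sampled just before the infusion starts (a dose
  contributes nothing at its own start time, so no epsilon-offset is
  needed).
* Covariates are drawn from the cohort's demographic summaries: age
  ~ N(57, 9) truncated to 30–85 y, BSA ~ N(1.95, 0.17) on 1.4–2.6 m²,
  CrCl ~ N(90.8, 34.7) on 30–200 mL/min, albumin ~ N(42.5, 5.7) on
  25–60 mg/dL, and log-normal weight calibrated to median 76 kg with IQR
  20 kg. Truncation bounds are plausibility limits for an adult VAD cohort,
  chosen once. Covariates carry **no** effect on the PK parameters by
  default (the original analysis retained none); a covariate-effect mode
  exists solely to power the covariate-search tests.
* Protein binding is uniform per subject on 96–98%, the observed range;
  unbound observations are `(1-PB) * C` with their own error draw and QL of
  1 mg/L.
* Observations are `f * (1 + 0.1 * eps)`; values below QL are flagged, and
  imputation remains a separate explicit step. A missingness knob can drop
  one record at random to replicate the cohort's 38 (of 39 nominal)
  samples; it is off by default.

What this emulates well: the sparse design, the BQL burden (~11–14% of
total-concentration samples, concentrated at the week-6 trough), the
concentration scale at all three occasions, and the IIV structure. What it
does not emulate: deviations from nominal sampling times, inter-occasion
variability, assay error structure beyond the proportional model, and any
covariate–parameter relationship. Passing tests therefore demonstrate
internal consistency of the method chain under the stated design, not
clinical validity on new data.

## Diagnostics

* `gof()` reports R² of observed vs population predictions (random effects
  at zero) and vs individual (empirical Bayes) predictions.
* `vpc()` simulates replicate datasets at the observed design and applies
  the same QL censoring + QL/2 imputation as the analysis pipeline before
  computing percentile bands, so bands are comparable to observations near
  the 12.5 mg/L limit (at the week-6 trough the 10th percentile is
  typically pinned at 6.25 on both sides — informative in itself). Binning
  is by exact nominal time when the design has at most 10 distinct times,
  quantile bins otherwise.
* `bootstrap_fit()` resamples whole subjects (record-level resampling is
  invalid for sparse repeated measures), refits each replicate, and reports
  percentile CIs; failures are counted and a >20% failure rate attaches a
  quality warning.
* `shrinkage()` reports `100*(1 - SD(EBE eta)/omega)` per random effect.
  Because the EBE summaries come from a finite MCMC sample, mildly negative
  values can occur with informative data; strong sparsity (one sample per
  subject) drives shrinkage toward 100%.

## Numerical choices and degenerate inputs

* `expm1` is used for all `1 - exp(-x)` terms; repeated disposition roots
  (`alpha == beta`) are rejected rather than approximated (unreachable with
  strictly positive rates).
* Observation times before any dose of the same subject are a validation
  error, not a zero-likelihood surprise; doses after a subject's last
  sample are irrelevant to the likelihood and the generator truncates them.
* Problem sizes used by the checked analyses: 10,000 individuals per PTA
  scenario; 20 replicate 100-subject cohorts (SAEM schedule 300 + 150) for
  the recovery experiment; 500 generator seeds for the BQL-burden estimate;
  these sizes put the Monte Carlo error well inside the tolerances asserted
  about them.

## Known limitations

* The week-6 mean trough implied by the shipped model (~17 mg/L with QL/2
  imputation) sits above the observed cohort mean (13.2 ± 9.9 mg/L in 13
  patients) by more than the 20% band the package's acceptance analysis
  allows, and the corresponding check is expected to read red: with 13
  patients the observed mean has a standard error of ~2.8 mg/L, and the
  model — fitted to all three occasions jointly — over-predicts the sparsest,
  most censored time point. The package reports what the model implies
  rather than adjusting toward the observed figure.
* QL/2 imputation biases late-time information; the M3 censored likelihood
  would use it better but is out of scope by design.
* No inter-occasion variability, no omega covariances, no covariate effects
  in the shipped model; CFR results inherit whatever MIC snapshot the user
  supplies.
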