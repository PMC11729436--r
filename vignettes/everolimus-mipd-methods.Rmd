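---
title: "Methods: population pharmacokinetics and precision dosing of everolimus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacokinetics and precision dosing of everolimus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(everopk)
```

## The problem

Everolimus after liver transplantation is dosed to a narrow whole-blood
trough window (3–8 ng/mL): below it the graft is under-immunosuppressed,
above it toxicity accumulates. Exposure varies several-fold between
patients, and three routinely measured covariates explain a useful part of
that variation: serum albumin (ALB), body surface area (BSA) and the
co-administered tacrolimus trough (TAC). This package implements the full
quantitative chain for that problem: a population pharmacokinetic (PopPK)
model, its estimation from sparse trough-only data, model validation
(bootstrap, prediction-corrected VPC), and the dosing layer that turns the
model into per-patient maintenance-dose recommendations and a 12-cell
clinical nomogram.

## Structural and statistical model

Drug disposition is a one-compartment model with first-order absorption and
elimination. For a repeated oral dose $D$ every $\tau$ hours the trough at
steady state is

$$C_0 = \frac{D\,k_a}{(V/F)\,(k_a - k_e)}\left(
  \frac{e^{-k_e\tau}}{1-e^{-k_e\tau}} - \frac{e^{-k_a\tau}}{1-e^{-k_a\tau}}
  \right), \qquad k_e = \frac{CL/F}{V/F},$$

in ng/mL with doses in mg and volumes in L (1 mg/L = 1000 ng/mL).
Absorption is fixed at $k_a = 0.647\,\mathrm{h^{-1}}$ throughout: with
pre-dose troughs as the only observation type the data carry no information
about absorption, and `pk_model_spec(estimate_ka = TRUE)` is rejected as a
specification error. The closed form is singular at $k_a = k_e$
("flip-flop" kinetics); the package rejects parameter sets in that regime
with an explicit error rather than silently switching to the limit form.

Covariates act on the typical values as

$$CL/F = \theta_{CL}\,
  \left(\frac{ALB}{4.0}\right)^{0.122}
  \left(\frac{BSA}{1.7}\right)^{0.474}
  e^{-0.026\,(TAC - 6)}, \qquad
  V_d/F = \theta_{V}\left(\frac{ALB}{4.0}\right)^{0.101}.$$

Power forms on median-normalized ALB and BSA and an exponential form on
centred TAC are the package's own reconstruction — the source equations are
not machine-readable — chosen so that the TAC coefficient (−0.026 per
ng/mL) produces the clinically material dose separation between the TAC 6
and TAC 10 strata that a power form with the same printed coefficient could
not. All forms (power, exponential, additive) are available per covariate
through `cov_effect()`, so alternative reconstructions are one line away.
The reference values (ALB 4.0 g/dL, BSA 1.7 m², TAC 6 ng/mL) are the
"normal" scenario levels; they are fields of `pop_params()` and fully
configurable.

Between-subject variability is lognormal, $CL_i = CL\,e^{\eta_i}$ with
$\eta \sim N(0, \omega^2)$, reported as
$\%CV = 100\sqrt{e^{\omega^2}-1}$ (`cv_percent()`); the omega matrix is
diagonal by default with an optional CL–V covariance used by the simulation
side (`pop_params(omega_cl_v = ...)`) — the estimation side keeps it fixed
at zero. Residual error is proportional, observed $= f\,(1+\varepsilon)$,
$\varepsilon \sim N(0, \sigma^2)$, and simulated concentrations are floored
at 0.01 ng/mL as a stand-in for the assay's lower limit of quantification.

Two packaged parameter sets reproduce the reported estimates: the default
(`pop_params()`, the refined estimates: CL/F 15.0 L/h, Vd/F 862 L,
$\omega^2$ 0.127/0.743, $\sigma^2$ 0.242) and
`pop_params_retrospective()` (the retrospective-only stage). Both also ship
as flat key–value files under `inst/extdata/`.

## Estimation

`fit_population()` maximizes the marginal likelihood of a
`pk_dataset` — NONMEM-style event records with dose rows (optionally
steady-state `SS`/`II` records) and trough observations. Internally every
observation's prediction is decomposed into *dose trains*: maximal runs of
equal doses at equal spacing, whose superposition has a geometric-series
closed form. A months-long q12h history therefore costs one term per
observation, and a steady-state record is just the $m \to \infty$ limit of
the same formula.

The per-subject integral over $(\eta_{CL}, \eta_V)$ is approximated by a
Laplace-type expansion at the conditional mode, with "interaction" (the
residual SD follows the individual prediction). Three numerical layers
matter:

* **Conditional modes** are found by a damped Newton search run
  simultaneously for all subjects (analytic gradients; Hessians from
  central differences of the gradient), to a gradient tolerance of 1e-8
  within at most 100 iterations.
* **Higher-order correction.** The volume random effect is wide
  ($\omega^2_V = 0.743$) and weakly identified by troughs, so the
  conditional posteriors are visibly non-Gaussian and the classical
  second-order Laplace value is off by ~0.05 units per subject. The package
  therefore adds the standard fourth-order correction assembled from the
  third- and fourth-derivative tensors at the mode.
* **Quadrature fallback.** The size of that correction is itself a
  diagnostic of expansion validity. Subjects whose correction exceeds 0.05
  log-units are integrated by adaptive Gauss–Hermite quadrature instead
  (9 nodes per dimension), with a smooth blend over corrections in
  [0.05, 0.10] so the objective stays continuous in the parameters.
  `neg2_loglik_agq()` (31+ nodes) provides the independent reference; the
  test suite keeps the default objective within 0.1 of it on the packaged
  5-subject cohort.

The outer problem optimizes typical values, covariate coefficients and
variances with `nlminb` (positive parameters log-transformed, relative
tolerance 1e-6 — below that the quadrature switching noise dominates, and a
tighter setting only produces spurious "false convergence" reports). The
variance components are kept above a floor of 1e-4 (a 1% CV): below it a
variance is indistinguishable from zero for these designs and the
log-scale search otherwise crawls toward minus infinity. When `nlminb`
stops with a "false convergence" code the fit is restarted from its
stopping point (up to three times) and declared converged once a restart
can no longer improve the objective by 0.1 units.
Because trough-only designs can carry distinct local optima in the volume
direction, the default start is a short multistart: clearance is moment-matched
from the observed troughs ($C_{avg} \approx 1000\,D/(\tau\,CL)$), and three
pilot fits seeded at elimination half-lives spanning 7 h to 3 days pick the
basin for the final run. The pilots run on the cheap classical-Laplace
surface, but the basins they reach are ranked by the full objective — the
two surfaces share basins yet can order them differently, and ranking on
the cheap one selects a volume-collapsed optimum on some datasets. Standard errors come from the central-difference
Hessian of the objective (relative step 1e-4) mapped back by the delta
method; `eta_shrinkage()` reports $100(1 - SD(\hat\eta)/\omega)$.

Stepwise covariate modeling (`scm()`) is the conventional greedy procedure:
forward inclusion at $\Delta OFV > 3.84$ (the 1-df $\chi^2$ value at
p = 0.05, computed by `scm_threshold()`, never hard-coded), backward
elimination retaining only effects whose removal costs more than 6.63
(p = 0.01). Ties between candidates are resolved by declaration order;
failed inner fits are recorded in the trace and never silently accepted.
`correlation_prune()` drops one member of every covariate pair with
$|r| > 0.7$ before screening, preferring the clinically reported choices
(BSA over weight, albumin over total protein); `genotype_coding()` maps
minor-allele copy counts to dominant/recessive/additive columns, and
`hwe_chi_square()` excludes variants off Hardy–Weinberg equilibrium
(p ≤ 0.05).

## Validation layer

`pk_bootstrap()` resamples subjects with replacement, refits (initialized
at the original estimates), and reports medians with 5th/95th percentiles;
replicates that fail are excluded and counted, and more than 20% failures
flags the result unreliable. `vpc()` simulates replicate datasets under the
original design and prediction-corrects both sides by the bin-median
population prediction. Binning defaults to eight equal-count bins; for
trough-only data every observation shares the same time-after-dose, so the
informative axis is time since first dose (`bin_on = "time"`), and the
binning collapses gracefully to the distinct values when there are fewer
than requested. `gof_table()` gives population/individual predictions and
(individual-)weighted residuals under the proportional-error model.

## The synthetic cohort generator

`cohort_config()` + `generate_dataset()` emulate the study population the
analysis assumes: ALB $\sim$ truncated-normal(3.89, 0.50) g/dL, BSA
$\sim$ truncated-normal(1.7, 0.1) m², and TAC from a lognormal
moment-matched to 8.29 ± 9.80 ng/mL and truncated at 30 ng/mL — a printed
SD larger than the mean implies strong right skew, and the truncation
removes physiologically absurd tails. Doses are q12h from the 0.25–2.5 mg
grid in 0.25 mg steps, constant within subject; covariates are
time-constant per subject (the simplest structure consistent with
trough-visit data). Troughs are pre-dose samples on a twice-weekly visit
schedule (3.5-day spacing) — the real outpatient schedule is not described
beyond "visits", so this stand-in is a package choice.

Two sampling encodings are provided. The default writes steady-state dose
records with troughs from day 14 (past eight elimination half-lives at the
typical parameters), which is compact and fast. For estimation studies of
the *volume* parameter this encoding is deliberately avoided: when every
trough sits exactly at steady state of a single regimen, each subject
contributes essentially one information point and $V_d/F$ collapses onto a
likelihood ridge (the fitted $\omega_V$ then shrinks toward zero — visible
as near-100% volume shrinkage). With `first_trough_day = 4` and explicit
dose rows (`ss_records = FALSE`) the first visits fall in the accumulation
phase, as they do in real therapeutic drug monitoring where sampling starts
within the first week, and the approach to steady state identifies $k_e$
and hence the volume. The parameter-recovery experiments use exactly that
design.

What passing tests on these cohorts do **not** show: robustness to
dropout, dose titration records, time-varying covariates, assay switches
mid-study, or model misspecification — the generator simulates the fitted
model's own structure, so recovery tests measure estimator quality, not
model correctness on real data.

## Dosing layer

`simulate_scenario()` draws virtual subjects at fixed covariates and
returns steady-state troughs; residual (assay) error is excluded by default
because target attainment is about true exposure, not measurement noise
(switchable). `recommend_dose()` picks from the candidate set
{1.0, 1.25, 1.5, 1.75} mg by maximizing the simulated probability that
$3 \le C_0 \le 8$ ng/mL, ties to the lower dose; the reported dose table
includes 1.75 mg even though the scenario text lists three doses, so the
candidate grid keeps it. Since troughs are linear in dose, one set of
$\eta$ draws prices all candidates (common random numbers), which makes the
recommendation deterministic given a seed and stabilizes between-cell
contrasts. A deterministic alternative rule ("midpoint": typical trough
closest to 5.5 ng/mL) is provided because the original selection rule is
not stated and the two rules can disagree. `build_nomogram()` evaluates the
rule at representative covariates per clinical stratum (scenario levels for
open-ended strata, the interval midpoint 1.75 m² for the middle BSA band)
and asserts, on every build, that the dose is non-decreasing in BSA and
ALB and non-increasing in TAC.

A known limitation worth stating plainly: with the reconstructed covariate
coefficients, typical clearance varies only ~±15% across the 12 strata
while the candidate doses step by 25%, so under either packaged rule many
strata share the same recommended dose and the table is much flatter than
the reported one (which spans 1–1.75 mg). The package asserts the
qualitative properties (dose band and monotonicity) and reports the
cell-by-cell table as a diagnostic, not as a reproduction — reproducing the
exact cells would require the original study's unreported selection rule and
functional forms.

## Problem sizes and numerical choices used by the tests

The parameter-recovery experiment (also run by `scripts/acceptance.R`)
simulates five independent cohorts of 100 subjects × 8 troughs and refits
each from scratch, reporting the median recovered CL/F and Vd/F; clearance
is expected within 10% and volume within 25% in at least four of five
seeds (volume is weakly identified from troughs, which the source data's
own 9.2% RSE from richer data reflects). Bootstrap tests use 25 replicates
on 15-subject cohorts with the covariate-free model; VPC tests use 200
simulations over 4 bins; the stepwise-selection study uses 30 subjects × 3
troughs with a deliberately strong albumin effect and two seeds. These
sizes are the package's chosen compromise between Monte-Carlo resolution
and a test suite that runs in minutes; all of them scale up through the
same interfaces.

## Other limitations

* Two-compartment disposition, zero-order or lagged absorption and
  nonlinear elimination are out of scope (the one-compartment form was the
  selected structure; `aic()` supports ranking alternatives, but no
  alternative structure ships).
* Bioavailability $F$ is not separable from trough-only oral data; all
  parameters are apparent (CL/F, V/F).
* Assay harmonization (`assay_harmonize()`) defaults to the identity
  because published immunoassay↔LC-MS/MS conversion coefficients are
  laboratory-specific; users must supply their own slope/intercept.
* Individual Bayesian dose adaptation from observed troughs (posterior
  updating) is a natural extension and deliberately not included.
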