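# everopk

Population pharmacokinetics and model-informed precision dosing (MIPD) of
everolimus in adult liver-transplant recipients.

Everolimus is titrated to a whole-blood trough window of 3–8 ng/mL.
`everopk` implements the quantitative chain behind that titration:

* a one-compartment oral PK model with first-order absorption
  (ka fixed at 0.647 h⁻¹) and covariate effects of serum albumin, body
  surface area and the tacrolimus trough on apparent clearance and volume:

  CL/F = 15.0 · (ALB/4.0)^0.122 · (BSA/1.7)^0.474 · e^(−0.026·(TAC−6)) L/h,
  V/F = 862 · (ALB/4.0)^0.101 L,

  with lognormal between-subject variability (ω² 0.127 on CL, 0.743 on V)
  and proportional residual error (σ² 0.242);
* maximum marginal-likelihood estimation from sparse, trough-only datasets
  (NONMEM-style event records), using a higher-order Laplace approximation
  with interaction and an adaptive Gauss–Hermite cross-check;
* stepwise covariate modeling (ΔOFV thresholds 3.84 forward / 6.63
  backward), correlation pruning, genotype coding and a Hardy–Weinberg
  screen;
* nonparametric bootstrap, prediction-corrected visual predictive checks
  and goodness-of-fit tables;
* Monte-Carlo scenario simulation, probability of target attainment,
  per-patient dose recommendation from the {1, 1.25, 1.5, 1.75} mg q12h
  candidate set, and a 12-cell covariate-stratified nomogram;
* a synthetic liver-transplant cohort generator so the whole pipeline runs
  and is tested without patient data.

See `vignettes/everolimus-mipd-methods.Rmd` for the model, the numerical
methods and the design decisions.

## Worked example

```r
library(everopk)

pop <- pop_params()            # refined population estimates
pop$cl_pop
#> [1] 15
cv_percent(pop$omega2_cl)      # between-subject CV of clearance
#> [1] 36.79905

## typical steady-state trough of 1 mg q12h at the reference covariates
ind <- list(cl = 15, v = 862, ka = 0.647)
steady_state_trough(1, 12, ind)
#> [1] 5.13325

## simulate a 20-subject virtual cohort and refit it
d <- generate_dataset(cohort_config(n = 20, n_troughs = 6,
                                    first_trough_day = 4,
                                    ss_records = FALSE),
                      pop, seed = 1)
fit <- fit_population(d, compute_se = FALSE)
round(fit$estimates[c("cl_pop", "v_pop")], 1)
#> cl_pop  v_pop 
#>   16.9 1167.4

## dose recommendation for one patient
rec <- recommend_dose(patient_covariates(alb = 4.0, bsa = 2.0, tac = 6),
                      pop, seed = 3)
as.numeric(rec)
#> [1] 1
```

The first number is the typical trough the model predicts for a reference
patient on 1 mg twice daily (about 5.1 ng/mL, mid-window). The refit
recovers the generating clearance within ~13% and the (weakly identified)
volume within ~35% from this deliberately small 20-subject cohort — the
full recovery experiment behind `scripts/acceptance.R` uses five
100-subject cohorts, where the median recovered CL/F lands within a few
percent of the generating 15 L/h. The recommendation is the candidate dose
with the highest simulated probability of a 3–8 ng/mL trough for that
covariate profile.

A command-line wrapper ships in `inst/cli/everopk`:

```sh
Rscript inst/cli/everopk recommend --alb 4.0 --height 170 --weight 70 --tac 6
Rscript inst/cli/everopk nomogram --seed 1 --out nomogram.csv
```

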