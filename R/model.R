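#' Patient covariates
#'
#' Covariate values for one or more subjects: serum albumin (g/dL), body
#' surface area (m^2) and the concurrent tacrolimus trough concentration
#' (ng/mL). Extra screening covariates may be supplied as additional columns.
#'
#' @param alb Serum albumin, g/dL (> 0).
#' @param bsa Body surface area, m^2 (> 0).
#' @param tac Tacrolimus trough, ng/mL (>= 0; 0 means no co-administration).
#' @param ... Further equal-length covariate vectors, kept by name.
#' @return A data frame of class `patient_covariates`.
#' @export
patient_covariates <- function(alb, bsa, tac, ...) {
  d <- data.frame(alb = alb, bsa = bsa, tac = tac, ...)
  validate_covariates(d)
  class(d) <- c("patient_covariates", "data.frame")
  d
}

validate_covariates <- function(d) {
  for (nm in c("alb", "bsa", "tac")) {
    if (is.null(d[[nm]]) || anyNA(d[[nm]]))
      stop("covariate '", nm, "' is missing", call. = FALSE)
  }
  if (any(d$alb <= 0)) stop("'alb' must be positive", call. = FALSE)
  if (any(d$bsa <= 0)) stop("'bsa' must be positive", call. = FALSE)
  if (any(d$tac < 0)) stop("'tac' must be non-negative", call. = FALSE)
  invisible(d)
}

#' Repeated oral dosing regimen
#'
#' @param dose Dose amount, mg (> 0).
#' @param tau Dosing interval, h (> 0); the default 12 h is the twice-daily
#'   schedule used clinically.
#' @param n_doses Number of administered doses, or `Inf` for steady state.
#' @return A list of class `dosing_regimen`.
#' @export
dosing_regimen <- function(dose, tau = 12, n_doses = Inf) {
  stopifnot(is.numeric(dose), length(dose) == 1L, dose > 0,
            is.numeric(tau), length(tau) == 1L, tau > 0)
  if (!identical(n_doses, Inf) && (n_doses < 1 || n_doses != round(n_doses)))
    stop("'n_doses' must be a positive integer or Inf", call. = FALSE)
  structure(list(dose = dose, tau = tau, n_doses = n_doses),
            class = "dosing_regimen")
}

#' Typical (population-predicted) apparent clearance
#'
#' Covariate model for CL/F: power functions of albumin and body surface
#' area normalized to reference values, and an exponential effect of the
#' tacrolimus trough centred at the reference trough. Higher albumin or BSA
#' increases clearance (hence lower troughs at the same dose); higher
#' tacrolimus exposure decreases it.
#'
#' @param cov A `patient_covariates` object or data frame with columns
#'   `alb`, `bsa`, `tac` (vectorized over rows).
#' @param pop A [pop_params()] object.
#' @return Typical CL/F in L/h, one value per subject.
#' @examples
#' typical_clearance(patient_covariates(4, 2.1, 6), pop_params())
#' @export
typical_clearance <- function(cov, pop) {
  stopifnot(inherits(pop, "pop_params"))
  validate_covariates(cov)
  pop$cl_pop *
    (cov$alb / pop$ref_alb)^pop$theta_cl_alb *
    (cov$bsa / pop$ref_bsa)^pop$theta_cl_bsa *
    exp(pop$theta_cl_tac * (cov$tac - pop$ref_tac))
}

#' Typical apparent volume of distribution
#'
#' Vd/F with a power effect of albumin normalized to the reference value.
#'
#' @inheritParams typical_clearance
#' @return Typical Vd/F in L, one value per subject.
#' @export
typical_volume <- function(cov, pop) {
  stopifnot(inherits(pop, "pop_params"))
  validate_covariates(cov)
  pop$v_pop * (cov$alb / pop$ref_alb)^pop$theta_v_alb
}

#' Draw individual parameters with lognormal interindividual variability
#'
#' Individual CL/F and Vd/F are the typical values multiplied by
#' \eqn{e^{\eta}} with \eqn{\eta \sim N(0, \Omega)}; the absorption rate
#' constant carries no random effect. One subject is drawn per row of `cov`.
#'
#' @inheritParams typical_clearance
#' @param seed Optional integer seed; when given the draw is reproducible and
#'   the caller's RNG state is untouched.
#' @return A data frame with columns `cl`, `v`, `ka`, `eta_cl`, `eta_v`.
#' @export
sample_individual <- function(cov, pop, seed = NULL) {
  stopifnot(inherits(pop, "pop_params"))
  validate_covariates(cov)
  n <- nrow(as.data.frame(cov))
  tcl <- typical_clearance(cov, pop)
  tv <- typical_volume(cov, pop)
  draw <- function() {
    if (pop$omega_cl_v != 0 && pop$omega2_cl > 0 && pop$omega2_v > 0) {
      # bivariate normal via Cholesky of the 2x2 omega matrix
      l11 <- sqrt(pop$omega2_cl)
      l21 <- pop$omega_cl_v / l11
      l22 <- sqrt(pop$omega2_v - l21^2)
      z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
      list(eta_cl = l11 * z1, eta_v = l21 * z1 + l22 * z2)
    } else {
      list(eta_cl = stats::rnorm(n, 0, sqrt(pop$omega2_cl)),
           eta_v = stats::rnorm(n, 0, sqrt(pop$omega2_v)))
    }
  }
  draw_valid <- function() {
    eta <- draw()
    ## the fixed-ka closed form needs ke < ka; redraw the (roughly 1 in
    ## 20,000 at the default variances) tail draws that would violate it
    for (tries in 1:100) {
      ke <- tcl * exp(eta$eta_cl) / (tv * exp(eta$eta_v))
      bad <- ke >= 0.95 * pop$ka
      if (!any(bad)) break
      redraw <- draw()
      eta$eta_cl[bad] <- redraw$eta_cl[bad]
      eta$eta_v[bad] <- redraw$eta_v[bad]
    }
    eta
  }
  eta <- if (is.null(seed)) draw_valid() else withr::with_seed(seed, draw_valid())
  data.frame(cl = tcl * exp(eta$eta_cl), v = tv * exp(eta$eta_v),
             ka = pop$ka, eta_cl = eta$eta_cl, eta_v = eta$eta_v)
}

## concentration (ng/mL) at `dt` hours after one oral `amt` mg dose;
## ii = Inf for a single dose, finite ii adds the steady-state accumulation
## of a repeated q`ii` regimen. 1 mg/L = 1000 ng/mL.
conc_one_dose <- function(amt, dt, ii, cl, v, ka) {
  n <- max(length(amt), length(dt), length(ii), length(cl), length(v),
           length(ka))
  amt <- rep_len(amt, n); dt <- rep_len(dt, n); ii <- rep_len(ii, n)
  cl <- rep_len(cl, n); v <- rep_len(v, n); ka <- rep_len(ka, n)
  ke <- cl / v
  if (any(ka - ke <= 0))
    stop("absorption rate constant must exceed the elimination rate ",
         "(ka > CL/V); the closed form is singular at ka = ke", call. = FALSE)
  acc_ke <- ifelse(is.finite(ii), 1 - exp(-ke * ii), 1)
  acc_ka <- ifelse(is.finite(ii), 1 - exp(-ka * ii), 1)
  out <- 1000 * amt * ka / (v * (ka - ke)) *
    (exp(-ke * dt) / acc_ke - exp(-ka * dt) / acc_ka)
  out[dt < 0] <- 0
  out
}

#' Concentration-time profile under repeated oral dosing
#'
#' Superposition of the one-compartment first-order absorption/elimination
#' closed form
#' \deqn{C(t) = \frac{D k_a}{(V/F)(k_a - k_e)}\left(e^{-k_e t} - e^{-k_a t}\right)}
#' over the doses of `regimen` given at 0, tau, 2 tau, ... Concentrations are
#' returned in ng/mL (doses in mg, volume in L; 1 mg/L = 1000 ng/mL).
#'
#' @param times Times since the first dose, h (>= 0).
#' @param regimen A [dosing_regimen()]; `n_doses = Inf` uses the steady-state
#'   closed form directly.
#' @param ind Individual parameters: any list/data frame with elements
#'   `cl` (L/h), `v` (L) and `ka` (1/h), e.g. a row of [sample_individual()].
#' @return Concentrations in ng/mL at `times`.
#' @export
concentration_profile <- function(times, regimen, ind) {
  stopifnot(inherits(regimen, "dosing_regimen"))
  if (any(times < 0)) stop("'times' must be non-negative", call. = FALSE)
  cl <- ind$cl[1]; v <- ind$v[1]; ka <- ind$ka[1]
  stopifnot(cl > 0, v > 0, ka > 0)
  if (identical(regimen$n_doses, Inf)) {
    # time within the steady-state interval
    dt <- times %% regimen$tau
    return(conc_one_dose(regimen$dose, dt, regimen$tau, cl, v, ka))
  }
  dose_times <- seq(0, by = regimen$tau, length.out = regimen$n_doses)
  sapply(times, function(t) {
    dt <- t - dose_times
    sum(conc_one_dose(regimen$dose, dt[dt >= 0], Inf, cl, v, ka))
  })
}

#' Steady-state trough concentration of a repeated oral regimen
#'
#' Closed-form pre-dose (trough) concentration at steady state of a dose `D`
#' every `tau` hours:
#' \deqn{C_0 = \frac{D k_a}{(V/F)(k_a - k_e)}\left(
#'   \frac{e^{-k_e \tau}}{1 - e^{-k_e \tau}} -
#'   \frac{e^{-k_a \tau}}{1 - e^{-k_a \tau}}\right)}
#' Linear in dose; decreasing in clearance at fixed volume.
#'
#' @param dose Dose, mg.
#' @param tau Dosing interval, h.
#' @param ind Individual parameters (`cl`, `v`, `ka`); vectorized over
#'   subjects.
#' @return Trough concentration(s), ng/mL.
#' @examples
#' steady_state_trough(1, 12, list(cl = 15, v = 862, ka = 0.647)) # ~5.13
#' @export
steady_state_trough <- function(dose, tau, ind) {
  stopifnot(all(dose > 0), all(tau > 0))
  conc_one_dose(dose, tau, tau, ind$cl, ind$v, ind$ka)
}

#' Apply proportional residual error to a model prediction
#'
#' Observed = predicted * (1 + eps), eps ~ N(0, sigma2). Realizations below
#' `floor` (a surrogate for the assay's lower limit of quantification) are
#' set to `floor`.
#'
#' @param conc Model-predicted concentration(s), ng/mL.
#' @param sigma2 Proportional error variance (>= 0).
#' @param seed Optional integer seed for reproducibility.
#' @param floor Lower bound applied to the noisy values, ng/mL.
#' @return Simulated observed concentrations.
#' @export
add_residual <- function(conc, sigma2, seed = NULL, floor = 0.01) {
  stopifnot(all(conc >= 0), sigma2 >= 0, floor > 0)
  draw <- function() stats::rnorm(length(conc), 0, sqrt(sigma2))
  eps <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  pmax(conc * (1 + eps), floor)
}

#' Body surface area from height and weight (Du Bois formula)
#'
#' \eqn{BSA = 0.007184 \, W^{0.425} H^{0.725}} with weight in kg and height
#' in cm; coefficients are configurable should another formula be preferred.
#'
#' @param height Height, cm (> 0).
#' @param weight Weight, kg (> 0).
#' @param coef,exp_weight,exp_height Formula constants.
#' @return Body surface area, m^2.
#' @export
bsa_du_bois <- function(height, weight, coef = 0.007184,
                        exp_weight = 0.425, exp_height = 0.725) {
  if (any(height <= 0)) stop("'height' must be positive", call. = FALSE)
  if (any(weight <= 0)) stop("'weight' must be positive", call. = FALSE)
  coef * weight^exp_weight * height^exp_height
}
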