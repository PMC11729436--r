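#' Covariate effect declaration for model building
#'
#' Declares one covariate-parameter relationship for estimation or stepwise
#' screening. Continuous covariates are centred on a reference value
#' (`x/ref` for the power form, `x - ref` for the exponential and additive
#' forms); the reference defaults to the dataset median at estimation time
#' unless fixed in the model specification.
#'
#' Forms, with `TV0` the typical value before the effect:
#' \describe{
#'   \item{power}{`TV = TV0 * (x/ref)^theta`}
#'   \item{exponential}{`TV = TV0 * exp(theta * (x - ref))`}
#'   \item{additive}{`TV = TV0 + theta * (x - ref)` (applied to the base
#'     typical value before multiplicative effects)}
#' }
#'
#' @param param `"cl"` or `"v"`: which structural parameter the covariate
#'   acts on.
#' @param covariate Covariate name; `"alb"`, `"bsa"`, `"tac"` map to the
#'   ALB/BSA/TAC dataset columns, anything else to a column of that name.
#' @param form Functional form.
#' @return A list of class `cov_effect`.
#' @export
cov_effect <- function(param = c("cl", "v"), covariate,
                       form = c("power", "exponential", "additive")) {
  param <- match.arg(param)
  form <- match.arg(form)
  stopifnot(is.character(covariate), length(covariate) == 1L)
  structure(list(param = param, covariate = tolower(covariate), form = form),
            class = "cov_effect")
}

#' Model specification for population fitting
#'
#' Describes the model to be estimated: the (fixed) absorption rate
#' constant, the covariate effects carried on clearance and volume, and the
#' normalization references. The absorption rate constant is always fixed:
#' trough-only sampling carries no information on absorption, so attempting
#' to estimate it is a specification error.
#'
#' @param covariate_effects List of [cov_effect()] entries. The default is
#'   the final everolimus covariate model: albumin and body surface area as
#'   power effects and the tacrolimus trough as an exponential effect on
#'   CL/F, and albumin as a power effect on Vd/F.
#' @param ka Fixed absorption rate constant, 1/h.
#' @param estimate_ka Must be `FALSE`; `TRUE` raises an error.
#' @param refs Named numeric vector of reference covariate values; anything
#'   not named here uses the median of the covariate over the dataset's
#'   observation rows.
#' @return An object of class `pk_model_spec`.
#' @export
pk_model_spec <- function(covariate_effects = list(
                            cov_effect("cl", "alb", "power"),
                            cov_effect("cl", "bsa", "power"),
                            cov_effect("cl", "tac", "exponential"),
                            cov_effect("v", "alb", "power")),
                          ka = 0.647,
                          estimate_ka = FALSE,
                          refs = c(alb = 4.0, bsa = 1.7, tac = 6.0)) {
  if (isTRUE(estimate_ka))
    stop("ka cannot be estimated from trough-only data; it must stay fixed",
         call. = FALSE)
  stopifnot(is.numeric(ka), length(ka) == 1L, ka > 0)
  if (!all(vapply(covariate_effects, inherits, TRUE, "cov_effect")))
    stop("'covariate_effects' must be a list of cov_effect() entries",
         call. = FALSE)
  labs <- vapply(covariate_effects, effect_label, "")
  if (anyDuplicated(labs))
    stop("duplicate covariate effect: ", labs[duplicated(labs)][1],
         call. = FALSE)
  structure(list(covariate_effects = covariate_effects, ka = ka, refs = refs),
            class = "pk_model_spec")
}

effect_label <- function(e) paste(e$param, e$covariate, e$form, sep = "_")

## spec with one effect added / removed (used by stepwise covariate modeling)
spec_add <- function(spec, effect) {
  spec$covariate_effects <- c(spec$covariate_effects, list(effect))
  spec
}
spec_drop <- function(spec, label) {
  keep <- vapply(spec$covariate_effects, effect_label, "") != label
  spec$covariate_effects <- spec$covariate_effects[keep]
  spec
}

## canonical spec implied by a pop_params object
spec_from_pop <- function(pop) {
  pk_model_spec(ka = pop$ka,
                refs = c(alb = pop$ref_alb, bsa = pop$ref_bsa,
                         tac = pop$ref_tac))
}

## named theta vector of a pop_params object for the canonical spec
theta_from_pop <- function(pop) {
  c(cl_pop = pop$cl_pop, v_pop = pop$v_pop,
    cl_alb_power = pop$theta_cl_alb, cl_bsa_power = pop$theta_cl_bsa,
    cl_tac_exponential = pop$theta_cl_tac, v_alb_power = pop$theta_v_alb,
    omega2_cl = pop$omega2_cl, omega2_v = pop$omega2_v,
    sigma2_prop = pop$sigma2_prop)
}
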