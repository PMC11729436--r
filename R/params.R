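#' Population pharmacokinetic parameter set
#'
#' Container for the fixed and random effects of the one-compartment oral
#' everolimus model: a fixed first-order absorption rate constant `ka`,
#' typical apparent clearance `cl_pop` (CL/F) and volume `v_pop` (Vd/F),
#' covariate coefficients (power-model exponents for albumin and body surface
#' area, an exponential slope for the tacrolimus trough), lognormal
#' between-subject variances, and a proportional residual-error variance.
#'
#' Covariate submodels (see [typical_clearance()] and [typical_volume()]):
#' \deqn{CL/F = cl_{pop} \cdot (ALB/ref_{alb})^{\theta_{alb}}
#'   \cdot (BSA/ref_{bsa})^{\theta_{bsa}} \cdot e^{\theta_{tac}(TAC - ref_{tac})}}
#' \deqn{V_d/F = v_{pop} \cdot (ALB/ref_{alb})^{\theta_{v,alb}}}
#'
#' Defaults are the refined estimates obtained after adding prospective
#' trough data (the "refined" set); [pop_params_retrospective()] returns the
#' earlier retrospective-only set.
#'
#' @param ka Absorption rate constant, 1/h (fixed; trough-only data cannot
#'   identify it).
#' @param cl_pop Typical apparent clearance CL/F, L/h.
#' @param v_pop Typical apparent volume of distribution Vd/F, L.
#' @param theta_cl_alb,theta_cl_bsa Dimensionless power exponents of albumin
#'   and body surface area on CL/F.
#' @param theta_cl_tac Exponential slope of the tacrolimus trough on CL/F,
#'   per ng/mL (negative: tacrolimus co-exposure lowers clearance).
#' @param theta_v_alb Power exponent of albumin on Vd/F.
#' @param omega2_cl,omega2_v Variances of the log-scale random effects on
#'   clearance and volume.
#' @param omega_cl_v Optional covariance between the two random effects
#'   (default 0, i.e. a diagonal omega matrix).
#' @param sigma2_prop Proportional residual-error variance.
#' @param ref_alb,ref_bsa,ref_tac Reference covariate values used for
#'   normalization: g/dL, m^2, ng/mL.
#' @return An object of class `pop_params` (a named list).
#' @examples
#' p <- pop_params()
#' cv_percent(p$omega2_cl)
#' @export
pop_params <- function(ka = 0.647,
                       cl_pop = 15.0,
                       v_pop = 862.0,
                       theta_cl_alb = 0.122,
                       theta_cl_bsa = 0.474,
                       theta_cl_tac = -0.026,
                       theta_v_alb = 0.101,
                       omega2_cl = 0.127,
                       omega2_v = 0.743,
                       omega_cl_v = 0,
                       sigma2_prop = 0.242,
                       ref_alb = 4.0,
                       ref_bsa = 1.7,
                       ref_tac = 6.0) {
  p <- list(ka = ka, cl_pop = cl_pop, v_pop = v_pop,
            theta_cl_alb = theta_cl_alb, theta_cl_bsa = theta_cl_bsa,
            theta_cl_tac = theta_cl_tac, theta_v_alb = theta_v_alb,
            omega2_cl = omega2_cl, omega2_v = omega2_v,
            omega_cl_v = omega_cl_v, sigma2_prop = sigma2_prop,
            ref_alb = ref_alb, ref_bsa = ref_bsa, ref_tac = ref_tac)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (ka <= 0) stop("'ka' must be positive", call. = FALSE)
  if (cl_pop <= 0) stop("'cl_pop' must be positive", call. = FALSE)
  if (v_pop <= 0) stop("'v_pop' must be positive", call. = FALSE)
  if (omega2_cl < 0 || omega2_v < 0)
    stop("random-effect variances must be non-negative", call. = FALSE)
  if (sigma2_prop <= 0)
    stop("'sigma2_prop' must be positive", call. = FALSE)
  if (ref_alb <= 0 || ref_bsa <= 0 || ref_tac <= 0)
    stop("reference covariate values must be positive", call. = FALSE)
  if (omega2_cl > 0 && omega2_v > 0 &&
      abs(omega_cl_v) >= sqrt(omega2_cl * omega2_v))
    stop("'omega_cl_v' implies |correlation| >= 1", call. = FALSE)
  if (ka <= cl_pop / v_pop)
    stop("'ka' must exceed the typical elimination rate cl_pop/v_pop ",
         "(flip-flop kinetics are outside the closed form used here)",
         call. = FALSE)
  structure(p, class = "pop_params")
}

#' Retrospective-stage parameter estimates
#'
#' The parameter set estimated from the retrospective trough data alone,
#' before refinement with the prospective cohort.
#'
#' @return A `pop_params` object.
#' @export
pop_params_retrospective <- function() {
  pop_params(cl_pop = 14.7, v_pop = 857.0,
             theta_cl_alb = 0.115, theta_cl_bsa = 0.492,
             theta_cl_tac = -0.0236, theta_v_alb = 0.112,
             omega2_cl = 0.146, omega2_v = 0.777,
             sigma2_prop = 0.243)
}

#' @export
print.pop_params <- function(x, ...) {
  cat("Population PK parameters (1-cmt oral, lognormal IIV, proportional error)\n")
  cat(sprintf("  ka       %8.4g 1/h (fixed)\n", x$ka))
  cat(sprintf("  CL/F     %8.4g L/h   IIV %%CV %.1f\n", x$cl_pop, cv_percent(x$omega2_cl)))
  cat(sprintf("  Vd/F     %8.4g L     IIV %%CV %.1f\n", x$v_pop, cv_percent(x$omega2_v)))
  cat(sprintf("  CL~ALB^%.3g  CL~BSA^%.3g  CL~exp(%.3g*(TAC-%g))  V~ALB^%.3g\n",
              x$theta_cl_alb, x$theta_cl_bsa, x$theta_cl_tac, x$ref_tac,
              x$theta_v_alb))
  cat(sprintf("  sigma2 (proportional) %.4g; refs ALB %g g/dL, BSA %g m2, TAC %g ng/mL\n",
              x$sigma2_prop, x$ref_alb, x$ref_bsa, x$ref_tac))
  invisible(x)
}

#' Interindividual variability as a percent coefficient of variation
#'
#' Converts a lognormal random-effect variance \eqn{\omega^2} to the percent
#' CV scale conventionally reported for population PK models:
#' \deqn{\%CV = 100\sqrt{e^{\omega^2} - 1}}
#'
#' @param omega2 Non-negative variance (vectorized).
#' @return Percent CV, same length as `omega2`.
#' @examples
#' cv_percent(0.127) # ~36.8
#' @export
cv_percent <- function(omega2) {
  if (!is.numeric(omega2) || any(!is.finite(omega2)))
    stop("'omega2' must be finite and numeric", call. = FALSE)
  if (any(omega2 < 0)) stop("'omega2' must be non-negative", call. = FALSE)
  100 * sqrt(exp(omega2) - 1)
}

#' Chi-square thresholds used by stepwise covariate modeling
#'
#' The change in objective function value (-2 log likelihood) needed for
#' significance at level `p` with `df` degrees of freedom; the conventional
#' forward-inclusion (p = 0.05, 3.84) and backward-elimination
#' (p = 0.01, 6.63) cutoffs for one extra parameter.
#'
#' @param p Significance level.
#' @param df Degrees of freedom (number of added parameters).
#' @return The chi-square critical value.
#' @export
scm_threshold <- function(p = 0.05, df = 1) {
  stopifnot(p > 0, p < 1, df >= 1)
  stats::qchisq(1 - p, df = df)
}

#' Read or write a parameter set as a flat key-value text file
#'
#' One `key = value` pair per line, keys exactly the field names of
#' [pop_params()]. Values are written with `format(..., digits = 15)` so a
#' write/read round trip is exact.
#'
#' @param pop A `pop_params` object.
#' @param path File path.
#' @return `read_params()` returns a `pop_params`; `write_params()` returns
#'   `path` invisibly.
#' @export
write_params <- function(pop, path) {
  stopifnot(inherits(pop, "pop_params"))
  lines <- sprintf("%s = %s", names(pop),
                   vapply(pop, function(v) format(v, digits = 15), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad))
    stop("malformed parameter line: ", lines[which(bad)[1]], call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[[`, "", 2L)))
  if (anyNA(vals))
    stop("non-numeric parameter value in ", path, call. = FALSE)
  do.call(pop_params, as.list(stats::setNames(vals, keys)))
}
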