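#' Fit the population model by maximum marginal likelihood
#'
#' Minimizes the Laplace-with-interaction objective ([neg2_loglik()]) over
#' the typical values, covariate coefficients and variance components of a
#' model specification. Positive parameters (typical values, variances) are
#' log-transformed during the search; the absorption rate constant stays
#' fixed at the value in `spec`. Standard errors come from the numerical
#' Hessian of the objective on the transformed scale (central differences,
#' relative step 1e-4), mapped back by the delta method.
#'
#' @param data A [pk_dataset()].
#' @param spec A [pk_model_spec()]; the default is the final everolimus
#'   covariate model.
#' @param init Optional starting values: a `pop_params` object or a named
#'   vector/list with any of `cl_pop`, `v_pop`, per-effect thetas (named as
#'   `param_covariate_form`, e.g. `cl_alb_power`), `omega2_cl`, `omega2_v`,
#'   `sigma2_prop`.
#' @param compute_se Compute standard errors (adds a Hessian evaluation;
#'   disable for bootstrap replicates).
#' @param control Passed to [stats::nlminb()]; defaults use a relative
#'   tolerance of 1e-6.
#' @return An object of class `pk_fit`: `estimates` (named vector on the
#'   natural scale), `pop` (a [pop_params()] when the specification is the
#'   canonical covariate model, else `NULL`), `ofv`, `se`, `rse` (percent),
#'   `eta_modes`, `converged`, `n_subjects`, `n_observations`, `spec`,
#'   `data`.
#' @export
fit_population <- function(data, spec = pk_model_spec(), init = NULL,
                           compute_se = TRUE, control = list()) {
  stopifnot(inherits(data, "pk_dataset"), inherits(spec, "pk_model_spec"))
  struct <- compile_pkdata(data, spec)
  labels <- vapply(spec$covariate_effects, effect_label, "")

  ## data-driven starting values: clearance from the steady-state average
  ## concentration relation C_avg = 1000 D / (tau CL), troughs standing in
  ## for the average; volume is poorly informed a priori, so the default
  ## start is a short multistart over plausible elimination half-lives
  df <- as.data.frame(data)
  med_dv <- stats::median(df$DV[df$EVID == 0L & df$MDV == 0L])
  med_amt <- stats::median(df$AMT[df$EVID == 1L], na.rm = TRUE)
  cl0 <- max(0.8 * 1000 * med_amt / (12 * med_dv), 0.5)
  init_full <- c(cl_pop = cl0, v_pop = cl0 / 0.03,
                 stats::setNames(rep(0, length(labels)), labels),
                 omega2_cl = 0.1, omega2_v = 0.1, sigma2_prop = 0.1)
  multistart <- is.null(init)
  if (inherits(init, "pop_params")) init <- theta_from_pop(init)
  if (!is.null(init)) {
    init <- unlist(init)
    keep <- intersect(names(init), names(init_full))
    init_full[keep] <- init[keep]
  }
  log_scale <- c(TRUE, TRUE, rep(FALSE, length(labels)), TRUE, TRUE, TRUE)
  to_trans <- function(x) ifelse(log_scale, log(x), x)
  from_trans <- function(p) ifelse(log_scale, exp(p), p)
  nm <- names(init_full)

  obj <- function(p) {
    th <- as.list(stats::setNames(from_trans(p), nm))
    ofv_engine(struct, th)
  }
  obj_coarse <- function(p) {      # classical Laplace: cheap pilot surface
    th <- as.list(stats::setNames(from_trans(p), nm))
    ofv_engine(struct, th, higher_order = FALSE)
  }
  ctrl <- utils::modifyList(list(rel.tol = 1e-6, eval.max = 1500,
                                 iter.max = 600), control)
  ## box bounds on the transformed scale: variances are kept off the
  ## omega -> 0 boundary (a 1% CV floor), which otherwise turns
  ## unidentified-variance fits into an endless downhill crawl
  lower <- rep(-Inf, length(init_full)); upper <- rep(Inf, length(init_full))
  names(lower) <- names(upper) <- nm
  lower[c("cl_pop", "v_pop")] <- log(c(0.05, 1))
  upper[c("cl_pop", "v_pop")] <- log(c(1e3, 1e5))
  lower[c("omega2_cl", "omega2_v")] <- log(1e-4)
  upper[c("omega2_cl", "omega2_v")] <- log(25)
  lower["sigma2_prop"] <- log(1e-8); upper["sigma2_prop"] <- log(25)
  lower[!log_scale] <- -50; upper[!log_scale] <- 50
  init_full <- pmin(pmax(init_full, from_trans(lower) * 1.0000001),
                    from_trans(upper))
  start <- to_trans(init_full)
  if (multistart) {
    ## coarse pilot fits from three elimination-rate scales; the marginal
    ## likelihood of trough-only designs can carry distinct local optima in
    ## the volume direction, so a single neutral start is not reliable
    ## pilots run on the cheap classical-Laplace surface, but the basins
    ## they end in are ranked by the full objective: the two surfaces share
    ## basins yet can order them differently
    pilot_ctrl <- list(rel.tol = 1e-4, eval.max = 120, iter.max = 80)
    best <- NULL
    for (ke0 in c(0.1, 0.03, 0.01)) {
      st <- init_full
      st["v_pop"] <- cl0 / ke0
      p0 <- tryCatch(stats::nlminb(to_trans(st), obj_coarse,
                                   control = pilot_ctrl,
                                   lower = lower, upper = upper),
                     error = function(e) NULL)
      if (is.null(p0)) next
      p0$hybrid <- obj(p0$par)
      if (is.null(best) || p0$hybrid < best$hybrid) best <- p0
    }
    if (!is.null(best)) start <- best$par
  }
  opt <- stats::nlminb(start, obj, control = ctrl, lower = lower,
                       upper = upper)
  ## nlminb's "false convergence" on this objective usually just means the
  ## quadrature-switching noise floor was reached; restart (up to three
  ## times) and call the fit converged once a restart cannot improve the
  ## objective materially
  for (r in 1:3) {
    if (opt$convergence == 0) break
    opt2 <- stats::nlminb(opt$par, obj, control = ctrl, lower = lower,
                          upper = upper)
    improved <- opt$objective - opt2$objective
    if (opt2$objective <= opt$objective) opt <- opt2
    if (improved < 0.1 && opt$objective < 1e9) {
      opt$convergence <- 0L
      break
    }
  }
  est <- stats::setNames(from_trans(opt$par), nm)
  theta_hat <- as.list(est)
  ## path-independent objective at the optimum (no warm-start memory)
  struct$cache$eta <- NULL
  ofv_final <- ofv_engine(struct, theta_hat)

  ## conditional modes at the optimum
  tt <- typical_obs(struct, theta_hat)
  omega <- make_omega(est[["omega2_cl"]], est[["omega2_v"]])
  im <- inner_modes(struct, tt$tcl, tt$tv, est[["sigma2_prop"]], omega)
  eta_modes <- im$eta
  colnames(eta_modes) <- c("eta_cl", "eta_v")
  rownames(eta_modes) <- as.character(struct$subj_ids)

  se <- rse <- stats::setNames(rep(NA_real_, length(est)), nm)
  vcov_t <- NULL
  if (compute_se) {
    H <- num_hessian(obj, opt$par)
    vcov_t <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(vcov_t)) {
      se_t <- sqrt(pmax(diag(vcov_t), 0))
      se <- stats::setNames(ifelse(log_scale, est * se_t, se_t), nm)
      rse <- stats::setNames(100 * se / abs(est), nm)
    }
  }

  pop <- tryCatch(pop_from_estimates(est, spec), error = function(e) NULL)
  structure(list(estimates = est, pop = pop, ofv = ofv_final,
                 se = se, rse = rse, eta_modes = eta_modes,
                 converged = opt$convergence == 0 && opt$objective < 1e9,
                 n_subjects = struct$n_subj,
                 n_observations = struct$n_obs,
                 spec = spec, data = data, message = opt$message,
                 vcov_trans = vcov_t, log_scale = log_scale),
            class = "pk_fit")
}

## central-difference Hessian, relative step
num_hessian <- function(fn, p, rel_h = 1e-4) {
  k <- length(p)
  h <- rel_h * pmax(abs(p), 1)
  H <- matrix(0, k, k)
  f0 <- fn(p)
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) {
        pp <- p; pp[i] <- p[i] + h[i]
        pm <- p; pm[i] <- p[i] - h[i]
        H[i, i] <- (fn(pp) - 2 * f0 + fn(pm)) / h[i]^2
      } else {
        ppp <- p; ppp[c(i, j)] <- p[c(i, j)] + h[c(i, j)]
        ppm <- p; ppm[i] <- p[i] + h[i]; ppm[j] <- p[j] - h[j]
        pmp <- p; pmp[i] <- p[i] - h[i]; pmp[j] <- p[j] + h[j]
        pmm <- p; pmm[c(i, j)] <- p[c(i, j)] - h[c(i, j)]
        H[i, j] <- H[j, i] <-
          (fn(ppp) - fn(ppm) - fn(pmp) + fn(pmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

## rebuild a pop_params from estimates when the spec is (a subset of) the
## canonical covariate model
pop_from_estimates <- function(est, spec) {
  labels <- vapply(spec$covariate_effects, effect_label, "")
  canonical <- c("cl_alb_power", "cl_bsa_power", "cl_tac_exponential",
                 "v_alb_power")
  if (!all(labels %in% canonical))
    stop("non-canonical covariate model")
  getv <- function(lb) if (lb %in% labels) est[[lb]] else 0
  refs <- spec$refs
  pop_params(ka = spec$ka, cl_pop = est[["cl_pop"]], v_pop = est[["v_pop"]],
             theta_cl_alb = getv("cl_alb_power"),
             theta_cl_bsa = getv("cl_bsa_power"),
             theta_cl_tac = getv("cl_tac_exponential"),
             theta_v_alb = getv("v_alb_power"),
             omega2_cl = est[["omega2_cl"]], omega2_v = est[["omega2_v"]],
             sigma2_prop = est[["sigma2_prop"]],
             ref_alb = if (is.na(refs["alb"])) 4 else refs[["alb"]],
             ref_bsa = if (is.na(refs["bsa"])) 1.7 else refs[["bsa"]],
             ref_tac = if (is.na(refs["tac"])) 6 else refs[["tac"]])
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("Population PK fit: %d subjects, %d observations\n",
              x$n_subjects, x$n_observations))
  cat(sprintf("OFV %.3f, converged: %s\n", x$ofv, x$converged))
  print(fit_table(x), digits = 4)
  invisible(x)
}

#' Parameter table of a fit
#'
#' Estimates with relative standard errors, interindividual variability on
#' the percent-CV scale for the variance components, and eta-shrinkage —
#' the layout conventional for population-PK reports.
#'
#' @param fit A `pk_fit`.
#' @return A data frame with columns `parameter`, `estimate`, `rse_pct`,
#'   `iiv_cv_pct`, `shrinkage_pct`.
#' @export
fit_table <- function(fit) {
  stopifnot(inherits(fit, "pk_fit"))
  nm <- names(fit$estimates)
  iiv <- ifelse(nm %in% c("omega2_cl", "omega2_v"),
                cv_percent(pmax(fit$estimates, 0))[seq_along(nm)], NA_real_)
  shr <- rep(NA_real_, length(nm))
  sh <- tryCatch(eta_shrinkage(fit), error = function(e) NULL)
  if (!is.null(sh)) {
    shr[nm == "omega2_cl"] <- sh[["eta_cl"]]
    shr[nm == "omega2_v"] <- sh[["eta_v"]]
  }
  data.frame(parameter = c("ka (fixed)", nm),
             estimate = c(fit$spec$ka, unname(fit$estimates)),
             rse_pct = c(NA, unname(fit$rse)),
             iiv_cv_pct = c(NA, iiv),
             shrinkage_pct = c(NA, shr))
}

#' Eta-shrinkage of the empirical Bayes estimates
#'
#' `100 * (1 - SD(eta_hat) / omega)` per random effect: near 0 when the data
#' determine each subject's random effect well, near 100 when the
#' conditional modes collapse to the population mean.
#'
#' @param fit A converged `pk_fit`.
#' @return Named vector (percent) for `eta_cl` and `eta_v`.
#' @export
eta_shrinkage <- function(fit) {
  stopifnot(inherits(fit, "pk_fit"))
  om <- c(eta_cl = fit$estimates[["omega2_cl"]],
          eta_v = fit$estimates[["omega2_v"]])
  if (any(om <= 0))
    stop("shrinkage is undefined when an omega variance is zero",
         call. = FALSE)
  vapply(c("eta_cl", "eta_v"), function(k)
    100 * (1 - stats::sd(fit$eta_modes[, k]) / sqrt(om[[k]])), 0)
}

#' Akaike information criterion from an OFV
#'
#' `AIC = OFV + 2 * n_params`; used to rank non-nested structural model
#' candidates (lower is better).
#'
#' @param ofv Objective function value (-2 log likelihood).
#' @param n_params Number of estimated parameters.
#' @return The AIC.
#' @export
aic <- function(ofv, n_params) {
  stopifnot(is.numeric(ofv), is.numeric(n_params), n_params >= 0)
  ofv + 2 * n_params
}
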