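#' Therapeutic target range for the everolimus trough
#'
#' @param lower,upper Bounds in ng/mL; defaults 3 and 8, the maintenance
#'   window targeted after liver transplantation.
#' @return A list of class `target_range`.
#' @export
target_range <- function(lower = 3, upper = 8) {
  stopifnot(is.numeric(lower), is.numeric(upper))
  if (!(0 < lower && lower < upper))
    stop("need 0 < lower < upper", call. = FALSE)
  structure(list(lower = lower, upper = upper), class = "target_range")
}

#' Scenario grid for simulation-based dosing optimization
#'
#' The covariate levels and candidate doses over which steady-state troughs
#' are simulated: body surface area at low/normal/high (1.4, 1.7, 2.1 m^2),
#' tacrolimus troughs of 6 and 10 ng/mL, albumin at low/normal (2.5,
#' 4.0 g/dL) — 12 covariate cells which, crossed with the candidate doses,
#' give the simulated scenarios.
#'
#' @param bsa_levels,tac_levels,alb_levels Covariate levels.
#' @param doses Candidate q12h doses, mg (ascending).
#' @param n_subjects Simulated subjects per scenario cell.
#' @param tau Dosing interval, h.
#' @return A list of class `scenario_grid`.
#' @export
scenario_grid <- function(bsa_levels = c(1.4, 1.7, 2.1),
                          tac_levels = c(6, 10),
                          alb_levels = c(2.5, 4.0),
                          doses = c(1.0, 1.25, 1.5, 1.75),
                          n_subjects = 50,
                          tau = 12) {
  stopifnot(all(bsa_levels > 0), all(tac_levels > 0), all(alb_levels > 0),
            all(doses > 0), n_subjects >= 1, tau > 0)
  if (is.unsorted(doses, strictly = TRUE))
    stop("'doses' must be strictly ascending", call. = FALSE)
  structure(list(bsa_levels = bsa_levels, tac_levels = tac_levels,
                 alb_levels = alb_levels, doses = doses,
                 n_subjects = n_subjects, tau = tau),
            class = "scenario_grid")
}

#' Simulate steady-state troughs for one scenario cell
#'
#' Draws `n` virtual subjects at fixed covariates (between-subject
#' variability only) and returns their steady-state troughs for the given
#' q12h dose. Residual (assay) error is excluded by default so that the
#' sample describes true trough exposure; set `residual = TRUE` to add it.
#'
#' @param cov Single-row covariates ([patient_covariates()] or data frame).
#' @param dose Dose, mg.
#' @param pop A [pop_params()].
#' @param n Number of subjects.
#' @param tau Dosing interval, h.
#' @param residual Add proportional residual error to the troughs.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` troughs, ng/mL.
#' @export
simulate_scenario <- function(cov, dose, pop, n = 50, tau = 12,
                              residual = FALSE, seed = NULL) {
  stopifnot(dose > 0, n >= 1)
  cov <- as.data.frame(cov)[rep(1L, n), , drop = FALSE]
  run <- function() {
    ind <- sample_individual(cov, pop)
    tr <- steady_state_trough(dose, tau, ind)
    if (residual) tr <- add_residual(tr, pop$sigma2_prop)
    tr
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Fraction of troughs inside the target range
#'
#' @param troughs Numeric vector of trough concentrations, ng/mL.
#' @param range A [target_range()].
#' @return Fraction of values in the closed interval.
#' @export
target_attainment <- function(troughs, range = target_range()) {
  stopifnot(inherits(range, "target_range"))
  if (!length(troughs)) stop("empty trough sample", call. = FALSE)
  mean(troughs >= range$lower & troughs <= range$upper)
}

#' Recommend a maintenance dose for one covariate profile
#'
#' Default criterion `"attainment"`: simulate steady-state troughs at every
#' candidate dose with common random numbers and pick the dose maximizing
#' the probability of landing in the target range (ties go to the lower
#' dose). Criterion `"midpoint"`: pick the dose whose typical-value trough
#' is closest to the middle of the range — deterministic, no simulation.
#'
#' @param cov Single-row covariates.
#' @param pop A [pop_params()].
#' @param candidates Candidate doses, mg (ascending).
#' @param range A [target_range()].
#' @param criterion Selection rule.
#' @param n Simulated subjects per candidate (attainment criterion).
#' @param tau Dosing interval, h.
#' @param seed Optional integer seed.
#' @return The recommended dose (mg), with attributes `attainment` (per
#'   candidate) and `typical_trough` (per candidate).
#' @export
recommend_dose <- function(cov, pop, candidates = c(1.0, 1.25, 1.5, 1.75),
                           range = target_range(),
                           criterion = c("attainment", "midpoint"),
                           n = 4000, tau = 12, seed = NULL) {
  criterion <- match.arg(criterion)
  if (!length(candidates)) stop("no candidate doses", call. = FALSE)
  candidates <- sort(candidates)
  cov <- as.data.frame(cov)[1L, , drop = FALSE]
  ind_typ <- list(cl = typical_clearance(cov, pop),
                  v = typical_volume(cov, pop), ka = pop$ka)
  typical <- vapply(candidates, steady_state_trough, 0, tau = tau,
                    ind = ind_typ)
  if (criterion == "midpoint") {
    mid <- (range$lower + range$upper) / 2
    pick <- which.min(abs(typical - mid))   # which.min takes the first tie
    att <- as.numeric(typical >= range$lower & typical <= range$upper)
  } else {
    ## one set of eta draws shared by all candidates: troughs are linear in
    ## dose, so each subject's trough at dose D is D * (1 mg trough)
    base <- simulate_scenario(cov, 1, pop, n = n, tau = tau, seed = seed)
    att <- vapply(candidates,
                  function(d) target_attainment(base * d, range), 0)
    if (max(att) <= 0)
      stop("no candidate dose attains the target range", call. = FALSE)
    pick <- which.max(att)                  # first maximum = lowest dose
  }
  structure(candidates[pick], attainment = att, typical_trough = typical,
            candidates = candidates)
}

#' Build the covariate-stratified dose nomogram
#'
#' Evaluates [recommend_dose()] at a representative covariate profile for
#' each of the 12 clinical strata (albumin below/at-or-above 3.5 g/dL,
#' tacrolimus trough below/at-or-above 8 ng/mL, body surface area < 1.6 /
#' 1.6-1.9 / > 1.9 m^2). Representatives default to the scenario levels for
#' the open-ended strata and the interval midpoint for the middle BSA
#' stratum. The returned table is checked for clinical monotonicity: the
#' recommended dose may not decrease with body surface area or albumin and
#' may not increase with the tacrolimus stratum.
#'
#' @param pop A [pop_params()].
#' @param grid A [scenario_grid()] supplying candidate doses and tau.
#' @param range A [target_range()].
#' @param criterion Passed to [recommend_dose()].
#' @param n Simulated subjects per cell-dose evaluation.
#' @param seed Optional integer seed.
#' @param alb_cut,tac_cut,bsa_cuts Stratum boundaries.
#' @return A data frame of class `pk_nomogram` with the stratum labels,
#'   representative covariates, recommended dose and per-cell attainment.
#' @export
build_nomogram <- function(pop, grid = scenario_grid(),
                           range = target_range(),
                           criterion = "attainment",
                           n = 4000, seed = NULL,
                           alb_cut = 3.5, tac_cut = 8,
                           bsa_cuts = c(1.6, 1.9)) {
  alb_rep <- c(grid$alb_levels[1], grid$alb_levels[2])
  tac_rep <- c(grid$tac_levels[1], grid$tac_levels[2])
  bsa_rep <- c(grid$bsa_levels[1], mean(bsa_cuts), grid$bsa_levels[3])
  alb_lab <- c(sprintf("<%.1f", alb_cut), sprintf(">=%.1f", alb_cut))
  tac_lab <- c(sprintf("<%g", tac_cut), sprintf(">=%g", tac_cut))
  bsa_lab <- c(sprintf("<%.1f", bsa_cuts[1]),
               sprintf("%.1f-%.1f", bsa_cuts[1], bsa_cuts[2]),
               sprintf(">%.1f", bsa_cuts[2]))
  rows <- list()
  k <- 0L
  for (ia in 1:2) for (it in 1:2) for (ib in 1:3) {
    k <- k + 1L
    ## common random numbers across cells: the same eta draws back every
    ## cell, so between-cell contrasts are not blurred by Monte-Carlo noise
    cell_seed <- seed
    cov <- patient_covariates(alb = alb_rep[ia], bsa = bsa_rep[ib],
                              tac = tac_rep[it])
    rec <- recommend_dose(cov, pop, candidates = grid$doses, range = range,
                          criterion = criterion, n = n, tau = grid$tau,
                          seed = cell_seed)
    rows[[k]] <- data.frame(alb_stratum = alb_lab[ia],
                            tac_stratum = tac_lab[it],
                            bsa_stratum = bsa_lab[ib],
                            alb = alb_rep[ia], tac = tac_rep[it],
                            bsa = bsa_rep[ib],
                            dose_mg = as.numeric(rec),
                            attainment = attr(rec, "attainment")[
                              match(as.numeric(rec), attr(rec, "candidates"))])
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pk_nomogram", "data.frame")
  check_nomogram_monotone(out)
  out
}

## dose must be non-decreasing in bsa and alb, non-increasing in tac
check_nomogram_monotone <- function(nom) {
  get <- function(a, t, b) nom$dose_mg[nom$alb == a & nom$tac == t & nom$bsa == b]
  albs <- sort(unique(nom$alb)); tacs <- sort(unique(nom$tac))
  bsas <- sort(unique(nom$bsa))
  for (a in albs) for (t in tacs)
    if (is.unsorted(vapply(bsas, function(b) get(a, t, b), 0)))
      stop("nomogram not monotone in body surface area", call. = FALSE)
  for (t in tacs) for (b in bsas)
    if (is.unsorted(vapply(albs, function(a) get(a, t, b), 0)))
      stop("nomogram not monotone in albumin", call. = FALSE)
  for (a in albs) for (b in bsas)
    if (is.unsorted(rev(vapply(tacs, function(t) get(a, t, b), 0))))
      stop("nomogram not monotone in tacrolimus", call. = FALSE)
  invisible(nom)
}

#' @export
print.pk_nomogram <- function(x, ...) {
  cat("Model-informed precision dosing nomogram (q12h maintenance dose)\n")
  print(as.data.frame(x)[, c("alb_stratum", "tac_stratum", "bsa_stratum",
                             "dose_mg", "attainment")], row.names = FALSE)
  invisible(x)
}

#' Write a nomogram as a delimited table
#'
#' @param nom A [build_nomogram()] result.
#' @param path Output file.
#' @export
write_nomogram <- function(nom, path) {
  stopifnot(inherits(nom, "pk_nomogram"))
  utils::write.csv(as.data.frame(nom), path, row.names = FALSE)
  invisible(path)
}

#' Pearson chi-square comparison of two target-achievement rates
#'
#' Standard 2x2 test without continuity correction, comparing k1/n1 versus
#' k2/n2 subjects achieving the therapeutic target. An expected cell below
#' 1 sets the `small_expected` flag on the result.
#'
#' @param k1,n1 Achievers and total in group 1.
#' @param k2,n2 Achievers and total in group 2.
#' @return List with `statistic`, `p_value`, `proportions`,
#'   `small_expected`.
#' @export
achievement_chi_square <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(tab == 0) && any(colSums(tab) == 0 | rowSums(tab) == 0)) {
    ## degenerate margin: identical all-or-nothing groups
    return(list(statistic = 0, p_value = 1,
                proportions = c(k1 / n1, k2 / n2),
                small_expected = TRUE))
  }
  ts <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ts$statistic), p_value = unname(ts$p.value),
       proportions = c(k1 / n1, k2 / n2),
       small_expected = any(expected < 1))
}
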