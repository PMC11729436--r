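test_that("typical clearance follows the covariate submodel", {
  pop <- refined_pop()
  ## at the reference covariates every factor is 1
  ref <- patient_covariates(alb = 4.0, bsa = 1.7, tac = 6.0)
  expect_identical(typical_clearance(ref, pop), 15.0)
  expect_identical(typical_volume(ref, pop), 862.0)
  ## direct evaluation of the power term in BSA
  cov <- patient_covariates(alb = 4.0, bsa = 2.1, tac = 6.0)
  expect_equal(typical_clearance(cov, pop), 15.0 * (2.1 / 1.7)^0.474,
               tolerance = 1e-12)
  expect_equal(typical_clearance(cov, pop), 16.58, tolerance = 5e-4)
  ## independent spreadsheet-style evaluation for a mixed profile
  cov2 <- patient_covariates(alb = 2.5, bsa = 1.7, tac = 10)
  by_hand <- 15.0 * (2.5 / 4.0)^0.122 * exp(-0.026 * (10 - 6))
  expect_equal(typical_clearance(cov2, pop), by_hand, tolerance = 1e-12)
  ## volume: albumin power effect only
  expect_equal(typical_volume(patient_covariates(2.5, 1.7, 6), pop),
               862 * 0.625^0.101, tolerance = 1e-12)
  expect_equal(typical_volume(patient_covariates(2.5, 1.7, 6), pop), 822,
               tolerance = 1e-3)
  p0 <- pop_params(theta_v_alb = 0)
  expect_identical(typical_volume(patient_covariates(1.2, 1.7, 6), p0), 862.0)
})

test_that("clearance is monotone in each covariate in the clinical direction", {
  pop <- refined_pop()
  alb <- seq(2, 5, by = 0.5)
  expect_true(all(diff(typical_clearance(
    patient_covariates(alb, 1.7, 6), pop)) > 0))
  bsa <- seq(1.2, 2.2, by = 0.2)
  expect_true(all(diff(typical_clearance(
    patient_covariates(4, bsa, 6), pop)) > 0))
  tac <- seq(0, 15, by = 3)
  expect_true(all(diff(typical_clearance(
    patient_covariates(4, 1.7, tac), pop)) < 0))
  expect_error(typical_clearance(data.frame(alb = -1, bsa = 1.7, tac = 6), pop),
               "alb")
})

test_that("individual parameters are lognormal around the typical values", {
  pop <- refined_pop()
  cov <- patient_covariates(4, 1.7, 6)
  ## degenerate variances collapse to the typical values
  p0 <- pop_params(omega2_cl = 0, omega2_v = 0)
  ind <- sample_individual(cov, p0, seed = 1)
  expect_equal(ind$cl, 15); expect_equal(ind$v, 862)
  ## determinism under a fixed seed
  covn <- patient_covariates(rep(4, 10), rep(1.7, 10), rep(6, 10))
  expect_identical(sample_individual(covn, pop, seed = 7),
                   sample_individual(covn, pop, seed = 7))
  ## large-sample CV of clearance matches the omega2 -> %CV transform
  big <- as.data.frame(cov)[rep(1, 1e5), ]
  draws <- sample_individual(big, pop, seed = 42)
  cv_emp <- 100 * stats::sd(draws$cl) / mean(draws$cl)
  expect_equal(cv_emp, 36.8, tolerance = 0.01)
  ## optional CL-V covariance shows up in the draws
  pc <- pop_params(omega_cl_v = 0.15)
  dc <- sample_individual(big, pc, seed = 42)
  expect_equal(stats::cov(dc$eta_cl, dc$eta_v), 0.15, tolerance = 0.05)
})

test_that("concentration profile matches an independent ODE integration", {
  skip_if_not_installed("deSolve")
  ind <- list(cl = 15, v = 862, ka = 0.647)
  reg <- dosing_regimen(1, 12, n_doses = 1)
  times <- c(0, 1, 3, 6, 12, 24, 48)
  closed <- concentration_profile(times, reg, ind)
  expect_identical(closed[1], 0)
  ## two-state absorption/central ODE system, dose in the gut at t = 0
  rhs <- function(t, y, p) {
    with(as.list(c(y, p)), list(c(-ka * gut, ka * gut - (cl / v) * cent)))
  }
  sol <- deSolve::lsoda(c(gut = 1, cent = 0), times, rhs,
                        c(ka = 0.647, cl = 15, v = 862),
                        rtol = 1e-10, atol = 1e-12)
  ode_ng <- 1000 * sol[, "cent"] / 862
  expect_equal(closed[-1], ode_ng[-1], tolerance = 1e-4)

  ## random parameter sets, multiple doses
  set.seed(5)
  for (r in 1:5) {
    cl <- runif(1, 5, 30); v <- runif(1, 300, 1500); ka <- runif(1, 0.3, 1.5)
    nd <- sample(2:6, 1)
    tt <- sort(runif(4, 0, nd * 12))
    closed <- concentration_profile(tt, dosing_regimen(1.5, 12, nd),
                                    list(cl = cl, v = v, ka = ka))
    dose_events <- data.frame(var = "gut", time = (0:(nd - 1)) * 12,
                              value = 1.5, method = "add")
    sol <- deSolve::lsoda(c(gut = 0, cent = 0),
                          sort(unique(c(0, tt, dose_events$time))), rhs,
                          c(ka = ka, cl = cl, v = v),
                          events = list(data = dose_events),
                          rtol = 1e-10, atol = 1e-12)
    ode_ng <- 1000 * sol[match(tt, sol[, "time"]), "cent"] / v
    expect_equal(closed, ode_ng, tolerance = 1e-3)
  }
})

test_that("superposition approaches the steady-state closed form", {
  ind <- list(cl = 15, v = 862, ka = 0.647)
  ss <- steady_state_trough(1, 12, ind)
  ## 40 q12h doses ~ 12 elimination half-lives at the typical parameters
  tr40 <- concentration_profile(40 * 12, dosing_regimen(1, 12, 40), ind)
  expect_equal(tr40, ss, tolerance = 5e-3)
  ## property over random valid parameter sets at >= 20 half-lives
  set.seed(11)
  for (r in 1:10) {
    cl <- runif(1, 5, 30); v <- runif(1, 300, 1500); ka <- runif(1, 0.3, 1.5)
    ke <- cl / v
    n_half <- ceiling(20 * log(2) / ke / 12) + 1
    indr <- list(cl = cl, v = v, ka = ka)
    tr <- concentration_profile(n_half * 12, dosing_regimen(2, 12, n_half),
                                indr)
    expect_equal(tr, steady_state_trough(2, 12, indr), tolerance = 5e-3)
  }
})

test_that("steady-state trough has the expected analytic behaviour", {
  ind <- list(cl = 15.0, v = 862, ka = 0.647)
  expect_equal(steady_state_trough(1, 12, ind), 5.13, tolerance = 2e-3)
  ## linear in dose
  expect_identical(steady_state_trough(2, 12, ind),
                   2 * steady_state_trough(1, 12, ind))
  ## washout limit
  expect_lt(steady_state_trough(1, 24 * 90, ind), 1e-6)
  ## decreasing in clearance at fixed volume
  cls <- seq(5, 40, by = 5)
  tr <- steady_state_trough(1, 12, list(cl = cls, v = 862, ka = 0.647))
  expect_true(all(diff(tr) < 0))
  ## flip-flop violation rejected
  expect_error(steady_state_trough(1, 12, list(cl = 600, v = 862, ka = 0.647)),
               "absorption")
})

test_that("proportional residual error has the configured spread and floor", {
  expect_identical(add_residual(c(1, 5, 10), 0), c(1, 5, 10))
  x <- add_residual(rep(10, 1e5), 0.242, seed = 3)
  ## robust spread of obs/pred: the LOQ floor clips ~2% of the left tail,
  ## so the quartile-based SD estimate is the right check of the generator
  ratio_sd <- stats::IQR(x / 10) / (2 * stats::qnorm(0.75))
  expect_equal(ratio_sd, sqrt(0.242), tolerance = 0.02)
  expect_identical(add_residual(rep(2, 50), 0.242, seed = 9),
                   add_residual(rep(2, 50), 0.242, seed = 9))
  ## hard negative draws are floored at the LOQ surrogate
  y <- add_residual(rep(0.05, 2e4), 4, seed = 2)
  expect_true(min(y) == 0.01)
})

test_that("Du Bois body surface area matches direct evaluation", {
  expect_equal(bsa_du_bois(169.0, 64.4),
               0.007184 * 64.4^0.425 * 169^0.725, tolerance = 1e-12)
  expect_equal(bsa_du_bois(169.0, 64.4), 1.74, tolerance = 2e-3)
  expect_equal(bsa_du_bois(166.24, 67.83), 1.76, tolerance = 3e-3)
  expect_equal(bsa_du_bois(170, 140) / bsa_du_bois(170, 70), 2^0.425,
               tolerance = 1e-12)
  expect_error(bsa_du_bois(-170, 70), "height")
})
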