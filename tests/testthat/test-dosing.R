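test_that("target attainment is the closed-interval fraction", {
  expect_equal(target_attainment(c(2, 4, 8, 9)), 0.5)
  expect_equal(target_attainment(c(3, 5, 8)), 1.0)
  expect_equal(target_attainment(c(1, 9)), 0)
  expect_error(target_attainment(numeric(0)), "empty")
  expect_error(target_range(5, 2), "lower")
})

test_that("scenario troughs follow the covariate physiology", {
  pop <- refined_pop()
  cov <- patient_covariates(4, 1.7, 6)
  ## no variability: every trough equals the typical trough
  p0 <- pop_params(omega2_cl = 0, omega2_v = 0)
  tr <- simulate_scenario(cov, 1, p0, n = 20, seed = 1)
  typ <- steady_state_trough(1, 12, list(cl = 15, v = 862, ka = 0.647))
  expect_equal(tr, rep(typ, 20), tolerance = 1e-12)
  ## doubling the dose doubles every trough
  t1 <- simulate_scenario(cov, 1, pop, n = 100, seed = 6)
  t2 <- simulate_scenario(cov, 2, pop, n = 100, seed = 6)
  expect_equal(t2, 2 * t1, tolerance = 1e-12)
  ## higher tacrolimus trough -> lower clearance -> higher troughs
  hi <- simulate_scenario(patient_covariates(4, 1.7, 10), 1, pop,
                          n = 10000, seed = 3)
  lo <- simulate_scenario(patient_covariates(4, 1.7, 6), 1, pop,
                          n = 10000, seed = 3)
  expect_gt(median(hi), median(lo))
})

test_that("dose recommendation maximizes attainment with lower-dose ties", {
  pop <- refined_pop()
  cov <- patient_covariates(4, 1.7, 6)
  ## single candidate: returned unconditionally
  expect_equal(as.numeric(recommend_dose(cov, pop, candidates = 1.25,
                                         seed = 2)), 1.25)
  rec <- recommend_dose(cov, pop, seed = 11)
  att <- attr(rec, "attainment")
  expect_gte(att[match(as.numeric(rec), attr(rec, "candidates"))], max(att))
  ## larger body surface area never lowers the recommended dose
  r_small <- recommend_dose(patient_covariates(4, 1.4, 6), pop, seed = 21)
  r_big <- recommend_dose(patient_covariates(4, 2.1, 6), pop, seed = 21)
  expect_gte(as.numeric(r_big), as.numeric(r_small))
  ## higher tacrolimus exposure never raises it
  r_tac <- recommend_dose(patient_covariates(4, 1.4, 10), pop, seed = 21)
  expect_lte(as.numeric(r_tac), as.numeric(r_small))
  ## midpoint criterion agrees on the trivial single-candidate case and is
  ## deterministic
  m1 <- recommend_dose(cov, pop, criterion = "midpoint")
  m2 <- recommend_dose(cov, pop, criterion = "midpoint")
  expect_identical(as.numeric(m1), as.numeric(m2))
})

test_that("the nomogram satisfies its clinical constraints on every build", {
  pop <- refined_pop()
  for (seed in c(1, 77)) {
    nom <- build_nomogram(pop, seed = seed)
    expect_identical(nrow(nom), 12L)
    ## all recommended doses inside the reported 1-1.75 mg band
    expect_true(all(nom$dose_mg >= 1.0 & nom$dose_mg <= 1.75))
    ## monotone in BSA and ALB, antitone in TAC (asserted internally too)
    expect_silent(everopk:::check_nomogram_monotone(nom))
  }
  n1 <- build_nomogram(pop, seed = 42)
  n2 <- build_nomogram(pop, seed = 42)
  expect_identical(n1$dose_mg, n2$dose_mg)
  ## export mirrors the three clinical-variable columns
  f <- withr::local_tempfile(fileext = ".csv")
  write_nomogram(n1, f)
  out <- utils::read.csv(f)
  expect_true(all(c("alb_stratum", "tac_stratum", "bsa_stratum", "dose_mg")
                  %in% names(out)))
})

test_that("achievement comparison reproduces the 2x2 Pearson chi-square", {
  ## identical groups: no signal
  r0 <- achievement_chi_square(13, 20, 13, 20)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1, tolerance = 1e-12)
  ## the 65.0% vs 62.4% comparison, checked against the closed-form
  ## n(ad - bc)^2 / (row and column product) evaluation
  a <- 13; b <- 7; c <- 53; d <- 32
  by_hand <- (a + b + c + d) * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  r <- achievement_chi_square(13, 20, 53, 85)
  expect_equal(r$statistic, by_hand, tolerance = 1e-12)
  expect_equal(r$proportions, c(0.65, 53 / 85), tolerance = 1e-12)
  expect_gt(r$p_value, 0.05)
  ## symmetric in group order
  r_sw <- achievement_chi_square(53, 85, 13, 20)
  expect_equal(r_sw$statistic, r$statistic, tolerance = 1e-12)
  ## extreme contrast
  rx <- achievement_chi_square(0, 10, 10, 10)
  expect_gt(rx$statistic, 10)
  expect_lt(rx$p_value, 0.01)
})
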