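## bootstrap and VPC run on a compact no-covariate model so each replicate
## fit stays fast; the generating truth uses the refined variances
boot_pop <- function() {
  pop_params(theta_cl_alb = 0, theta_cl_bsa = 0, theta_cl_tac = 0,
             theta_v_alb = 0)
}
boot_spec <- function() pk_model_spec(covariate_effects = list())

test_that("bootstrap percentiles bracket the generating clearance", {
  pop <- boot_pop()
  d <- generate_dataset(cohort_config(n = 15, n_troughs = 4,
                                      first_trough_day = 4,
                                      ss_records = FALSE), pop, seed = 18)
  fit <- fit_population(d, boot_spec(), compute_se = FALSE)
  bs <- pk_bootstrap(d, boot_spec(), fit = fit, n_reps = 25, seed = 5)
  expect_true(bs$reliable)
  expect_gte(bs$n_success, 20)
  s <- bs$summary
  expect_true(all(s$p5 <= s$median & s$median <= s$p95))
  cl_row <- s[s$parameter == "cl_pop", ]
  expect_gt(15, cl_row$p5); expect_lt(15, cl_row$p95)
})

test_that("cloned subjects give (near) zero-width bootstrap intervals", {
  pop <- boot_pop()
  one <- as.data.frame(generate_dataset(cohort_config(n = 1, n_troughs = 4),
                                        pop, seed = 3))
  clones <- do.call(rbind, lapply(1:6, function(k) {
    x <- one; x$ID <- sprintf("C%02d", k); x
  }))
  d <- pk_dataset(clones)
  fit <- fit_population(d, boot_spec(), compute_se = FALSE)
  bs <- pk_bootstrap(d, boot_spec(), fit = fit, n_reps = 10, seed = 1)
  width <- (bs$summary$p95 - bs$summary$p5) /
    pmax(abs(bs$summary$estimate), 1e-6)
  expect_lt(max(width), 1e-3)
  ## deterministic under a fixed seed
  bs2 <- pk_bootstrap(d, boot_spec(), fit = fit, n_reps = 10, seed = 1)
  expect_identical(bs$summary, bs2$summary)
})

test_that("VPC is self-consistent on model-true data", {
  pop <- boot_pop()
  d <- generate_dataset(cohort_config(n = 40, n_troughs = 5,
                                      first_trough_day = 4,
                                      ss_records = FALSE), pop, seed = 27)
  fit <- fit_population(d, boot_spec(), compute_se = FALSE)
  v <- vpc(d, fit, n_sim = 200, seed = 9, n_bins = 4)
  ## data simulated from the fitted model: most percentile points must sit
  ## inside their simulation bands, the median everywhere
  expect_true(all(v$bins$band_lower <= v$bins$band_upper))
  med <- v$bins[v$bins$percentile == 0.5, ]
  expect_gte(mean(med$inside), 0.75)
  expect_gte(mean(v$bins$inside), 0.8)
  ## observed percentiles do not depend on the number of simulations
  v2 <- vpc(d, fit, n_sim = 50, seed = 10, n_bins = 4)
  expect_equal(v2$bins$observed, v$bins$observed, tolerance = 1e-12)
})

test_that("shrinking the variances collapses prediction-corrected values", {
  ## variances at the estimation floor (1% CV): prediction-corrected
  ## observations coincide with the bin prediction and the simulation
  ## bands narrow to a few percent
  pop0 <- pop_params(theta_cl_alb = 0, theta_cl_bsa = 0, theta_cl_tac = 0,
                     theta_v_alb = 0,
                     omega2_cl = 1e-4, omega2_v = 1e-4, sigma2_prop = 1e-4)
  d <- generate_dataset(cohort_config(n = 8, n_troughs = 3,
                                      first_trough_day = 4,
                                      ss_records = FALSE), pop0, seed = 2)
  fit <- fit_population(d, boot_spec(),
                        init = c(cl_pop = 15, v_pop = 862,
                                 omega2_cl = 1e-4, omega2_v = 1e-4,
                                 sigma2_prop = 1e-4),
                        compute_se = FALSE)
  v <- vpc(d, fit, n_sim = 30, seed = 4, n_bins = 2)
  spread <- with(v$bins, (band_upper - band_lower) / observed)
  expect_lt(max(spread), 0.2)
})

test_that("goodness-of-fit table behaves like its definitions", {
  pop <- boot_pop()
  d <- generate_dataset(cohort_config(n = 20, n_troughs = 4), pop, seed = 31)
  fit <- fit_population(d, boot_spec(), compute_se = FALSE)
  g <- gof_table(d, fit)
  expect_identical(nrow(g), fit$n_observations)
  expect_equal(g$res, g$dv - g$pred)
  expect_equal(g$wres, (g$dv - g$pred) / (sqrt(fit$estimates[["sigma2_prop"]]) * g$pred))
  ## population prediction equals the profile at eta = 0
  df <- as.data.frame(d)
  id1 <- df$ID[1]
  obs1 <- df[df$ID == id1 & df$EVID == 0, ]
  ind0 <- list(cl = fit$estimates[["cl_pop"]], v = fit$estimates[["v_pop"]],
               ka = fit$spec$ka)
  direct <- steady_state_trough(df$AMT[df$ID == id1 & df$EVID == 1][1], 12,
                                ind0)
  expect_equal(g$pred[g$id == id1], rep(direct, nrow(obs1)),
               tolerance = 1e-10)
  ## near-perfect data leave near-zero residuals
  popt <- pop_params(theta_cl_alb = 0, theta_cl_bsa = 0, theta_cl_tac = 0,
                     theta_v_alb = 0,
                     omega2_cl = 1e-4, omega2_v = 1e-4, sigma2_prop = 1e-4)
  dt <- generate_dataset(cohort_config(n = 6, n_troughs = 3,
                                       first_trough_day = 4,
                                       ss_records = FALSE), popt, seed = 6)
  ft <- fit_population(dt, boot_spec(),
                       init = c(cl_pop = 15, v_pop = 862,
                                omega2_cl = 1e-4, omega2_v = 1e-4,
                                sigma2_prop = 1e-4),
                       compute_se = FALSE)
  gt <- gof_table(dt, ft)
  expect_lt(max(abs(gt$res / gt$dv)), 0.05)
})

test_that("weighted residuals on model-true data look standard normal", {
  pop <- boot_pop()
  d <- generate_dataset(cohort_config(n = 60, n_troughs = 8), pop,
                        seed = 55)
  fit <- fit_population(d, boot_spec(), compute_se = FALSE)
  g <- gof_table(d, fit)
  skew <- mean((g$iwres - mean(g$iwres))^3) / stats::sd(g$iwres)^3
  expect_lt(abs(skew), 0.5)
  expect_equal(stats::sd(g$iwres), 1, tolerance = 0.2)
})
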