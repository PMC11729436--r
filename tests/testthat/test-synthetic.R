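test_that("generated covariates match the configured marginals", {
  cfg <- cohort_config(n = 1e4)
  cov <- generate_covariates(cfg, seed = 14)
  expect_identical(nrow(cov), 10000L)
  ## 3-sigma Monte-Carlo bands around the configured moments
  expect_equal(mean(cov$alb), 3.89, tolerance = 3 * 0.5 / sqrt(1e4) / 3.89)
  expect_equal(sd(cov$alb), 0.50, tolerance = 0.05)
  expect_equal(mean(cov$bsa), 1.7, tolerance = 3 * 0.1 / sqrt(1e4) / 1.7)
  ## tacrolimus: right-skewed, truncated, positive
  expect_true(all(cov$tac > 0 & cov$tac <= 30))
  expect_gt(mean(cov$tac), median(cov$tac))     # right skew
  expect_true(all(cov$alb > 0 & cov$bsa > 0))
  ## degenerate spread: identical subjects
  cfg0 <- cohort_config(n = 5, alb_sd = 0, bsa_sd = 0, tac_sd = 0)
  cov0 <- generate_covariates(cfg0, seed = 1)
  expect_equal(cov0$alb, rep(3.89, 5))
  expect_equal(cov0$tac, rep(8.29, 5))
  ## determinism
  expect_identical(generate_covariates(cfg, seed = 3),
                   generate_covariates(cfg, seed = 3))
})

test_that("generated datasets have the expected shape and pass validation", {
  pop <- refined_pop()
  cfg <- cohort_config(n = 20, n_troughs = 11)
  d <- generate_dataset(cfg, pop, seed = 8)
  expect_s3_class(d, "pk_dataset")
  expect_length(unique(d$ID), 20L)
  expect_identical(sum(d$EVID == 0), 220L)       # n * troughs
  ## doses come from the configured q12h grid
  expect_true(all(d$AMT[d$EVID == 1] %in% seq(0.25, 2.5, by = 0.25)))
  ## round-trip through the file format
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, f)
  expect_equal(as.data.frame(read_dataset(f)), as.data.frame(d),
               tolerance = 1e-12)
})

test_that("silencing all variability reproduces the typical predictions", {
  pop0 <- pop_params(omega2_cl = 0, omega2_v = 0, sigma2_prop = 1e-12)
  cfg <- cohort_config(n = 6, n_troughs = 3)
  d <- generate_dataset(cfg, pop0, seed = 4)
  df <- as.data.frame(d)
  obs <- df[df$EVID == 0, ]
  pred <- steady_state_trough(
    df$AMT[df$EVID == 1][match(obs$ID, df$ID[df$EVID == 1])], 12,
    list(cl = typical_clearance(data.frame(alb = obs$ALB, bsa = obs$BSA,
                                           tac = obs$TAC), pop0),
         v = typical_volume(data.frame(alb = obs$ALB, bsa = obs$BSA,
                                       tac = obs$TAC), pop0),
         ka = pop0$ka))
  expect_equal(obs$DV, pred, tolerance = 1e-4)
})

test_that("explicit-dose and steady-state encodings agree once equilibrated", {
  pop0 <- pop_params(omega2_cl = 0, omega2_v = 0, sigma2_prop = 1e-12)
  cfg_ss <- cohort_config(n = 4, n_troughs = 3, first_trough_day = 21)
  cfg_ex <- cohort_config(n = 4, n_troughs = 3, first_trough_day = 21,
                          ss_records = FALSE)
  d_ss <- generate_dataset(cfg_ss, pop0, seed = 9)
  d_ex <- generate_dataset(cfg_ex, pop0, seed = 9)
  y_ss <- d_ss$DV[d_ss$EVID == 0]
  y_ex <- d_ex$DV[d_ex$EVID == 0]
  expect_equal(y_ex, y_ss, tolerance = 5e-3)
})

test_that("Hardy-Weinberg chi-square matches hand calculations", {
  ## exact equilibrium proportions
  r <- hwe_chi_square(c(25, 50, 25))
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)
  expect_false(r$excluded)
  ## het deficit: expected (25, 50, 25), chi-square 1 + 2 + 1 = 4
  r2 <- hwe_chi_square(c(30, 40, 30))
  expect_equal(r2$statistic, 4, tolerance = 1e-12)
  expect_equal(r2$p_value, stats::pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(r2$p_value, 0.0455, tolerance = 1e-2)
  expect_true(r2$excluded)
  ## monomorphic variants are undefined
  expect_error(hwe_chi_square(c(0, 0, 10)), "monomorphic")
  expect_error(hwe_chi_square(c(0, 0, 0)), "positive total")
})

test_that("simulated genotypes sit at Hardy-Weinberg proportions", {
  g <- generate_genotypes(2e4, maf = 0.3, seed = 12)
  counts <- tabulate(g + 1L, nbins = 3)
  r <- hwe_chi_square(counts)
  expect_false(r$excluded)
  expect_equal(r$maf, 0.3, tolerance = 0.01)
  ## coding plugs into the screening machinery
  expect_identical(length(genotype_coding(g, "dominant")), 20000L)
})
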