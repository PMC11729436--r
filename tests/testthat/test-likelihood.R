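test_that("with no random effects the OFV is the exact normal log-density", {
  ## one subject, one steady-state trough, omega = 0: the marginal
  ## likelihood collapses to the proportional-error normal density
  pop <- pop_params(omega2_cl = 0, omega2_v = 0)
  f <- steady_state_trough(1.5, 12, list(cl = 15, v = 862, ka = 0.647))
  y <- 6.2
  d <- pk_dataset(data.frame(
    ID = "S1", TIME = c(0, 12), EVID = c(1L, 0L),
    AMT = c(1.5, NA), DV = c(NA, y), MDV = c(1L, 0L),
    SS = c(1L, 0L), II = c(12, NA), ALB = 4, BSA = 1.7, TAC = 6))
  expected <- -2 * stats::dnorm(y, f, sqrt(pop$sigma2_prop) * f, log = TRUE)
  expect_equal(neg2_loglik(d, pop), expected, tolerance = 1e-10)
  expect_equal(neg2_loglik_agq(d, pop), expected, tolerance = 1e-10)
})

test_that("independence across subjects: duplicating the data doubles the OFV", {
  d <- small_dataset(n = 6, n_troughs = 3, seed = 31)
  pop <- refined_pop()
  df <- as.data.frame(d)
  df2 <- df
  df2$ID <- paste0(df2$ID, "_copy")
  dd <- pk_dataset(rbind(df, df2))
  expect_equal(neg2_loglik(dd, pop), 2 * neg2_loglik(d, pop),
               tolerance = 1e-8)
})

test_that("mode-expansion OFV agrees with adaptive quadrature", {
  pop <- refined_pop()
  ## packaged fixture plus freshly generated small sets
  d_fix <- read_dataset(fixture_path())
  expect_lt(abs(neg2_loglik(d_fix, pop) - neg2_loglik_agq(d_fix, pop, 31)),
            0.1)
  for (seed in c(2, 3)) {
    d <- small_dataset(n = 5, n_troughs = 3, seed = seed)
    expect_lt(abs(neg2_loglik(d, pop) - neg2_loglik_agq(d, pop, 31)), 0.1)
  }
})

test_that("quadrature reference is stable in the node count", {
  pop <- refined_pop()
  d <- read_dataset(fixture_path())
  expect_lt(abs(neg2_loglik_agq(d, pop, 31) - neg2_loglik_agq(d, pop, 61)),
            0.02)
})

test_that("an uninformative covariate effect leaves the OFV unchanged", {
  d <- small_dataset(n = 8, n_troughs = 3, seed = 12)
  ## same model with the BSA exponent fixed at null vs dropping the effect
  pop0 <- pop_params(theta_cl_bsa = 0)
  ## evaluating the engine with a null coefficient must equal dropping it
  spec_full <- pk_model_spec()
  spec_drop <- pk_model_spec(covariate_effects = list(
    cov_effect("cl", "alb", "power"),
    cov_effect("cl", "tac", "exponential"),
    cov_effect("v", "alb", "power")))
  th_full <- as.list(everopk:::theta_from_pop(pop0))
  th_drop <- th_full[setdiff(names(th_full), "cl_bsa_power")]
  s_full <- everopk:::compile_pkdata(d, spec_full)
  s_drop <- everopk:::compile_pkdata(d, spec_drop)
  expect_lt(abs(everopk:::ofv_engine(s_full, th_full) -
                everopk:::ofv_engine(s_drop, th_drop)), 1e-6)
})

test_that("dose-train compilation reproduces brute-force superposition", {
  ## explicit dose history vs the same history encoded as one observation's
  ## train decomposition, including a dose change mid-history
  pop <- refined_pop()
  rows <- data.frame(
    ID = "S1",
    TIME = c(seq(0, 96, by = 12), seq(108, 180, by = 12), 190),
    EVID = c(rep(1L, 16), 0L),
    AMT = c(rep(1, 9), rep(1.75, 7), NA),
    DV = c(rep(NA, 16), 4.5), MDV = c(rep(1L, 16), 0L),
    SS = 0L, II = NA_real_, ALB = 4, BSA = 1.7, TAC = 6)
  d <- pk_dataset(rows)
  st <- everopk:::compile_pkdata(d, pk_model_spec())
  ind <- list(cl = 15, v = 862, ka = 0.647)
  f_engine <- everopk:::predict_f(st, 15, 862)$f
  dose_times <- rows$TIME[rows$EVID == 1]
  amts <- rows$AMT[rows$EVID == 1]
  f_direct <- sum(everopk:::conc_one_dose(amts, 190 - dose_times, Inf,
                                          15, 862, 0.647))
  expect_equal(f_engine, f_direct, tolerance = 1e-12)
})
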