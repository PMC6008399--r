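test_that("rate, steady state and closed form agree on hand cases", {
  st <- kinetic_state(k1 = 1, k_minus1 = 0.5, k2 = 0.5)
  expect_equal(formaldehyde_rate(1, st), 0)
  expect_equal(formaldehyde_rate(0, st), 1)
  expect_equal(formaldehyde_rate(analytic_steady_state(st), st), 0)

  expect_equal(analytic_steady_state(kinetic_state(1, 1, 0)), 1)
  expect_error(analytic_steady_state(kinetic_state(1, 0, 0)),
               "without bound")

  # F_ss = F_eq / (1 + beta) when k2[Ru5P] = beta * k_minus1[NADH]
  beta <- 0.2529
  st2 <- kinetic_state(1, 1, beta)
  expect_equal(analytic_steady_state(st2),
               analytic_steady_state(kinetic_state(1, 1, 0)) / (1 + beta),
               tolerance = 1e-12)

  # joint scaling of the rate constants leaves F_ss unchanged
  st3 <- kinetic_state(5 * 1, 5 * 1, 5 * beta)
  expect_equal(analytic_steady_state(st3), analytic_steady_state(st2),
               tolerance = 1e-12)

  # closed form boundary cases
  expect_equal(analytic_solution(st, 0, f0 = 0.3), 0.3)
  expect_equal(analytic_solution(st, 1e6), analytic_steady_state(st))
  lam <- 1  # 0.5 + 0.5
  expect_equal(analytic_solution(st, log(2) / lam),
               analytic_steady_state(st) / 2, tolerance = 1e-12)
})

test_that("both integrators track the closed form across random parameters", {
  set.seed(77)
  for (i in 1:100) {
    st <- kinetic_state(k1 = runif(1, 0.1, 5), k_minus1 = runif(1, 0.1, 3),
                        k2 = runif(1, 0, 3))
    lam <- st$k_minus1 + st$k2
    cfg <- simulation_config(dt = 0.5 / lam, t_end = 10 / lam,
                             method = "adaptive")
    tc <- simulate_formaldehyde(st, cfg)
    fss <- analytic_steady_state(st)
    err <- max(abs(tc$formaldehyde - analytic_solution(st, tc$time)))
    expect_lt(err, 1e-6 * fss)
    expect_true(all(tc$formaldehyde >= 0))
    expect_equal(utils::tail(tc$formaldehyde, 1), fss, tolerance = 0.01)
  }
})

test_that("forward Euler at the reference step stays within its truncation budget", {
  st <- kinetic_state(1, 1, 0.25)
  lam <- 1.25
  tc <- simulate_formaldehyde(st, simulation_config(dt = 0.002,
                                                    t_end = 5 / lam))
  at_end <- utils::tail(tc$formaldehyde, 1)
  expect_equal(at_end, analytic_solution(st, utils::tail(tc$time, 1)),
               tolerance = 0.005)

  expect_error(
    simulate_formaldehyde(kinetic_state(1, 500, 600),
                          simulation_config(dt = 0.002, t_end = 1)),
    "unstable")

  # zero production gives the identically-zero trace
  tc0 <- simulate_formaldehyde(kinetic_state(0, 1, 1),
                               simulation_config(dt = 0.01, t_end = 1))
  expect_true(all(tc0$formaldehyde == 0))
})

test_that("simulated steady states match the closed form across a sweep", {
  set.seed(91)
  for (i in 1:20) {
    st <- kinetic_state(runif(1, 0.5, 2), runif(1, 0.2, 2), runif(1, 0.2, 2))
    lam <- st$k_minus1 + st$k2
    tc <- simulate_formaldehyde(st, simulation_config(dt = 0.2 / lam,
                                                      t_end = 12 / lam,
                                                      method = "adaptive"))
    ss <- detect_steady_state(tc)
    expect_true(ss$reached)
    expect_equal(ss$value, analytic_steady_state(st), tolerance = 1e-3)
  }
})

test_that("plateau detection flags unfinished approaches", {
  st <- kinetic_state(1, 1, 0)  # lambda = 1
  mk <- function(t_end) {
    t <- seq(0, t_end, by = 0.01)
    structure(data.frame(time = t, formaldehyde = analytic_solution(st, t)),
              class = c("timecourse", "data.frame"))
  }
  early <- detect_steady_state(mk(1), window = 10)   # 63% of plateau
  expect_false(early$reached)
  late <- detect_steady_state(mk(10), window = 10)
  expect_true(late$reached)
  expect_equal(late$value, analytic_steady_state(st), tolerance = 1e-3)

  const <- data.frame(time = 1:10, formaldehyde = rep(2.5, 10))
  got <- detect_steady_state(const)
  expect_true(got$reached)
  expect_equal(got$value, 2.5)
})

test_that("enzyme dosing shows the equilibrium-regime dichotomy", {
  cfg <- simulation_config(dt = 0.05, t_end = 30, method = "adaptive")
  # identity dose
  sc0 <- enzyme_dose_scan(kinetic_state(1, 1, 1), 1, cfg)
  expect_equal(sc0$flux_summary$hps_flux_gain, 1.0, tolerance = 1e-12)
  expect_equal(sc0$baseline$formaldehyde, sc0$dosed$formaldehyde,
               tolerance = 1e-9)

  # closed-form gain: c(k-1 B + k2 C) / (c k-1 B + k2 C)
  gain <- function(c, rev, hps) c * (rev + hps) / (c * rev + hps)
  near <- enzyme_dose_scan(kinetic_state(1, k_minus1 = 1, k2 = 0.01), 4, cfg)
  expect_equal(near$flux_summary$hps_flux_gain, gain(4, 1, 0.01),
               tolerance = 1e-9)
  expect_lt(near$flux_summary$hps_flux_gain, 1.05)

  far <- enzyme_dose_scan(kinetic_state(1, k_minus1 = 0.01, k2 = 1), 4, cfg)
  expect_equal(far$flux_summary$hps_flux_gain, gain(4, 0.01, 1),
               tolerance = 1e-9)
  expect_gt(far$flux_summary$hps_flux_gain, 3.8)

  # k1-only scaling moves the steady state proportionally in both regimes
  k1only <- enzyme_dose_scan(kinetic_state(1, 1, 0.01), 4, cfg,
                             mode = "k1_only")
  expect_equal(k1only$flux_summary$f_ss_dosed /
                 k1only$flux_summary$f_ss_baseline, 4, tolerance = 1e-9)
})
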