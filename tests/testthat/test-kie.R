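test_that("isotope-effect constructor enforces alpha > gamma > 0", {
  eff <- isotope_effects()
  expect_equal(eff$alpha, 3.2)
  expect_equal(eff$gamma, 1.07)
  expect_error(isotope_effects(alpha = 1.0, gamma = 1.07), "alpha > gamma")
  expect_error(isotope_effects(alpha = 1.07, gamma = 1.07), "alpha > gamma")
  expect_error(isotope_effects(gamma = -1), "positive")
})

test_that("beta and the flux partition follow the closed forms", {
  eff <- isotope_effects()
  # equilibrium: no net assimilation
  expect_equal(beta_from_ratio(eff$gamma, eff), 0)
  expect_equal(forward_fraction_from_kie(eff$gamma, eff), 0.5)
  expect_equal(reversibility_ratio_from_kie(eff$gamma, eff), 1.0)
  # irreversible limit
  expect_identical(beta_from_ratio(eff$alpha, eff), Inf)
  expect_equal(forward_fraction_from_kie(eff$alpha, eff), 1.0)
  expect_identical(reversibility_ratio_from_kie(eff$alpha, eff), Inf)
  # hand arithmetic at the measured ratio
  expect_equal(beta_from_ratio(1.5, eff), (1.07 - 1.5) / (1.5 - 3.2),
               tolerance = 1e-12)
  expect_equal(beta_from_ratio(1.5, eff), 0.2529, tolerance = 1e-3)
  expect_equal(forward_fraction_from_kie(1.5, eff), 0.556, tolerance = 1e-3)
  expect_equal(percent_round(forward_fraction_from_kie(1.5, eff)), 56)
  expect_equal(reversibility_ratio_from_kie(1.5, eff), 2.13 / 1.7,
               tolerance = 1e-12)
})

test_that("the two partition forms agree exactly across the valid domain", {
  eff <- isotope_effects()
  set.seed(101)
  r <- runif(1000, eff$gamma + 1e-6, eff$alpha - 1e-6)
  for (ri in r) {
    b <- beta_from_ratio(ri, eff)
    expect_equal(forward_fraction_from_kie(ri, eff), (1 + b) / (2 + b),
                 tolerance = 1e-12)
    expect_equal(reversibility_ratio_from_kie(ri, eff), 1 + b,
                 tolerance = 1e-12)
  }
  # strictly monotone in R, mapping [gamma, alpha] onto [0.5, 1]:
  # the EIE endpoint is equilibrium (half forward), the KIE endpoint
  # fully forward
  grid <- seq(eff$gamma, eff$alpha, length.out = 200)
  ff <- vapply(grid, forward_fraction_from_kie, numeric(1), effects = eff)
  expect_true(all(diff(ff) > 0))
  expect_equal(ff[1], 0.5)
  expect_equal(ff[200], 1.0)
})

test_that("the kinetic forward model inverts beta_from_ratio", {
  eff <- isotope_effects()
  # k2 = 0: no Hps, ratio collapses to the EIE
  expect_equal(predicted_ratio_from_kinetics(kinetic_state(1, 1, 0), eff),
               eff$gamma)
  # k_minus1 = 0: irreversible Mdh, ratio equals the KIE
  expect_equal(predicted_ratio_from_kinetics(kinetic_state(1, 0, 1), eff),
               eff$alpha)
  expect_error(predicted_ratio_from_kinetics(kinetic_state(1, 0, 0), eff),
               "undefined")
  # the worked inverse pair
  st <- kinetic_state(1, 1, 0.2529412)
  expect_equal(predicted_ratio_from_kinetics(st, eff), 1.5, tolerance = 1e-6)
  # identity over a log-grid of beta
  for (b in 10^seq(-4, 4, length.out = 17)) {
    st <- kinetic_state(1, 1, b)
    r <- predicted_ratio_from_kinetics(st, eff)
    expect_equal(beta_from_ratio(r, eff), b, tolerance = 1e-10 * max(1, b))
  }
})

test_that("ratio validation distinguishes strict, clamp and boundary cases", {
  eff <- isotope_effects()
  v <- validate_ratio(3.2, eff, policy = "strict")
  expect_true("at_KIE_limit" %in% v$flags)
  expect_equal(v$ratio, 3.2)

  v2 <- validate_ratio(0.9, eff, policy = "clamp")
  expect_equal(v2$ratio, eff$gamma)
  expect_true("clamped_to_EIE" %in% v2$flags)

  v3 <- validate_ratio(2.0, eff, policy = "strict")
  expect_length(v3$flags, 0)

  expect_error(validate_ratio(0.9, eff, policy = "strict"), "admissible")
  expect_error(validate_ratio(4.0, eff, policy = "strict"), "admissible")
})

test_that("Monte-Carlo KIE partition reports intervals and clamp fractions", {
  # degenerate
  est0 <- kie_partition_with_uncertainty(ratio = 1.5, ratio_sd = 0, seed = 1)
  expect_equal(est0$forward_fraction, 0.556, tolerance = 1e-3)
  expect_equal(est0$interval[1], est0$interval[2])
  expect_identical(est0$bound_kind, "point_estimate")

  est <- kie_partition_with_uncertainty(ratio = 1.5, ratio_sd = 0.3,
                                        n_samples = 100000, seed = 7)
  expect_equal(est$forward_fraction, 0.556, tolerance = 1e-3)
  # draws below the EIE clamp to exactly 0.5, so the lower percentile
  # may sit on the boundary
  expect_gte(est$interval[1], 0.50)
  expect_lt(est$interval[1], 0.54)
  expect_gt(est$interval[2], 0.58)
  expect_lt(est$interval[2], 0.66)

  # boundary measurement: half the draws clamp at the KIE
  estb <- kie_partition_with_uncertainty(ratio = 3.2, ratio_sd = 0.4,
                                         n_samples = 100000, seed = 7)
  expect_equal(estb$forward_fraction, 1.0)
  expect_equal(attr(estb, "clamp_fraction"), 0.5, tolerance = 0.02)

  # reproducibility under the seed
  est2 <- kie_partition_with_uncertainty(ratio = 1.5, ratio_sd = 0.3,
                                         n_samples = 100000, seed = 7)
  expect_identical(est$interval, est2$interval)

  # paired-concentration entry agrees with the ratio entry at zero noise
  estp <- kie_partition_with_uncertainty(f_ss_h = 45, f_ss_d = 30, seed = 1)
  expect_equal(estp$forward_fraction,
               forward_fraction_from_kie(1.5), tolerance = 1e-9)
})
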