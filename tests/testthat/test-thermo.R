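test_that("reaction quotient handles absolute, ratio-only and degenerate states", {
  unit <- concentration_state(1, 1, nad = 1, nadh = 1)
  expect_equal(reaction_quotient(unit), 1.0)

  # ratio-only form: Q = [CH2O] / ([CH3OH] * NAD:NADH)
  st <- concentration_state(0.25, 5.0e-5, nad_ratio = 31.3)
  expect_equal(reaction_quotient(st), 5e-5 / (0.25 * 31.3), tolerance = 1e-12)
  expect_equal(reaction_quotient(st), 6.39e-6, tolerance = 1e-3)

  zero <- concentration_state(0.25, 0, nad_ratio = 31.3)
  expect_equal(reaction_quotient(zero), 0)

  expect_error(reaction_quotient(concentration_state(0, 1, nad_ratio = 1)),
               "methanol")
  expect_error(reaction_quotient(concentration_state(1, 1, nad = 0, nadh = 1)),
               "NAD")
})

test_that("delta_g follows dG0 + RT ln Q with its sentinels", {
  expect_equal(delta_g(34.2, 1, 298), 34.2)
  # equilibrium by construction
  dg0 <- 12.3; temp <- 310.15
  expect_equal(delta_g(dg0, exp(-dg0 / (R_GAS * temp)), temp), 0,
               tolerance = 1e-12)
  # hand arithmetic: 34.2 + 0.0083145*310.15*ln(6.39e-6)
  expect_equal(delta_g(34.2, 6.39e-6, 310.15), 3.4, tolerance = 0.02)
  expect_warning(val <- delta_g(10, 0), "-Inf")
  expect_identical(val, -Inf)
  expect_error(delta_g(10, -1), "non-negative")
})

test_that("equilibrium concentration inverts delta_g and is linear in methanol", {
  st <- concentration_state(1, 0, nad = 1, nadh = 1)
  expect_equal(equilibrium_concentration(0, st, "formaldehyde"), 1.0)

  # at the solved concentration dG is zero
  st2 <- concentration_state(0.25, 0, nad_ratio = 31.3, temperature = 310.15)
  f_eq <- equilibrium_concentration(34.2, st2, "formaldehyde")
  expect_equal(f_eq, 1.35e-5, tolerance = 0.02)
  st_at <- concentration_state(0.25, f_eq, nad_ratio = 31.3,
                               temperature = 310.15)
  expect_equal(delta_g(34.2, reaction_quotient(st_at), 310.15), 0,
               tolerance = 1e-9)

  st3 <- concentration_state(0.5, 0, nad_ratio = 31.3, temperature = 310.15)
  expect_equal(equilibrium_concentration(34.2, st3, "formaldehyde"),
               2 * f_eq, tolerance = 1e-12)
})

test_that("flux-force relation and its inverse are consistent", {
  expect_equal(flux_ratio_from_dg(0), 1.0)
  expect_equal(flux_ratio_from_dg(-R_GAS * T_DEFAULT * log(3)), 3.0,
               tolerance = 1e-12)
  expect_equal(flux_ratio_from_dg(3.4, 310.15), 0.268, tolerance = 2e-3)
  # roundtrip identity over a dG grid
  dgs <- seq(-50, 50, length.out = 101)
  expect_equal(dg_from_flux_ratio(flux_ratio_from_dg(dgs)), dgs,
               tolerance = 1e-10)
  # complementary fractions
  r <- exp(seq(log(1e-3), log(1e3), length.out = 41))
  expect_equal(forward_fraction(r) + forward_fraction(1 / r), rep(1, 41),
               tolerance = 1e-12)
})

test_that("paired steady states give the printed lower bounds", {
  bound_for <- function(ratio) {
    a <- steady_state_observation(ratio * 20, 0, pathway = "mdh_only")
    b <- steady_state_observation(20, 0, pathway = "full_pathway")
    reversibility_bound(a, b, seed = 1)
  }
  expect_equal(percent_round(bound_for(1.2)$forward_fraction), 55)
  expect_equal(bound_for(3.0)$forward_fraction, 0.75)
  expect_equal(bound_for(1.0)$forward_fraction, 0.50)
  expect_equal(bound_for(4.7)$forward_fraction, 0.825, tolerance = 1e-3)
  expect_identical(bound_for(1.2)$bound_kind, "lower_bound")
})

test_that("reversibility bound applies the NAD-ratio correction and is monotone", {
  mk <- function(f, r, pathway) steady_state_observation(f, 0, r, 0,
                                                         pathway = pathway)
  # equal ratios: pure formaldehyde fold
  b1 <- reversibility_bound(mk(30, 31.3, "mdh_only"),
                            mk(10, 31.3, "full_pathway"), seed = 1)
  expect_equal(b1$flux_ratio, 3.0, tolerance = 1e-12)
  # full-pathway ratio doubled doubles the bound (correction r2/r1)
  b2 <- reversibility_bound(mk(30, 31.3, "mdh_only"),
                            mk(10, 62.6, "full_pathway"), seed = 1)
  expect_equal(b2$flux_ratio, 6.0, tolerance = 1e-12)

  # monotonicity in the fold ratio
  folds <- seq(1, 6, by = 0.5)
  ff <- vapply(folds, function(r)
    reversibility_bound(mk(r * 10, NA, "mdh_only"),
                        mk(10, NA, "full_pathway"), seed = 1)$forward_fraction,
    numeric(1))
  expect_true(all(diff(ff) > 0))

  expect_error(reversibility_bound(mk(10, NA, "full_pathway"),
                                   mk(10, NA, "mdh_only")),
               "mdh_only")
})

test_that("Monte-Carlo propagation is seeded, degenerate at zero sd, and matches the delta method", {
  # degenerate case
  p0 <- propagate_uncertainty(function(x) x^2, list(x = c(3, 0)), seed = 1)
  expect_identical(p0$interval, c(9, 9))
  expect_identical(p0$sd, 0)

  fn <- function(r) r / (1 + r)
  p1 <- propagate_uncertainty(fn, list(r = c(1.2, 0.1)),
                              n_samples = 100000, seed = 42)
  p2 <- propagate_uncertainty(fn, list(r = c(1.2, 0.1)),
                              n_samples = 100000, seed = 42)
  expect_identical(p1$interval, p2$interval)
  expect_equal(p1$point, 0.5454545, tolerance = 1e-6)
  expect_true(p1$interval[1] < 0.5454545 && p1$interval[2] > 0.5454545)
  half_width <- diff(p1$interval) / 2
  expect_gt(half_width, 0.02)
  expect_lt(half_width, 0.06)
  # delta method agrees to first order: d/dr [r/(1+r)] = 1/(1+r)^2
  expect_equal(p1$delta_sd, 0.1 / (1 + 1.2)^2, tolerance = 1e-4)
  expect_equal(p1$sd, p1$delta_sd, tolerance = 0.05)

  # undefined on most draws -> error
  expect_error(
    propagate_uncertainty(function(x) {
      o <- rep(NaN, length(x)); o[x > 0] <- log(x[x > 0]); o
    }, list(x = c(0.0001, 10)), n_samples = 2000, seed = 1),
    "50%")
})

test_that("capped sentinel is reported when the full-pathway level is zero", {
  a <- steady_state_observation(50, 0, pathway = "mdh_only")
  b <- steady_state_observation(1e-12, 0, pathway = "full_pathway")
  # formally huge but finite bound still works
  expect_gt(reversibility_bound(a, b, seed = 1)$flux_ratio, 1e10)
})
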