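paper_levels <- c(6, 12, 35, 70, 150, 300)

test_that("noiseless Michaelis-Menten data are recovered exactly", {
  v <- 1 * paper_levels / (35 + paper_levels)
  fit <- fit_michaelis_menten(paper_levels, v)
  expect_equal(fit$vmax, 1, tolerance = 1e-8)
  expect_equal(fit$km, 35, tolerance = 1e-8)
  # fitted curve at S = Km gives Vmax / 2
  expect_equal(fit$vmax * fit$km / (fit$km + fit$km), fit$vmax / 2)
  expect_error(fit_michaelis_menten(c(1, 1, 1), c(1, 1, 1)), "distinct")
})

test_that("MM fitting is scale-equivariant in velocity", {
  set.seed(5)
  v <- 2 * paper_levels / (50 + paper_levels) + rnorm(6, 0, 0.02)
  f1 <- fit_michaelis_menten(paper_levels, v)
  f2 <- fit_michaelis_menten(paper_levels, 10 * v)
  expect_equal(f2$vmax, 10 * f1$vmax, tolerance = 1e-6)
  expect_equal(f2$km, f1$km, tolerance = 1e-6)
})

test_that("confidence intervals achieve near-nominal coverage", {
  vmax_true <- 1; km_true <- 35
  n_trials <- 500
  covered <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    d <- generate_mm_assay(vmax_true, km_true, noise_sd = 0.05,
                           n_replicates = 3, seed = 1000 + i)
    fit <- tryCatch(fit_michaelis_menten(d$substrate, d$velocity),
                    error = function(e) NULL)
    covered[i] <- !is.null(fit) &&
      fit$vmax_ci[1] <= vmax_true && vmax_true <= fit$vmax_ci[2] &&
      fit$km_ci[1] <= km_true && km_true <= fit$km_ci[2]
  }
  expect_gte(mean(covered), 0.90)
})

test_that("paired H/D plates recover the kinetic isotope effect", {
  # exact construction
  vh <- 3.2 * paper_levels / (35 + paper_levels)
  vd <- 1.0 * paper_levels / (35 + paper_levels)
  fit_h <- fit_michaelis_menten(paper_levels, vh)
  fit_d <- fit_michaelis_menten(paper_levels, vd)
  k <- kie_from_paired_fits(fit_h, fit_d, seed = 1)
  expect_equal(k$alpha, 3.2, tolerance = 1e-6)
  # reciprocity
  k_inv <- kie_from_paired_fits(fit_d, fit_h, seed = 1)
  expect_equal(k$alpha * k_inv$alpha, 1.0, tolerance = 1e-10)

  # noisy recovery: truth inside the Monte-Carlo CI
  dh <- generate_mm_assay(3.2, 35, noise_sd = 0.05, n_replicates = 3,
                          isotope = "H", seed = 21)
  dd <- generate_mm_assay(1.0, 35, noise_sd = 0.05, n_replicates = 3,
                          isotope = "D", seed = 22)
  kf <- kie_from_paired_fits(fit_michaelis_menten(dh$substrate, dh$velocity),
                             fit_michaelis_menten(dd$substrate, dd$velocity),
                             seed = 3)
  expect_gt(3.2, kf$ci[1])
  expect_lt(3.2, kf$ci[2])
  expect_lt(diff(kf$ci), 2.6)  # same order as the reported +/- 1.3

  # identical fits give alpha = 1
  expect_equal(kie_from_paired_fits(fit_h, fit_h, seed = 1)$alpha, 1.0)
})

test_that("Nash calibration and quantification invert each other", {
  std <- generate_nash_standards(slope = 0.012, intercept = 0.04,
                                 noise_sd = 0)
  cal <- fit_nash_calibration(std$concentration_uM, std$a412)
  expect_equal(cal$slope, 0.012, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1.0)

  # standards fed back through their own curve
  q <- nash_quantify(std$a412, cal)
  expect_equal(q$concentration_uM, std$concentration_uM, tolerance = 1e-9)

  # blank reads 0, midpoint reads 50
  mid <- (cal$intercept + (cal$intercept + cal$slope * 100)) / 2
  expect_equal(nash_quantify(mid, cal)$concentration_uM, 50)
  blank <- nash_quantify(cal$intercept - 0.01, cal)
  expect_equal(blank$concentration_uM, 0)
  expect_equal(blank$flag, "floored_at_zero")
  high <- nash_quantify(cal$intercept + cal$slope * 150, cal)
  expect_equal(high$flag, "above_calibrated_range")

  # noisy standards recovered within residual noise
  stdn <- generate_nash_standards(slope = 0.012, intercept = 0.04,
                                  noise_sd = 0.005, seed = 9)
  caln <- fit_nash_calibration(stdn$concentration_uM, stdn$a412)
  qn <- nash_quantify(stdn$a412, caln)
  expect_lt(max(abs(qn$concentration_uM - stdn$concentration_uM)),
            4 * 0.005 / caln$slope)

  expect_error(fit_nash_calibration(c(0, 50, 100), c(1, 0.5, 0)), "slope")
})

test_that("initial rates convert absorbance slopes to concentrations", {
  # flat trace
  flat <- rate_from_absorbance(0:9, rep(0.1, 10))
  expect_equal(flat$rate_uM_per_min, 0)
  # Beer-Lambert arithmetic: 0.0622 AU/min over 6220 M-1 cm-1 = 10 uM/min
  r <- rate_from_absorbance(0:10, 0.1 + 0.0622 * (0:10))
  expect_equal(r$rate_uM_per_min, 10, tolerance = 1e-9)
  # trace that goes flat after substrate exhaustion: only the linear
  # prefix is used
  t <- seq(0, 10, by = 0.5)
  a <- pmin(0.05 * t, 0.25)
  rs <- rate_from_absorbance(t, a)
  expect_lt(length(rs$window), length(t))
  expect_equal(rs$rate_uM_per_min, 0.05 / 6220 * 1e6, tolerance = 0.05)
  # standard-curve mode matches extinction mode on a perfect line
  curve <- fit_nash_calibration(c(0, 50, 100),
                                6220 / 1e6 * c(0, 50, 100) + 0.01)
  r2 <- rate_from_absorbance(0:10, 0.1 + 0.0622 * (0:10),
                             standard_curve = curve)
  expect_equal(r2$rate_uM_per_min, 10, tolerance = 1e-6)
  expect_error(rate_from_absorbance(0:1, c(0, 1)), "at least 3")
})

test_that("expression and inhibition summaries follow their definitions", {
  expect_equal(soluble_fraction(1, 1, 10, 0), 100)
  expect_equal(soluble_fraction(1, 1, 25, 25), 50)
  expect_equal(soluble_fraction(2, 1, 10, 40), 100 * 0.2 / 0.6,
               tolerance = 1e-12)
  expect_error(soluble_fraction(1, 1, 0, 0), "undefined")

  expect_equal(fractional_inhibition(2, 2), 0)
  expect_equal(fractional_inhibition(2, 1), 50)
  expect_equal(fractional_inhibition(2, 0), 100)
  expect_error(fractional_inhibition(0, 1), "positive")
})
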