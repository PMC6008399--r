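# Michaelis-Menten fitting for Mdh assays, the paired H/D KIE from fits,
# Nash-assay calibration and quantification, initial-rate extraction from
# A340 traces, and expression/inhibition summaries.

#' Fit the Michaelis-Menten model to an initial-rate dataset
#'
#' Least-squares fit of v = Vmax S / (Km + S) by Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]), started from a Lineweaver-Burk seed with a
#' small grid of fallback starts so the fit is deterministic given the
#' data. Confidence intervals are t-based from the asymptotic covariance
#' at the optimum (the classical nlinfit/nlparci contract).
#'
#' @param substrate Substrate concentrations (mM), >= 3 distinct levels.
#' @param velocity Observed initial rates, same length.
#' @param ci_level Confidence level, default 0.95.
#' @return Object of class `mm_fit`: `vmax`, `km`, `vmax_ci`, `km_ci`,
#'   `sigma`, `df`, `cov`, `converged`, `flags`.
#' @examples
#' s <- c(6, 12, 35, 70, 150, 300)
#' v <- 1 * s / (35 + s)
#' fit_michaelis_menten(s, v)
#' @export
fit_michaelis_menten <- function(substrate, velocity, ci_level = 0.95) {
  stopifnot(length(substrate) == length(velocity))
  if (any(substrate < 0)) stop("substrate concentrations must be non-negative")
  if (length(unique(substrate)) < 3)
    stop("need at least 3 distinct substrate levels")
  dat <- data.frame(s = substrate, v = velocity)

  # Lineweaver-Burk seed on strictly positive rates
  pos <- dat$v > 0 & dat$s > 0
  starts <- list()
  if (sum(pos) >= 2) {
    lb <- stats::lm(I(1 / v) ~ I(1 / s), data = dat[pos, ])
    vmax0 <- 1 / stats::coef(lb)[1]
    km0 <- stats::coef(lb)[2] * vmax0
    if (is.finite(vmax0) && vmax0 > 0 && is.finite(km0) && km0 > 0)
      starts <- list(c(vmax = unname(vmax0), km = unname(km0)))
  }
  starts <- c(starts, list(
    c(vmax = max(dat$v), km = stats::median(dat$s)),
    c(vmax = 2 * max(dat$v), km = max(dat$s)),
    c(vmax = max(dat$v), km = min(dat$s[dat$s > 0]))))

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ vmax * s / (km + s), data = dat,
                        start = as.list(st),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12)
        best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop("Michaelis-Menten fit failed to converge from all starting values; ",
         "check that velocities saturate with substrate")

  fit <- best$fit
  est <- stats::coef(fit)
  df <- length(dat$v) - 2L
  sigma <- sqrt(best$rss / max(df, 1L))
  covm <- tryCatch(stats::vcov(fit), error = function(e)
    matrix(NA_real_, 2, 2, dimnames = list(names(est), names(est))))
  se <- sqrt(diag(covm))
  tcrit <- stats::qt(1 - (1 - ci_level) / 2, df)
  flags <- character()
  if (any(est <= 0)) flags <- c(flags, "nonpositive_parameter")

  structure(
    list(vmax = unname(est["vmax"]), km = unname(est["km"]),
         vmax_ci = unname(est["vmax"] + c(-1, 1) * tcrit * se["vmax"]),
         km_ci = unname(est["km"] + c(-1, 1) * tcrit * se["km"]),
         sigma = sigma, df = df, cov = covm, ci_level = ci_level,
         converged = TRUE, flags = flags, n = length(dat$v)),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit (n = %d):\n", x$n))
  cat(sprintf("  Vmax = %.4g  [%.4g, %.4g]\n", x$vmax, x$vmax_ci[1], x$vmax_ci[2]))
  cat(sprintf("  Km   = %.4g mM  [%.4g, %.4g]\n", x$km, x$km_ci[1], x$km_ci[2]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Kinetic isotope effect from paired H/D Michaelis-Menten fits
#'
#' alpha = Vmax_H / Vmax_D, the single k_H/k_D a Michaelis plot with
#' protonated versus deuterated substrate yields. The confidence
#' interval propagates both fit covariances by seeded Monte-Carlo
#' sampling of the (vmax, km) estimates. A per-substrate-level velocity
#' ratio diagnostic is attached (`ratio_by_level`) to reveal any Km
#' isotope effect the Vmax ratio would hide.
#'
#' @param fit_h,fit_d `mm_fit` objects for CH3OH and CD3OD.
#' @param n_samples,seed Monte-Carlo controls.
#' @param substrate_levels Optional levels at which to evaluate the
#'   fitted-velocity ratio diagnostic.
#' @return List of class `kie_fit`: `alpha`, `ci`, `sd`, `ratio_by_level`.
#' @export
kie_from_paired_fits <- function(fit_h, fit_d, n_samples = 10000, seed = 1L,
                                 substrate_levels = c(6, 12, 35, 70, 150, 300)) {
  stopifnot(inherits(fit_h, "mm_fit"), inherits(fit_d, "mm_fit"))
  if (!fit_h$converged || !fit_d$converged) stop("both fits must have converged")
  if (fit_d$vmax_ci[1] <= 0 && fit_d$vmax_ci[2] >= 0)
    stop("Vmax_D confidence interval spans zero; the KIE ratio is unstable")

  alpha <- fit_h$vmax / fit_d$vmax

  ok_cov <- !anyNA(fit_h$cov) && !anyNA(fit_d$cov)
  if (ok_cov && (fit_h$sigma > 0 || fit_d$sigma > 0)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
    dh <- MASS::mvrnorm(n_samples, c(fit_h$vmax, fit_h$km), fit_h$cov)
    dd <- MASS::mvrnorm(n_samples, c(fit_d$vmax, fit_d$km), fit_d$cov)
    ratios <- dh[, 1] / dd[, 1]
    ratios <- ratios[is.finite(ratios) & ratios > 0]
    ci <- unname(stats::quantile(ratios, c(0.025, 0.975)))
    sdr <- stats::sd(ratios)
  } else {
    ci <- c(alpha, alpha); sdr <- 0
  }

  mm <- function(f, s) f$vmax * s / (f$km + s)
  structure(
    list(alpha = alpha, ci = ci, sd = sdr,
         ratio_by_level = data.frame(
           substrate = substrate_levels,
           velocity_ratio = mm(fit_h, substrate_levels) /
                            mm(fit_d, substrate_levels))),
    class = "kie_fit"
  )
}

#' @export
print.kie_fit <- function(x, ...) {
  cat(sprintf("KIE from paired fits: alpha = %.3g [%.3g, %.3g]\n",
              x$alpha, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Fit a Nash-assay calibration curve
#'
#' Ordinary least squares of A412 on formaldehyde standard
#' concentration. The intercept is free by default (blank wells drift
#' day to day); forcing through the origin is available but flagged.
#'
#' @param concentration_uM Standard concentrations (uM), >= 3 values.
#' @param a412 Absorbance readings, same length.
#' @param force_origin Fit without intercept (flagged in the result).
#' @return Object of class `calibration_curve`: `slope`, `intercept`,
#'   `r_squared`, `range_uM`, `residual_sd`, `flags`.
#' @export
fit_nash_calibration <- function(concentration_uM, a412, force_origin = FALSE) {
  stopifnot(length(concentration_uM) == length(a412))
  if (length(unique(concentration_uM)) < 3)
    stop("calibration needs at least 3 distinct standards")
  flags <- character()
  if (force_origin) {
    fit <- stats::lm(a412 ~ concentration_uM + 0)
    slope <- unname(stats::coef(fit)[1]); intercept <- 0
    flags <- "forced_through_origin"
  } else {
    fit <- stats::lm(a412 ~ concentration_uM)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
  }
  if (slope <= 0) stop("invalid calibration: non-positive slope")
  sm <- suppressWarnings(summary(fit))  # perfect synthetic standards warn
  structure(
    list(slope = slope, intercept = intercept,
         r_squared = sm$r.squared,
         range_uM = range(concentration_uM),
         residual_sd = sm$sigma,
         flags = flags),
    class = "calibration_curve"
  )
}

#' Quantify formaldehyde from Nash-assay absorbance
#'
#' Inverts the calibration line: conc = (A412 - intercept) / slope.
#' Negative results (blank noise) are floored at zero and flagged;
#' readings above the calibrated range are flagged as extrapolation.
#'
#' @param a412 Absorbance vector.
#' @param curve A [fit_nash_calibration()] result.
#' @return Data frame with `concentration_uM` and `flag` per reading.
#' @export
nash_quantify <- function(a412, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  conc <- (a412 - curve$intercept) / curve$slope
  flag <- rep("", length(conc))
  flag[conc < 0] <- "floored_at_zero"
  flag[conc > curve$range_uM[2]] <- "above_calibrated_range"
  conc[conc < 0] <- 0
  data.frame(concentration_uM = conc, flag = flag,
             stringsAsFactors = FALSE)
}

#' Initial rate from an A340 trace
#'
#' Selects the initial linear segment (longest prefix whose linear fit
#' has r^2 >= `min_r2`, minimum `min_points` points), fits its slope,
#' and converts absorbance per minute to NADH production in uM min-1.
#' Two conversion modes: Beer-Lambert with the NADH extinction
#' coefficient, or an empirical NADH standard curve (a
#' `calibration_curve` with slope in AU per uM).
#'
#' @param time_min Time points (minutes).
#' @param a340 Absorbance at 340 nm, same length.
#' @param extinction NADH molar extinction coefficient (M-1 cm-1),
#'   default 6220.
#' @param path Optical path length (cm), default 1.
#' @param standard_curve Optional `calibration_curve` for standard-curve
#'   mode (overrides Beer-Lambert conversion).
#' @param min_r2,min_points Linear-window selection controls.
#' @return List: `rate_uM_per_min`, `slope_au_per_min`, `window`
#'   (indices used), `r_squared`.
#' @export
rate_from_absorbance <- function(time_min, a340, extinction = 6220, path = 1,
                                 standard_curve = NULL,
                                 min_r2 = 0.99, min_points = 4) {
  stopifnot(length(time_min) == length(a340))
  n <- length(a340)
  if (n < 3) stop("need at least 3 points in the trace")
  min_points <- max(3, min_points)

  # longest prefix passing the linearity criterion
  best_end <- NA_integer_
  for (end in seq(min(min_points, n), n)) {
    flat <- stats::sd(a340[1:end]) < 1e-12
    r2 <- if (flat) 1 else {
      f <- stats::lm(a340[1:end] ~ time_min[1:end])
      suppressWarnings(summary(f)$r.squared)  # perfect fits warn
    }
    if (flat || r2 >= min_r2) best_end <- end else break
  }
  if (is.na(best_end)) {
    best_end <- min_points
    warning("no prefix met the linearity criterion; using the first ",
            best_end, " points")
  }
  seg <- 1:best_end
  f <- stats::lm(a340[seg] ~ time_min[seg])
  slope <- unname(stats::coef(f)[2])
  r2 <- if (stats::sd(a340[seg]) < 1e-12) 1 else
    suppressWarnings(summary(f)$r.squared)

  if (!is.null(standard_curve)) {
    stopifnot(inherits(standard_curve, "calibration_curve"))
    rate <- slope / standard_curve$slope  # AU/min over AU/uM
  } else {
    rate <- slope / (extinction * path) * 1e6  # M/min -> uM/min
  }
  list(rate_uM_per_min = rate, slope_au_per_min = slope,
       window = seg, r_squared = r2)
}

#' Soluble enzyme fraction from fractionated expression analysis
#'
#' Combines total protein in the soluble and insoluble lysate fractions
#' with the densitometric band percentage attributed to the enzyme in
#' each:
#' %soluble = 100 P_s f_s / (P_s f_s + P_i f_i).
#'
#' @param protein_s,protein_i Total protein in the soluble and insoluble
#'   fractions (any shared unit).
#' @param pct_s_mdh,pct_i_mdh Band percentages (0-100) in each fraction.
#' @return Percentage of the enzyme that is soluble.
#' @export
soluble_fraction <- function(protein_s, protein_i, pct_s_mdh, pct_i_mdh) {
  if (any(c(protein_s, protein_i) < 0)) stop("protein amounts must be >= 0")
  if (any(c(pct_s_mdh, pct_i_mdh) < 0 | c(pct_s_mdh, pct_i_mdh) > 100))
    stop("band percentages must lie in [0, 100]")
  num <- protein_s * pct_s_mdh
  den <- num + protein_i * pct_i_mdh
  if (den == 0) stop("undefined: no enzyme detected in either fraction")
  100 * num / den
}

#' Fractional inhibition of an activity
#'
#' 100 (1 - v_treated / v_control).
#'
#' @param v_control Control rate (> 0).
#' @param v_treated Treated rate.
#' @return Percent inhibition.
#' @export
fractional_inhibition <- function(v_control, v_treated) {
  if (any(v_control <= 0)) stop("control rate must be positive")
  100 * (1 - v_treated / v_control)
}
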