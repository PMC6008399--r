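# Seeded synthetic-data generators with known ground truth for every
# analysis stage: paired H/D formaldehyde timecourses, steady-state
# observation tables (including the bundled in-study fixture), plate
# assays, Nash standards, and mass-isotopomer distributions.
#
# All noise is multiplicative log-normal parameterised by a CV:
# concentration readings are positive and CV-dominated, so additive
# gaussian noise would misbehave near zero. Every generator is a pure
# function of its seed.

# log-normal multiplicative noise with unit mean and the given CV
.lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Ground truth for a paired H/D isotope experiment
#'
#' Converts a chosen forward-flux fraction f in (0.5, 1) into the
#' consistent beta = (2f - 1) / (1 - f) and a mass-action kinetic state
#' realising it, with k2\[Ru5P\] = beta k-1\[NADH\]. The deuterated
#' channel constants follow the isotope-effect relations
#' k1D = k1H / alpha and k-1D = gamma k-1H / alpha.
#'
#' @param forward_fraction True forward fraction, strictly inside
#'   (0.5, 1).
#' @param effects [isotope_effects()].
#' @param k1,k_minus1 H-channel rate constants (dimensionless defaults).
#' @return List of class `ground_truth`: `forward_fraction`, `beta`,
#'   `ratio` (noise-free R_H/D), `state_h`, `state_d`, `effects`.
#' @export
ground_truth <- function(forward_fraction, effects = isotope_effects(),
                         k1 = 1, k_minus1 = 1) {
  if (forward_fraction <= 0.5 || forward_fraction >= 1)
    stop("forward_fraction must lie strictly inside (0.5, 1)")
  beta <- (2 * forward_fraction - 1) / (1 - forward_fraction)
  state_h <- kinetic_state(k1 = k1, k_minus1 = k_minus1, k2 = beta * k_minus1)
  state_d <- kinetic_state(k1 = k1 / effects$alpha,
                           k_minus1 = effects$gamma * k_minus1 / effects$alpha,
                           k2 = beta * k_minus1)
  structure(list(forward_fraction = forward_fraction, beta = beta,
                 ratio = (effects$gamma + effects$alpha * beta) / (1 + beta),
                 state_h = state_h, state_d = state_d, effects = effects),
            class = "ground_truth")
}

#' Generate a paired H/D formaldehyde steady-state experiment
#'
#' Simulates the protonated and deuterated channels of the mass-action
#' formaldehyde balance to (effective) steady state, samples the traces
#' at `n_times` points, and applies multiplicative log-normal noise per
#' replicate. The attached truth record makes end-to-end parameter
#' recovery testable: with zero noise, the plateau ratio equals the
#' analytic R_H/D and the KIE inversion returns `forward_fraction`
#' exactly.
#'
#' @param truth A [ground_truth()].
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param n_replicates Replicates per channel.
#' @param n_times Sampling points per trace.
#' @param t_end Duration in units of 1/lambda_D (the slower channel);
#'   default 12 guarantees both channels plateau.
#' @param seed Integer seed.
#' @return List of class `paired_kie_experiment`: `h` and `d` (long-form
#'   data frames time/replicate/formaldehyde), `truth`, `seed`.
#' @export
generate_paired_kie_experiment <- function(truth, noise_cv = 0.05,
                                           n_replicates = 3, n_times = 40,
                                           t_end = 12, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  lam_d <- .loss_rate(truth$state_d)
  lam_h <- .loss_rate(truth$state_h)
  horizon <- t_end / min(lam_d, lam_h)
  sample_channel <- function(state) {
    cfg <- simulation_config(dt = horizon / n_times, t_end = horizon,
                             method = "adaptive")
    tc <- simulate_formaldehyde(state, cfg)
    do.call(rbind, lapply(seq_len(n_replicates), function(rep) {
      data.frame(time = tc$time, replicate = rep,
                 formaldehyde = tc$formaldehyde *
                   .lnorm_noise(nrow(tc), noise_cv))
    }))
  }
  structure(list(h = sample_channel(truth$state_h),
                 d = sample_channel(truth$state_d),
                 truth = truth, noise_cv = noise_cv, seed = seed),
            class = "paired_kie_experiment")
}

#' Recover the forward-flux fraction from a paired experiment
#'
#' Averages the plateau of each channel (trailing `plateau_fraction` of
#' the sampled points, across replicates), forms R_H/D, and inverts the
#' isotope-effect relation with the clamp policy.
#'
#' @param experiment A [generate_paired_kie_experiment()] result.
#' @param plateau_fraction Trailing fraction of points treated as
#'   plateau.
#' @return List: `ratio`, `forward_fraction`, `flags`.
#' @export
recover_forward_fraction <- function(experiment, plateau_fraction = 0.25) {
  stopifnot(inherits(experiment, "paired_kie_experiment"))
  plateau_mean <- function(df) {
    tmax <- max(df$time)
    mean(df$formaldehyde[df$time >= tmax * (1 - plateau_fraction)])
  }
  r <- plateau_mean(experiment$h) / plateau_mean(experiment$d)
  v <- validate_ratio(r, experiment$truth$effects, policy = "clamp")
  list(ratio = r,
       forward_fraction = forward_fraction_from_kie(
         v$ratio, experiment$truth$effects, policy = "clamp"),
       flags = v$flags)
}

#' Bundled steady-state observation fixture
#'
#' The printed steady-state formaldehyde observations of the source
#' study, one row per strain/condition/isotope in the observation-table
#' schema consumed by [run_reversibility_analysis()]. Printed values are
#' used verbatim (e.g. 52 +/- 1 and 17 +/- 1.5 uM for the IA + glpX
#' pair); where one member of a pair was not printed it is derived from
#' the printed fold ratio (full-pathway "none" = 56 / 1.2; Mdh-only
#' "xylose" = 7.5 * 4.7), so every printed fold is reproduced exactly.
#' Deuterated-channel rows encode the printed H/D ratios (1.5 for
#' "none", 3.2 for "IA + glpX"); the xylose D channel is NA — the
#' concentrations were too low to measure — and downstream analysis must
#' mark it indeterminate rather than impute.
#'
#' @return Data frame with columns condition, pathway, isotope,
#'   formaldehyde_uM, formaldehyde_sd_uM, nad_ratio, nad_ratio_sd,
#'   n_replicates.
#' @export
steady_state_fixture <- function() {
  utils::read.csv(system.file("extdata", "steady_state_observations.csv",
                              package = "mdhflux"),
                  stringsAsFactors = FALSE)
}

#' Generate (or echo) a steady-state observation table
#'
#' With `conditions = NULL` returns the bundled fixture. Otherwise
#' builds a table from a list of condition specs, each a list with
#' `condition`, `f_mdh`, `f_full`, optional sds, `nad_ratio`, and
#' optional `hd_ratio` (encoded as a deuterated full-pathway row).
#'
#' @param conditions `NULL` or a list of condition specs.
#' @param path Optional path; when given the table is also written as
#'   CSV.
#' @return The observation data frame.
#' @export
generate_steady_state_table <- function(conditions = NULL, path = NULL) {
  if (is.null(conditions)) {
    tab <- steady_state_fixture()
  } else {
    rows <- lapply(conditions, function(cs) {
      stopifnot(!is.null(cs$condition), !is.null(cs$f_mdh), !is.null(cs$f_full))
      nr <- if (is.null(cs$nad_ratio)) NA_real_ else cs$nad_ratio
      base <- data.frame(
        condition = cs$condition,
        pathway = c("mdh_only", "full_pathway"),
        isotope = "H",
        formaldehyde_uM = c(cs$f_mdh, cs$f_full),
        formaldehyde_sd_uM = c(cs$f_mdh_sd %||% 0, cs$f_full_sd %||% 0),
        nad_ratio = nr, nad_ratio_sd = NA_real_,
        n_replicates = cs$n_replicates %||% 3,
        stringsAsFactors = FALSE)
      if (!is.null(cs$hd_ratio)) {
        base <- rbind(base, data.frame(
          condition = cs$condition, pathway = "full_pathway", isotope = "D",
          formaldehyde_uM = cs$f_full / cs$hd_ratio,
          formaldehyde_sd_uM = cs$f_d_sd %||% 0,
          nad_ratio = nr, nad_ratio_sd = NA_real_,
          n_replicates = cs$n_replicates %||% 3,
          stringsAsFactors = FALSE))
      }
      base
    })
    tab <- do.call(rbind, rows)
  }
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a Michaelis-Menten assay plate
#'
#' @param vmax,km True parameters (Km in mM).
#' @param substrate Substrate levels (mM); default the six methanol
#'   concentrations of the standard assay.
#' @param noise_sd Additive gaussian noise sd on velocities, as a
#'   fraction of `vmax`.
#' @param n_replicates Replicates per level.
#' @param isotope Label recorded in the output (`"H"` or `"D"`).
#' @param seed Integer seed.
#' @return Data frame substrate/velocity/replicate/isotope.
#' @export
generate_mm_assay <- function(vmax, km,
                              substrate = c(6, 12, 35, 70, 150, 300),
                              noise_sd = 0, n_replicates = 1,
                              isotope = "H", seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  s <- rep(substrate, times = n_replicates)
  v <- vmax * s / (km + s) + stats::rnorm(length(s), 0, noise_sd * vmax)
  data.frame(substrate = s,
             velocity = v,
             replicate = rep(seq_len(n_replicates), each = length(substrate)),
             isotope = isotope,
             stringsAsFactors = FALSE)
}

#' Generate a Nash-assay standard series
#'
#' @param concentration_uM Standard concentrations; default 0-100 uM in
#'   the usual daily-calibration range.
#' @param slope,intercept True line (AU per uM, AU).
#' @param noise_sd Additive gaussian noise on absorbance (AU).
#' @param seed Integer seed.
#' @return Data frame concentration_uM/a412.
#' @export
generate_nash_standards <- function(concentration_uM = seq(0, 100, by = 12.5),
                                    slope = 0.01, intercept = 0.05,
                                    noise_sd = 0, seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  data.frame(
    concentration_uM = concentration_uM,
    a412 = intercept + slope * concentration_uM +
      stats::rnorm(length(concentration_uM), 0, noise_sd))
}

#' Generate a measured mass-isotopomer distribution
#'
#' Convolves a true label-count profile with natural abundance (and
#' optionally tracer impurity), applies multiplicative noise, and
#' renormalises — emulating an LC-MS MID measurement with known truth.
#'
#' @param profile True label-count fractions M+0..M+n (normalised
#'   internally).
#' @param abundance_13c Natural 13C abundance (0 disables convolution).
#' @param purity Tracer purity.
#' @param noise_cv CV of multiplicative noise on measured fractions.
#' @param metabolite Label.
#' @param seed Integer seed.
#' @return A [mass_distribution()] with attribute `truth` (the input
#'   profile as a `mass_distribution`).
#' @export
generate_mid <- function(profile, abundance_13c = 0.0107, purity = 1,
                         noise_cv = 0, metabolite = "F6P", seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  truth <- mass_distribution(profile, metabolite = metabolite)
  measured <- convolve_natural_abundance(truth, abundance_13c, purity)
  noisy <- measured$fractions * .lnorm_noise(length(measured$fractions), noise_cv)
  out <- mass_distribution(noisy, truth$n_carbons, metabolite)
  attr(out, "truth") <- truth
  out
}
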