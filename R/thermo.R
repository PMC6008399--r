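# Gibbs-energy arithmetic for the Mdh reaction
#   CH3OH + NAD+  ->  CH2O + NADH + H+
# and the paired-steady-state reversibility bound.

#' Gas constant in kJ mol-1 K-1
#'
#' @format Length-one numeric, 8.3145e-3 kJ mol-1 K-1.
#' @export
R_GAS <- 8.3145e-3

#' Default assay temperature (37 degrees C) in kelvin
#' @format Length-one numeric, 310.15 K.
#' @export
T_DEFAULT <- 310.15

#' Concentration state entering the Mdh reaction quotient
#'
#' Bundles the molar concentrations of methanol, formaldehyde, NAD+ and
#' NADH at a given temperature. The cofactors may be supplied either as
#' absolute concentrations (`nad`, `nadh`) or only as the NAD:NADH ratio
#' (`nad_ratio`), which is all the in vivo measurements provide; in the
#' latter case absolute cofactor values are flagged unknown and every
#' downstream computation uses the ratio only.
#'
#' @param methanol Methanol concentration (M).
#' @param formaldehyde Formaldehyde concentration (M).
#' @param nad,nadh Absolute cofactor concentrations (M), or `NULL` when
#'   only the ratio is known.
#' @param nad_ratio NAD:NADH ratio (dimensionless). Ignored when `nad`
#'   and `nadh` are both given.
#' @param temperature Temperature in kelvin. Default 310.15 K (37 C).
#' @return An object of class `concentration_state`.
#' @examples
#' concentration_state(methanol = 0.25, formaldehyde = 5e-5,
#'                     nad_ratio = 31.3)
#' @export
concentration_state <- function(methanol, formaldehyde,
                                nad = NULL, nadh = NULL,
                                nad_ratio = NULL,
                                temperature = T_DEFAULT) {
  stopifnot(is.numeric(methanol), is.numeric(formaldehyde))
  if (methanol < 0 || formaldehyde < 0)
    stop("concentrations must be non-negative")
  if (temperature <= 0) stop("temperature must be positive (kelvin)")
  have_abs <- !is.null(nad) && !is.null(nadh)
  if (have_abs) {
    if (nad < 0 || nadh < 0) stop("cofactor concentrations must be non-negative")
    nad_ratio <- if (nadh > 0) nad / nadh else Inf
  } else {
    if (is.null(nad_ratio))
      stop("supply either nad and nadh, or nad_ratio")
    if (nad_ratio < 0) stop("nad_ratio must be non-negative")
  }
  structure(
    list(methanol = methanol, formaldehyde = formaldehyde,
         nad = if (have_abs) nad else NA_real_,
         nadh = if (have_abs) nadh else NA_real_,
         nad_ratio = nad_ratio,
         ratio_only = !have_abs,
         temperature = temperature),
    class = "concentration_state"
  )
}

#' @export
print.concentration_state <- function(x, ...) {
  cat("Mdh concentration state (", x$temperature, " K)\n", sep = "")
  cat("  [CH3OH] =", x$methanol, "M,  [CH2O] =", x$formaldehyde, "M\n")
  if (x$ratio_only) {
    cat("  NAD:NADH =", x$nad_ratio, "(absolute cofactor levels unknown)\n")
  } else {
    cat("  [NAD] =", x$nad, "M,  [NADH] =", x$nadh, "M\n")
  }
  invisible(x)
}

#' Reaction quotient of the Mdh reaction
#'
#' Q = ([CH2O][NADH]) / ([CH3OH][NAD]). When the state only carries the
#' NAD:NADH ratio this reduces to [CH2O] / ([CH3OH] * ratio); the proton
#' is absorbed into the transformed standard Gibbs energy.
#'
#' @param state A [concentration_state()].
#' @return Dimensionless reaction quotient.
#' @export
reaction_quotient <- function(state) {
  stopifnot(inherits(state, "concentration_state"))
  if (state$methanol == 0)
    stop("reaction quotient undefined: methanol concentration is zero")
  if (state$ratio_only) {
    if (state$nad_ratio == 0)
      stop("reaction quotient undefined: nad_ratio is zero")
    state$formaldehyde / (state$methanol * state$nad_ratio)
  } else {
    if (state$nad == 0)
      stop("reaction quotient undefined: NAD concentration is zero")
    (state$formaldehyde * state$nadh) / (state$methanol * state$nad)
  }
}

#' Gibbs energy of reaction at a given quotient
#'
#' dG = dG0 + R T ln Q with R = 8.3145e-3 kJ mol-1 K-1. A quotient of
#' exactly zero (no product) returns `-Inf` with a warning; negative
#' quotients are a domain error.
#'
#' @param dg0 Transformed standard Gibbs energy (kJ mol-1).
#' @param q Reaction quotient (dimensionless, >= 0).
#' @param temperature Kelvin.
#' @return Gibbs energy in kJ mol-1.
#' @export
delta_g <- function(dg0, q, temperature = T_DEFAULT) {
  if (any(q < 0)) stop("reaction quotient must be non-negative")
  out <- dg0 + R_GAS * temperature * log(q)
  if (any(q == 0)) warning("zero reaction quotient: returning -Inf")
  out
}

#' Concentration at which the Mdh reaction reaches equilibrium
#'
#' Solves dG = 0 for one species of the reaction quotient, holding the
#' others fixed. Since Q is linear in each species the solution is unique
#' and closed-form: Q_eq = exp(-dG0 / (R T)).
#'
#' @param dg0 Standard Gibbs energy (kJ mol-1).
#' @param state A [concentration_state()] supplying the fixed species.
#' @param solve_for One of `"formaldehyde"`, `"methanol"`, `"nad"`,
#'   `"nadh"`. The cofactors require absolute concentrations in `state`.
#' @return The equilibrium concentration (M) of the requested species.
#' @examples
#' st <- concentration_state(0.25, 0, nad_ratio = 31.3)
#' equilibrium_concentration(34.2, st, "formaldehyde")  # ~ 1.4e-5 M
#' @export
equilibrium_concentration <- function(dg0, state,
                                      solve_for = c("formaldehyde", "methanol",
                                                    "nad", "nadh")) {
  stopifnot(inherits(state, "concentration_state"))
  solve_for <- match.arg(solve_for)
  q_eq <- exp(-dg0 / (R_GAS * state$temperature))
  if (state$ratio_only && solve_for %in% c("nad", "nadh"))
    stop("cannot solve for a cofactor when only the NAD:NADH ratio is known")
  num_ratio <- if (state$ratio_only) 1 / state$nad_ratio else
    state$nadh / state$nad
  out <- switch(solve_for,
    formaldehyde = {
      if (state$methanol <= 0) stop("methanol must be positive to solve for formaldehyde")
      q_eq * state$methanol / num_ratio
    },
    methanol = {
      if (state$formaldehyde <= 0) stop("formaldehyde must be positive to solve for methanol")
      state$formaldehyde * num_ratio / q_eq
    },
    nadh = {
      if (state$formaldehyde <= 0) stop("formaldehyde must be positive to solve for NADH")
      q_eq * state$methanol * state$nad / state$formaldehyde
    },
    nad = {
      q_eq_inv <- state$formaldehyde * state$nadh / (q_eq * state$methanol)
      if (state$methanol <= 0) stop("methanol must be positive to solve for NAD")
      q_eq_inv
    })
  out
}

#' Forward/reverse flux ratio implied by a Gibbs energy
#'
#' The flux-force relationship dG = -R T ln(J+/J-), so
#' J+/J- = exp(-dG / (R T)). [dg_from_flux_ratio()] is the inverse.
#'
#' @param dg Gibbs energy (kJ mol-1), finite.
#' @param temperature Kelvin.
#' @return The flux ratio J+/J- (dimensionless, > 0).
#' @export
flux_ratio_from_dg <- function(dg, temperature = T_DEFAULT) {
  exp(-dg / (R_GAS * temperature))
}

#' @rdname flux_ratio_from_dg
#' @param flux_ratio J+/J- (> 0).
#' @export
dg_from_flux_ratio <- function(flux_ratio, temperature = T_DEFAULT) {
  if (any(flux_ratio <= 0)) stop("flux ratio must be positive")
  -R_GAS * temperature * log(flux_ratio)
}

#' Forward-flux fraction from a flux ratio
#'
#' f = r / (1 + r) where r = J+/J-. Satisfies f(r) + f(1/r) = 1.
#'
#' @param flux_ratio J+/J- (>= 0, may be `Inf`).
#' @return Fraction of total flux in the forward direction, in \[0, 1\].
#' @export
forward_fraction <- function(flux_ratio) {
  if (any(flux_ratio < 0)) stop("flux ratio must be non-negative")
  ifelse(is.infinite(flux_ratio), 1, flux_ratio / (1 + flux_ratio))
}

#' A single steady-state formaldehyde observation
#'
#' @param formaldehyde_uM Steady-state formaldehyde concentration in uM.
#' @param sd_uM Standard deviation of the same, uM (0 if unknown).
#' @param nad_ratio,nad_ratio_sd NAD:NADH ratio and its sd (optional).
#' @param condition Free-text condition label.
#' @param pathway `"mdh_only"` or `"full_pathway"`.
#' @return An object of class `steady_state_observation`.
#' @export
steady_state_observation <- function(formaldehyde_uM, sd_uM = 0,
                                     nad_ratio = NA_real_,
                                     nad_ratio_sd = NA_real_,
                                     condition = "unspecified",
                                     pathway = c("mdh_only", "full_pathway")) {
  pathway <- match.arg(pathway)
  if (formaldehyde_uM <= 0) stop("steady-state formaldehyde must be positive")
  if (sd_uM < 0) stop("standard deviation must be non-negative")
  if (!is.na(nad_ratio_sd) && nad_ratio_sd < 0)
    stop("nad_ratio_sd must be non-negative")
  structure(
    list(formaldehyde_uM = formaldehyde_uM, sd_uM = sd_uM,
         nad_ratio = nad_ratio, nad_ratio_sd = nad_ratio_sd,
         condition = condition, pathway = pathway),
    class = "steady_state_observation"
  )
}

# Cap used when the full-pathway steady state is zero and the bound is
# formally infinite; reported with the `capped` flag set.
.FLUX_RATIO_CAP <- 1e6

#' Construct a reversibility estimate
#'
#' Container tying together the flux ratio J+/J-, the forward-flux
#' fraction r/(1+r), whether the number is a lower bound (paired
#' steady-state analysis) or a point estimate (KIE analysis), and an
#' uncertainty interval.
#'
#' @param flux_ratio J+/J- (>= 0; `Inf` allowed).
#' @param bound_kind `"lower_bound"` or `"point_estimate"`.
#' @param interval Length-2 numeric, interval on the forward fraction.
#' @param method Short description of how the estimate was obtained.
#' @param flags Character vector of quality flags.
#' @return Object of class `reversibility_estimate` with fields
#'   `forward_fraction`, `flux_ratio`, `bound_kind`, `interval`.
#' @export
reversibility_estimate <- function(flux_ratio,
                                   bound_kind = c("lower_bound", "point_estimate"),
                                   interval = c(NA_real_, NA_real_),
                                   method = "", flags = character()) {
  bound_kind <- match.arg(bound_kind)
  if (!is.na(flux_ratio) && flux_ratio < 0) stop("flux ratio must be non-negative")
  ff <- forward_fraction(flux_ratio)
  if (!anyNA(interval) && interval[1] > interval[2])
    stop("interval must be ordered (lo <= hi)")
  structure(
    list(forward_fraction = ff, flux_ratio = flux_ratio,
         bound_kind = bound_kind, interval = interval,
         method = method, flags = flags),
    class = "reversibility_estimate"
  )
}

#' @export
print.reversibility_estimate <- function(x, ...) {
  kind <- if (x$bound_kind == "lower_bound") "minimum forward fraction"
          else "forward fraction (point estimate)"
  cat(sprintf("%s: %.1f%% (J+/J- = %.3g)\n",
              kind, 100 * x$forward_fraction, x$flux_ratio))
  if (!anyNA(x$interval))
    cat(sprintf("  interval: [%.3f, %.3f]\n", x$interval[1], x$interval[2]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Percent reporting helper
#'
#' Rounds a fraction to the nearest integer percent, half away from zero,
#' matching the convention used for headline flux-partition numbers.
#'
#' @param fraction Numeric in \[0, 1\].
#' @return Integer percent.
#' @export
percent_round <- function(fraction) {
  floor(100 * fraction + 0.5)
}

#' Thermodynamic lower bound on Mdh forward flux from paired steady states
#'
#' Compares the steady-state formaldehyde level of a strain expressing
#' only Mdh (assumed at, or below, equilibrium) with that of a strain
#' carrying the full assimilation pathway, treated identically. Because
#' methanol and (by assumption or measurement) the NAD:NADH ratio are
#' shared, the Gibbs energy of the full-pathway condition obeys
#' dG <= R T ln(\[CH2O\]_full / \[CH2O\]_mdh), giving via the flux-force
#' relation a guaranteed minimum J+/J- >= \[CH2O\]_mdh / \[CH2O\]_full.
#' When both observations carry NAD:NADH ratios the correction factor
#' ratio_full / ratio_mdh multiplies the bound before reduction.
#'
#' The result is always a lower bound, never a point estimate: the
#' Mdh-only strain may itself sit below equilibrium.
#'
#' @param obs_mdh_only,obs_full [steady_state_observation()]s for the
#'   Mdh-only and full-pathway strains of the same condition.
#' @param temperature Kelvin (propagated into the reported dG bound).
#' @param n_samples Monte-Carlo draws for the uncertainty interval.
#' @param seed Integer seed making the interval reproducible.
#' @return A [reversibility_estimate()] with `bound_kind = "lower_bound"`;
#'   attribute `delta_g_upper` carries the dG upper bound in kJ mol-1.
#' @examples
#' a <- steady_state_observation(52, 1, pathway = "mdh_only")
#' b <- steady_state_observation(17, 1.5, pathway = "full_pathway")
#' reversibility_bound(a, b, seed = 1)
#' @export
reversibility_bound <- function(obs_mdh_only, obs_full,
                                temperature = T_DEFAULT,
                                n_samples = 10000, seed = 1L) {
  stopifnot(inherits(obs_mdh_only, "steady_state_observation"),
            inherits(obs_full, "steady_state_observation"))
  if (obs_mdh_only$pathway != "mdh_only" || obs_full$pathway != "full_pathway")
    stop("arguments must be an mdh_only and a full_pathway observation, in that order")

  have_ratios <- !is.na(obs_mdh_only$nad_ratio) && !is.na(obs_full$nad_ratio)
  point_fun <- function(f1, f2, r1, r2) {
    corr <- if (have_ratios) r2 / r1 else 1
    (f1 / f2) * corr
  }

  flags <- character()
  if (obs_full$formaldehyde_uM == 0) {
    # formally infinite driving force; cap and flag
    return(reversibility_estimate(.FLUX_RATIO_CAP, "lower_bound",
                                  interval = c(1, 1),
                                  method = "paired_steady_state",
                                  flags = "infinite_bound_capped"))
  }

  fr_point <- point_fun(obs_mdh_only$formaldehyde_uM, obs_full$formaldehyde_uM,
                        obs_mdh_only$nad_ratio, obs_full$nad_ratio)

  inputs <- list(
    f1 = c(obs_mdh_only$formaldehyde_uM, obs_mdh_only$sd_uM),
    f2 = c(obs_full$formaldehyde_uM, obs_full$sd_uM),
    r1 = c(if (have_ratios) obs_mdh_only$nad_ratio else 1,
           if (have_ratios && !is.na(obs_mdh_only$nad_ratio_sd))
             obs_mdh_only$nad_ratio_sd else 0),
    r2 = c(if (have_ratios) obs_full$nad_ratio else 1,
           if (have_ratios && !is.na(obs_full$nad_ratio_sd))
             obs_full$nad_ratio_sd else 0)
  )
  prop <- propagate_uncertainty(
    function(f1, f2, r1, r2) forward_fraction(point_fun(f1, f2, r1, r2)),
    inputs, n_samples = n_samples, seed = seed)

  est <- reversibility_estimate(fr_point, "lower_bound",
                                interval = prop$interval,
                                method = "paired_steady_state",
                                flags = flags)
  attr(est, "delta_g_upper") <- dg_from_flux_ratio(fr_point, temperature)
  attr(est, "uncertainty") <- prop
  est
}

#' Monte-Carlo (and delta-method) propagation of measurement uncertainty
#'
#' Resamples each input from an independent gaussian with the given mean
#' and sd, evaluates the estimator on every draw, and summarises the
#' distribution. Ratios of noisy positive quantities are skewed, so the
#' interval reported is percentile-based (2.5/97.5); mean and sd of the
#' draws are returned alongside, as is a first-order delta-method sd for
#' cross-checking. Draws on which the estimator is undefined (NaN, NA,
#' error) are dropped; more than 50% undefined is an error.
#'
#' @param point_fn Estimator. Called with one named argument per input;
#'   must accept equal-length numeric vectors (vectorised evaluation).
#' @param inputs Named list; each element a length-2 numeric
#'   `c(mean, sd)`.
#' @param n_samples Number of Monte-Carlo draws (>= 1).
#' @param seed Integer seed; the same seed always gives the same interval.
#' @return List with `point` (estimator at the means), `mean`, `sd`,
#'   `interval` (2.5/97.5 percentiles), `delta_sd`, `n_valid`.
#' @export
propagate_uncertainty <- function(point_fn, inputs, n_samples = 10000,
                                  seed = 1L) {
  stopifnot(is.list(inputs), length(inputs) >= 1, n_samples >= 1)
  means <- vapply(inputs, function(x) x[1], numeric(1))
  sds   <- vapply(inputs, function(x) x[2], numeric(1))
  if (any(sds < 0)) stop("standard deviations must be non-negative")

  point <- do.call(point_fn, as.list(means))

  if (all(sds == 0)) {
    return(list(point = point, mean = point, sd = 0,
                interval = c(point, point),
                delta_sd = 0, n_valid = n_samples))
  }

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  draws <- lapply(seq_along(means), function(i)
    stats::rnorm(n_samples, means[i], sds[i]))
  names(draws) <- names(inputs)
  vals <- tryCatch(do.call(point_fn, draws), error = function(e) NULL)
  if (is.null(vals) || length(vals) != n_samples) {
    # estimator not vectorised; fall back to a loop
    vals <- vapply(seq_len(n_samples), function(j) {
      args <- lapply(draws, `[`, j)
      tryCatch(do.call(point_fn, args), error = function(e) NA_real_)
    }, numeric(1))
  }
  ok <- is.finite(vals)
  if (mean(ok) < 0.5)
    stop("estimator undefined on more than 50% of Monte-Carlo draws; ",
         "check input domains (means: ",
         paste(sprintf("%s=%g", names(means), means), collapse = ", "), ")")
  v <- vals[ok]

  # first-order delta method for cross-checks
  grad <- vapply(seq_along(means), function(i) {
    h <- max(1e-8, 1e-6 * abs(means[i]))
    up <- means; up[i] <- up[i] + h
    dn <- means; dn[i] <- dn[i] - h
    (do.call(point_fn, as.list(up)) - do.call(point_fn, as.list(dn))) / (2 * h)
  }, numeric(1))
  delta_sd <- sqrt(sum((grad * sds)^2))

  list(point = point,
       mean = mean(v), sd = stats::sd(v),
       interval = unname(stats::quantile(v, c(0.025, 0.975))),
       delta_sd = delta_sd,
       n_valid = sum(ok))
}

# Preserve the caller's RNG state so seeded internals are polite.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
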