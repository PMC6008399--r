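---
title: "Diagnosing thermodynamic versus kinetic limitation of methanol dehydrogenase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing thermodynamic versus kinetic limitation of methanol dehydrogenase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdhflux)
```

## The problem

Engineering *E. coli* to assimilate methanol grafts three reactions onto
central metabolism: an NAD-dependent methanol dehydrogenase (Mdh,
CH~3~OH + NAD^+^ → CH~2~O + NADH + H^+^), hexulose phosphate synthase
(Hps, CH~2~O + Ru5P → H6P) and phosphohexulose isomerase (Phi, H6P →
F6P). The Mdh step is strongly uphill (ΔG°′ ≈ +34.2 kJ mol^−1^), so net
methanol oxidation requires the product formaldehyde to be kept at low
micromolar levels by the downstream sink. When engineering such a strain
the central diagnostic question is: *is flux limited by thermodynamics
(Mdh running near equilibrium, its forward flux largely cancelled by
reverse flux) or by kinetics (Mdh far from equilibrium but slow)?* The
answer dictates opposite remedies — improve the formaldehyde sink versus
improve the enzyme.

`mdhflux` implements two complementary, purely measurement-driven ways
of answering that question, together with the supporting enzymology,
isotope bookkeeping, dynamics and constraint-based modelling, and a
synthetic-data layer that generates every input with known ground truth.

## The paired-steady-state thermodynamic bound

Two strains treated identically — one expressing only Mdh, one the full
pathway — share the same methanol level and (by measurement) the same
NAD:NADH ratio. If the Mdh-only strain sits at (or below) equilibrium,
then for the full pathway

$$\Delta G \le RT \ln \frac{[\mathrm{CH_2O}]_{\mathrm{full}}}{[\mathrm{CH_2O}]_{\mathrm{Mdh\ only}}},$$

and the flux-force relationship $\Delta G = -RT\ln(J^+/J^-)$ converts
this into a *guaranteed minimum* on the forward-flux ratio:
$J^+/J^- \ge [\mathrm{CH_2O}]_{1}/[\mathrm{CH_2O}]_{2}$. The result is a
lower bound, never a point estimate (`bound_kind` records this), because
the reference strain may itself be below equilibrium. When both
observations carry NAD:NADH ratios the correction factor
$r_2/r_1$ is applied before the reduction.

```{r}
a <- steady_state_observation(52, 1, pathway = "mdh_only")
b <- steady_state_observation(17, 1.5, pathway = "full_pathway")
reversibility_bound(a, b, seed = 1)
```

## The kinetic-isotope-effect point estimate

Deuterated methanol (CD~3~OD) slows Mdh by the primary kinetic isotope
effect α = k~1H~/k~1D~ (≈ 3.2 for this enzyme), while the equilibrium
isotope effect for NAD-dependent primary alcohol oxidation is only
γ ≈ 1.07. A mass balance on formaldehyde with mass-action kinetics,

$$\frac{d[F]}{dt} = k_1[\mathrm{NAD}][\mathrm{CH_3OH}]
  - k_{-1}[\mathrm{NADH}][F] - k_2[\mathrm{Ru5P}][F],$$

gives a steady state $[F]_{SS} = k_1[\mathrm{NAD}][\mathrm{CH_3OH}] /
(k_{-1}[\mathrm{NADH}] + k_2[\mathrm{Ru5P}])$. Writing β for the ratio
of irreversible Hps flux to reverse Mdh flux and taking the H/D ratio of
steady states yields

$$R_{H/D} = \frac{\gamma + \alpha\beta}{1+\beta}, \qquad
  \beta = \frac{\gamma - R_{H/D}}{R_{H/D} - \alpha}, \qquad
  \frac{\mathrm{MDH_F}}{\mathrm{MDH_F+MDH_R}} = \frac{1+\beta}{2+\beta}
  = \frac{\gamma-\alpha}{\gamma + R_{H/D} - 2\alpha}.$$

$R_{H/D}$ is physically confined to [γ, α]: γ means Mdh at equilibrium
(50% forward), α means fully irreversible (100% forward). The fraction
is strictly increasing in $R_{H/D}$ across that band.

```{r}
forward_fraction_from_kie(1.5)          # unsupplemented condition
kie_partition_with_uncertainty(ratio = 3.2, ratio_sd = 0.4, seed = 1)
```

Measurement noise can push a ratio outside [γ, α]; each call chooses
`strict` (error) or `clamp` (project to the boundary, flag, and report
the fraction of Monte-Carlo draws clamped). The batch pipeline defaults
to clamp-with-flags because real boundary-hugging measurements exist.
Conditions where the deuterated channel could not be measured are
marked `indeterminate`, never imputed.

## Parameters that matter

* **α (KIE)** — default 3.2, dimensionless; measured from paired
  Michaelis plots via `kie_from_paired_fits()` (Vmax ratio, with a
  per-substrate-level ratio diagnostic to expose Km isotope effects).
* **γ (EIE)** — default 1.07, literature value for NAD-dependent primary
  alcohol oxidation; recorded with provenance metadata.
* **Hps secondary KIE** — default 1.04, stored but neglected by the core
  inversion (the framework's derivation assumes it negligible); an
  optional mode in `predicted_ratio_from_kinetics()` applies it for
  sensitivity analysis.
* **Temperature** — default 310.15 K (assays run at 37 °C), overridable
  everywhere; the gas constant is fixed at 8.3145 × 10^−3^ kJ mol^−1^
  K^−1^.
* Concentrations are molar internally; the CSV interfaces speak μM
  because that is how the measurements are reported.

The constructor rejects α ≤ γ: with no net isotope discrimination the
ratio carries no information and the framework degenerates.

## Dynamics and the enzyme-dose dichotomy

`simulate_formaldehyde()` integrates the linear balance either by
forward Euler at the reference step 0.002 (the scheme the original
spreadsheet analysis used; refused when dt·λ ≥ 2) or adaptively via
`deSolve::lsoda` at rtol 1e−10, which tracks the closed form
$F(t) = F_{SS}(1-e^{-\lambda t}) + f_0 e^{-\lambda t}$ to well below
1e−6 relative error. The closed form is kept as an independent oracle.

"Increasing the Vmax of Mdh" is modelled as an enzyme-dose change:
`enzyme_dose_scan()` scales k~1~ *and* k~−1~ together, leaving the
equilibrium untouched. This is the only reading that produces the
regime dichotomy: the steady-state Hps flux gain under dose factor c is

$$\mathrm{gain} = \frac{c\,(k_{-1}B + k_2C)}{c\,k_{-1}B + k_2C},$$

which tends to 1 near equilibrium (reverse Mdh flux dominant) and to c
far from it. Scaling k~1~ alone would scale the steady state
proportionally in *both* regimes and show no dichotomy; that mode is
retained for contrast (`mode = "k1_only"`), and the scaling assumption
is recorded in the scan output. The exact rate constants behind the
published dose-scan figure are supplementary-only, so the package treats
the dichotomy qualitatively, with dimensionless defaults
(k~1~[NAD][CH~3~OH] = 1, β set by scenario).

```{r}
near <- enzyme_dose_scan(kinetic_state(1, k_minus1 = 1, k2 = 0.01), 4)
far  <- enzyme_dose_scan(kinetic_state(1, k_minus1 = 0.01, k2 = 1), 4)
c(near_equilibrium = near$flux_summary$hps_flux_gain,
  far_from_equilibrium = far$flux_summary$hps_flux_gain)
```

## Enzymology and calibration

Michaelis–Menten fits use Levenberg–Marquardt least squares started from
a Lineweaver–Burk seed (plus a small deterministic grid of fallback
starts), with t-based confidence intervals from the asymptotic
covariance — the same contract as the classical `nlinfit`/`nlparci`
pair. Coverage is validated by seeded simulation (≥ 90% at nominal 95%
over 500 trials) rather than assumed. Nash-assay calibration fits a free
intercept by default, since blank wells drift daily; forcing the line
through the origin is possible but flagged. Initial-rate extraction
takes the longest linear prefix (r² ≥ 0.99, ≥ 4 points) of an A340
trace and converts via Beer–Lambert (ε = 6220 M^−1^ cm^−1^) or an NADH
standard curve.

## Isotopomer bookkeeping

Natural-abundance correction is the carbon-only matrix method: column j
of the correction matrix is the binomial convolution of j tracer-labeled
carbons with natural ^13^C (1.07%) on the remaining positions, solved by
non-negative least squares and renormalised. Carbon-only columns sum to
one, so the correction conserves mass up to the reported clipping.
Tracer purity (default 1; 0.99 typical for commercial ^13^C-methanol) is
an optional second convolution — whether published enrichment values
were purity-corrected is not stated, so both modes are exposed and the
roundtrip identity holds in each. F6P is handled as a 6-carbon backbone.

## The constraint-based layer

`heterologous_reactions()` defines Mdh, Hps and Phi (all elementally
audited against standard formulas) plus passive methanol diffusion.
Tests run against a bundled ~16-reaction synthetic toy network whose
growth is linear in substrate uptake, so uptake matching
(`match_growth_by_uptake()`, bisection to within a 2% relative
tolerance) and carbon-normalised "proportional flux" have hand-checkable
answers. Proportional flux divides by C-mol uptake so glucose (6 C) and
methanol (1 C) flux maps are commensurate — the normalisation is a
package choice, stated here because the term is not otherwise defined.
Flux comparisons use flux-variability ranges rather than single optima
to avoid alternate-optimum artefacts. Genome-scale runs are possible via
the minimal SBML L3/fbc reader but are deliberately out of scope for the
test suite (results are model-version-dependent). The LP itself is a
self-contained two-phase tableau simplex with Bland's anti-cycling rule,
which is robust on the small, highly degenerate flux polytopes involved.

## What the synthetic data emulate — and what they do not

The generators reproduce the *structure* of the study's measurements:
exponential-approach formaldehyde timecourses from the mass-action
balance, paired H/D channels whose deuterated rate constants follow
k~1D~ = k~1H~/α and k~−1D~ = γk~−1H~/α, six-level Michaelis plates,
0–100 μM Nash standard series, and MIDs convolved with natural
abundance. Noise is multiplicative log-normal parameterised by a CV
(concentration readings are positive and CV-dominated; 5% CV is used as
the realistic default in recovery tests, with 3 replicates matching the
study's biological replication). Ground truth is encoded by the forward
fraction itself through β = (2f−1)/(1−f).

Not emulated: plate-reader optics, LC-MS peak shapes, slow drifts,
correlated replicate structure, or biological variation of the rate
constants between conditions. Passing recovery tests therefore
demonstrate the *inference machinery* is unbiased and correctly seeded
at realistic noise, not that any real instrument behaves this simply.

## Numerical choices and degenerate inputs

* Monte-Carlo error propagation (seeded, gaussian resampling,
  percentile intervals) is the default because ratios of noisy positive
  quantities are skewed; a first-order delta-method sd is emitted for
  cross-checks. Estimators undefined on > 50% of draws raise an error.
* A measured ratio exactly at α maps to β = ∞ and is reported as a
  sentinel with `at_KIE_limit` flag; a zero full-pathway steady state
  caps the thermodynamic bound at 10^6^ with a flag.
* Zero reaction quotient returns −∞ with a warning; negative quotients
  error.
* Corrected MID components forced negative by noise are clipped to zero,
  renormalised, and the clipped mass reported.
* Percent reporting rounds half away from zero to integer percent, the
  convention used for the headline numbers; raw fractions are always
  retained.

## Problem sizes used by the test suite

The suite validates the integrators on 100-point random parameter
sweeps, CI coverage on 500 seeded fits, end-to-end isotope recovery on
200 seeded paired experiments across true forward fractions
{0.55, 0.65, 0.75, 0.85, 0.95} at 5% CV, and the algebraic identities on
1000-point random grids. These sizes give stable pass/fail behaviour at
sub-minute runtimes and are the package's reference configurations.

## Known limitations

* The equilibrium-concentration solver treats activities as
  concentrations; with the main-text inputs (250 mM methanol, NAD:NADH
  31.3, +34.2 kJ mol^−1^) it predicts an equilibrium formaldehyde of
  ~14 μM at 310 K, whereas the published prediction of ~50 μM rests on
  supplementary activity/ionic-strength corrections that are not
  reproducible from the main text. The solver is generic and makes no
  attempt to hard-code the published value.
* Formaldehyde is treated as a single pool (no hydration equilibrium),
  matching what the Nash assay measures.
* The KIE framework is exactly the two-step lumped Mdh→Hps system; no
  multi-enzyme isotope network is attempted.
* NADH inhibition of Mdh is summarised descriptively
  (`fractional_inhibition()`); no mechanistic inhibition model is
  fitted, because the available data do not discriminate competitive
  from uncompetitive binding.
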