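# Mass-isotopomer distribution (MID) handling for 13C-methanol labeling:
# natural-abundance correction (carbon-only matrix method, with optional
# tracer purity), mean enrichment, M+0 fold-changes, and the
# internal-standard quantification used for relative pool sizes.

#' Construct a mass-isotopomer distribution
#'
#' @param fractions Numeric vector of fractional abundances M+0..M+n.
#' @param n_carbons Number of carbons in the metabolite backbone
#'   (default `length(fractions) - 1`).
#' @param metabolite Label.
#' @param normalize Renormalise to sum 1 (required within 1e-6 if
#'   `FALSE`).
#' @return Object of class `mass_distribution`.
#' @export
mass_distribution <- function(fractions, n_carbons = length(fractions) - 1L,
                              metabolite = "unknown", normalize = TRUE) {
  if (any(fractions < 0)) stop("isotopomer fractions must be non-negative")
  if (length(fractions) != n_carbons + 1L)
    stop("need exactly n_carbons + 1 fractions (M+0..M+n)")
  s <- sum(fractions)
  if (s == 0) stop("all fractions are zero")
  if (normalize) fractions <- fractions / s
  else if (abs(s - 1) > 1e-6) stop("fractions must sum to 1 within 1e-6")
  structure(list(fractions = fractions, n_carbons = as.integer(n_carbons),
                 metabolite = metabolite),
            class = "mass_distribution")
}

#' @export
print.mass_distribution <- function(x, ...) {
  cat("MID for", x$metabolite, "(", x$n_carbons, "carbons ):\n")
  print(stats::setNames(round(x$fractions, 4),
                        paste0("M+", seq_along(x$fractions) - 1L)))
  invisible(x)
}

#' Natural-abundance (and tracer-purity) convolution matrix
#'
#' Column j (0-based number of tracer-labeled carbons) gives the
#' measured-mass distribution of a molecule with exactly j labeled
#' positions: the n - j unlabeled carbons each carry 13C at the natural
#' abundance, and optionally each of the j tracer positions is 13C only
#' with probability `purity`. With `purity = 1` the matrix is lower
#' triangular; in the carbon-only model every column sums to 1, so the
#' correction is mass-conserving.
#'
#' @param n_carbons Number of carbons.
#' @param abundance_13c Natural 13C abundance, default 0.0107.
#' @param purity Isotopic purity of the tracer, default 1 (use 0.99 for
#'   commercial 13C-methanol when purity correction is wanted).
#' @return (n+1) x (n+1) matrix mapping true label counts to measured
#'   mass shifts.
#' @export
correction_matrix <- function(n_carbons, abundance_13c = 0.0107, purity = 1) {
  if (abundance_13c < 0 || abundance_13c >= 1)
    stop("abundance must lie in [0, 1)")
  if (purity <= 0 || purity > 1) stop("purity must lie in (0, 1]")
  n <- as.integer(n_carbons)
  m <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    nat <- stats::dbinom(0:(n - j), n - j, abundance_13c)  # unlabeled carbons
    lab <- stats::dbinom(0:j, j, purity)                   # tracer carbons
    col <- .convolve_discrete(lab, nat)                    # total 13C count
    m[seq_along(col), j + 1L] <- col
  }
  m
}

.convolve_discrete <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' Correct a measured MID for natural abundance
#'
#' Solves M x = raw for the label-count distribution x by non-negative
#' least squares ([pracma::lsqnonneg()]), then renormalises. NNLS keeps
#' noise-induced negative components at zero; the mass lost to that
#' clipping is reported. Convolving a distribution with
#' [correction_matrix()] and correcting recovers it to machine
#' precision.
#'
#' @param raw A [mass_distribution()] of measured fractions.
#' @param abundance_13c Natural 13C abundance used in the matrix.
#' @param purity Tracer purity (see [correction_matrix()]).
#' @return The corrected `mass_distribution`; attributes
#'   `clipped_mass` (fraction removed by the non-negativity constraint)
#'   and `residual_norm`.
#' @export
correct_natural_abundance <- function(raw, abundance_13c = 0.0107,
                                      purity = 1) {
  stopifnot(inherits(raw, "mass_distribution"))
  m <- correction_matrix(raw$n_carbons, abundance_13c, purity)
  if (rcond(m) < 1e-12) stop("correction matrix is ill-conditioned")
  sol <- pracma::lsqnonneg(m, raw$fractions)
  x <- sol$x
  if (sum(x) == 0) stop("correction produced an all-zero distribution")
  exact <- solve(m, raw$fractions)
  clipped <- sum(pmax(-exact, 0))
  out <- mass_distribution(x / sum(x), raw$n_carbons, raw$metabolite)
  attr(out, "clipped_mass") <- clipped
  attr(out, "residual_norm") <- sqrt(sum((m %*% x - raw$fractions)^2))
  out
}

#' Convolve a true label distribution with natural abundance
#'
#' Forward operation of [correct_natural_abundance()]; useful for
#' generating synthetic measured MIDs and for roundtrip checks.
#'
#' @inheritParams correct_natural_abundance
#' @param mid A [mass_distribution()] of true label counts.
#' @export
convolve_natural_abundance <- function(mid, abundance_13c = 0.0107,
                                       purity = 1) {
  stopifnot(inherits(mid, "mass_distribution"))
  m <- correction_matrix(mid$n_carbons, abundance_13c, purity)
  mass_distribution(as.numeric(m %*% mid$fractions), mid$n_carbons,
                    mid$metabolite)
}

#' Mean isotopic enrichment of a MID
#'
#' sum(i * M_i) / n_carbons: the average fraction of carbon positions
#' that are labeled. 0 for pure M+0, 1 for fully labeled.
#'
#' @param mid A [mass_distribution()].
#' @return Fraction in \[0, 1\].
#' @export
mean_enrichment <- function(mid) {
  stopifnot(inherits(mid, "mass_distribution"))
  if (mid$n_carbons == 0) stop("mean enrichment undefined for zero carbons")
  i <- seq_along(mid$fractions) - 1L
  sum(i * mid$fractions) / sum(mid$fractions) / mid$n_carbons
}

#' Fold change of the unlabeled (M+0) fraction between two MIDs
#'
#' @param mid_a,mid_b [mass_distribution()]s of the same metabolite
#'   (numerator and denominator).
#' @return M+0(a) / M+0(b).
#' @export
m0_fold_change <- function(mid_a, mid_b) {
  stopifnot(inherits(mid_a, "mass_distribution"),
            inherits(mid_b, "mass_distribution"))
  if (mid_a$metabolite != mid_b$metabolite)
    warning("comparing M+0 fractions of different metabolites (",
            mid_a$metabolite, " vs ", mid_b$metabolite, ")")
  b0 <- mid_b$fractions[1] / sum(mid_b$fractions)
  if (b0 == 0) stop("denominator M+0 fraction is zero")
  (mid_a$fractions[1] / sum(mid_a$fractions)) / b0
}

#' Absolute quantification against a fully labeled internal standard
#'
#' amount = standard_amount * area_unlabeled / area_fully_labeled.
#' Ratios of two such quantifications cancel the standard amount, so
#' relative pool sizes are independent of it.
#'
#' @param area_unlabeled Integrated peak area of the unlabeled analyte.
#' @param area_fully_labeled Area of the fully 13C-labeled standard
#'   (> 0).
#' @param standard_amount Known amount/concentration of the standard.
#' @return Estimated analyte amount in the units of `standard_amount`.
#' @export
quantify_internal_standard <- function(area_unlabeled, area_fully_labeled,
                                       standard_amount) {
  if (any(area_fully_labeled <= 0)) stop("labeled-standard area must be positive")
  if (any(area_unlabeled < 0)) stop("peak areas must be non-negative")
  standard_amount * area_unlabeled / area_fully_labeled
}
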