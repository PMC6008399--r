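# Constraint-based (FBA) support: a small metabolic model container,
# amendment with the heterologous methanol-assimilation reactions
# (Mdh, Hps, Phi + passive methanol diffusion), LP optimisation of
# growth, uptake matching against a target growth rate, proportional
# (carbon-normalised) fluxes, and flux-variability ranges.
#
# Models are small (the bundled toy network has ~16 reactions), and the
# LP layer is a self-contained two-phase tableau simplex with Bland's
# anti-cycling rule, which terminates on the degenerate bases that
# steady-state flux polytopes routinely produce.

.BOUND_INF <- 1000

# --- LP core ------------------------------------------------------------

# Canonical-tableau simplex iterations with Bland's rule (minimisation).
# tab: m x (N+1) tableau (RHS last), basis: current basic column per row,
# cost: length-N objective, allowed: columns permitted to enter.
.simplex_iterate <- function(tab, basis, cost, allowed, tol = 1e-9) {
  m <- nrow(tab); n_cols <- ncol(tab) - 1L
  repeat {
    red <- cost - as.numeric(cost[basis] %*% tab[, seq_len(n_cols), drop = FALSE])
    red[basis] <- 0
    red[!allowed] <- 0
    ent <- which(red < -tol)
    if (!length(ent))
      return(list(tab = tab, basis = basis, status = "optimal"))
    j <- min(ent)                                  # Bland: lowest index enters
    col <- tab[, j]
    pos <- which(col > tol)
    if (!length(pos))
      return(list(tab = tab, basis = basis, status = "unbounded"))
    ratios <- tab[pos, n_cols + 1L] / col[pos]
    cand <- pos[ratios <= min(ratios) + tol]
    i <- cand[which.min(basis[cand])]              # Bland: lowest basis leaves
    tab[i, ] <- tab[i, ] / tab[i, j]
    for (r in seq_len(m)) if (r != i)
      tab[r, ] <- tab[r, ] - tab[r, j] * tab[i, ]
    basis[i] <- j
  }
}

# Solve: optimise c'x subject to x >= 0, A_ub x <= b_ub, A_eq x = b_eq.
# Two-phase: artificials for the equality rows, then the real objective.
.lp_solve <- function(cc, a_ub, b_ub, a_eq, b_eq, maximize = TRUE,
                      tol = 1e-9) {
  n <- length(cc)
  m1 <- nrow(a_ub); m2 <- nrow(a_eq)
  flip <- b_eq < 0
  a_eq[flip, ] <- -a_eq[flip, , drop = FALSE]
  b_eq[flip] <- -b_eq[flip]
  n_tot <- n + m1 + m2                              # vars + slacks + artificials
  tab <- cbind(rbind(cbind(a_ub, diag(m1), matrix(0, m1, m2)),
                     cbind(a_eq, matrix(0, m2, m1), diag(m2))),
               c(b_ub, b_eq))
  basis <- c(n + seq_len(m1), n + m1 + seq_len(m2))

  phase1 <- c(rep(0, n + m1), rep(1, m2))
  res <- .simplex_iterate(tab, basis, phase1, allowed = rep(TRUE, n_tot), tol)
  infeas <- sum(phase1[res$basis] * res$tab[, n_tot + 1L])
  if (res$status != "optimal" || infeas > 1e-6)
    return(list(status = "infeasible", x = NULL, value = NA_real_))

  # drive any zero-valued artificial out of the basis (or drop its row if
  # redundant) so phase-2 pivots cannot resurrect it
  art_cols <- n + m1 + seq_len(m2)
  keep <- rep(TRUE, nrow(res$tab))
  for (i in which(res$basis %in% art_cols)) {
    piv <- which(abs(res$tab[i, seq_len(n + m1)]) > tol)
    if (!length(piv)) { keep[i] <- FALSE; next }    # redundant constraint
    j <- piv[1]
    res$tab[i, ] <- res$tab[i, ] / res$tab[i, j]
    for (r in seq_len(nrow(res$tab))) if (r != i)
      res$tab[r, ] <- res$tab[r, ] - res$tab[r, j] * res$tab[i, ]
    res$basis[i] <- j
  }
  res$tab <- res$tab[keep, , drop = FALSE]
  res$basis <- res$basis[keep]

  phase2 <- c(if (maximize) -cc else cc, rep(0, m1 + m2))
  allowed <- c(rep(TRUE, n + m1), rep(FALSE, m2))   # artificials locked out
  res <- .simplex_iterate(res$tab, res$basis, phase2, allowed, tol)
  if (res$status != "optimal")
    return(list(status = "unbounded", x = NULL, value = NA_real_))
  x <- numeric(n_tot)
  x[res$basis] <- res$tab[, n_tot + 1L]
  list(status = "optimal", x = x[seq_len(n)],
       value = sum(cc * x[seq_len(n)]))
}

#' Construct a constraint-based metabolic model
#'
#' Minimal container: metabolites (with optional chemical formulas for
#' balance checks), reactions as sparse stoichiometry maps with bounds,
#' and one objective reaction. Exchange reactions follow the usual
#' convention: a single boundary metabolite with coefficient -1, and
#' negative flux meaning uptake.
#'
#' @param id Model identifier.
#' @param metabolites Data frame with columns `id`, `formula` (may be
#'   `NA`), `boundary` (logical; boundary species are excluded from the
#'   steady-state constraint).
#' @param reactions Named list; each element a list with `stoich`
#'   (named numeric vector), `lb`, `ub`, and optionally `name`.
#' @param objective Reaction id to maximise.
#' @return Object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, objective) {
  stopifnot(is.data.frame(metabolites),
            all(c("id", "formula", "boundary") %in% names(metabolites)),
            is.list(reactions), objective %in% names(reactions))
  for (r in reactions) {
    if (!all(names(r$stoich) %in% metabolites$id))
      stop("reaction references unknown metabolite: ",
           paste(setdiff(names(r$stoich), metabolites$id), collapse = ", "))
    if (r$lb > r$ub) stop("reaction has lb > ub")
  }
  structure(list(id = id, metabolites = metabolites,
                 reactions = reactions, objective = objective),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model", x$id, ":", nrow(x$metabolites), "metabolites,",
      length(x$reactions), "reactions; objective =", x$objective, "\n")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' Rows are non-boundary metabolites, columns reactions.
#'
#' @param model A [metabolic_model()].
#' @return Dense numeric matrix with dimnames.
#' @export
stoichiometric_matrix <- function(model) {
  mets <- model$metabolites$id[!model$metabolites$boundary]
  rxns <- names(model$reactions)
  s <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    st <- model$reactions[[j]]$stoich
    keep <- names(st) %in% mets
    s[names(st)[keep], j] <- st[keep]
  }
  s
}

#' Set the flux bounds of a reaction
#'
#' @param model A [metabolic_model()].
#' @param reaction_id Reaction to modify.
#' @param lb,ub New bounds (either may be `NULL` to keep the current
#'   value).
#' @return The modified model.
#' @export
set_bounds <- function(model, reaction_id, lb = NULL, ub = NULL) {
  if (!reaction_id %in% names(model$reactions))
    stop("unknown reaction: ", reaction_id)
  if (!is.null(lb)) model$reactions[[reaction_id]]$lb <- lb
  if (!is.null(ub)) model$reactions[[reaction_id]]$ub <- ub
  model
}

# --- elemental bookkeeping ---------------------------------------------

# parse "C6H11O9P" -> c(C = 6, H = 11, O = 9, P = 1)
.parse_formula <- function(formula) {
  if (is.na(formula) || formula == "") return(numeric(0))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  counts <- numeric(0)
  for (p in parts) {
    el <- gsub("[0-9]", "", p)
    n <- gsub("[A-Za-z]", "", p)
    counts[el] <- (if (el %in% names(counts)) counts[el] else 0) +
      if (n == "") 1 else as.numeric(n)
  }
  counts
}

#' Check the elemental balance of a reaction
#'
#' Sums element counts weighted by stoichiometric coefficients using the
#' metabolite formulas. Exchange/boundary reactions are intrinsically
#' unbalanced and are skipped (returned as `NA`).
#'
#' @param model A [metabolic_model()].
#' @param reaction_id Reaction to check.
#' @param elements Elements to audit.
#' @return Named numeric of element imbalances (0 = balanced), or `NA`
#'   for exchange reactions.
#' @export
check_balance <- function(model, reaction_id,
                          elements = c("C", "H", "O", "N", "P")) {
  r <- model$reactions[[reaction_id]]
  if (is.null(r)) stop("unknown reaction: ", reaction_id)
  met_tab <- model$metabolites
  if (any(met_tab$boundary[match(names(r$stoich), met_tab$id)]) ||
      length(r$stoich) == 1)
    return(NA)
  bal <- stats::setNames(numeric(length(elements)), elements)
  for (m in names(r$stoich)) {
    f <- met_tab$formula[match(m, met_tab$id)]
    if (is.na(f))
      stop("metabolite ", m, " has no formula; cannot audit balance")
    cnt <- .parse_formula(f)
    for (el in intersect(names(cnt), elements))
      bal[el] <- bal[el] + r$stoich[[m]] * cnt[el]
  }
  bal
}

# --- heterologous pathway ----------------------------------------------

#' Heterologous methanol-assimilation reactions
#'
#' The three enzymatic steps grafted into E. coli — Mdh (methanol + NAD+
#' -> formaldehyde + NADH + H+), Hps (formaldehyde + Ru5P -> H6P) and
#' Phi (H6P -> F6P) — plus passive methanol diffusion across the
#' membrane and a methanol exchange. New metabolites (extracellular and
#' cytosolic methanol, formaldehyde, H6P) carry chemical formulas so
#' every enzymatic reaction can be audited for elemental balance.
#'
#' @return List with `metabolites` (data frame) and `reactions` (named
#'   list in [metabolic_model()] format). Cofactor/sugar species
#'   (`nad`, `nadh`, `h`, `ru5p`, `f6p`) are assumed to exist in the
#'   host model.
#' @export
heterologous_reactions <- function() {
  metabolites <- data.frame(
    id = c("meoh_e", "meoh", "fald", "h6p"),
    formula = c("CH4O", "CH4O", "CH2O", "C6H11O9P"),
    boundary = c(FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  reactions <- list(
    EX_meoh = list(name = "methanol exchange",
                   stoich = c(meoh_e = -1), lb = 0, ub = .BOUND_INF),
    MEOHt = list(name = "methanol passive diffusion",
                 stoich = c(meoh_e = -1, meoh = 1),
                 lb = -.BOUND_INF, ub = .BOUND_INF),
    MDH = list(name = "methanol dehydrogenase",
               stoich = c(meoh = -1, nad = -1, fald = 1, nadh = 1, h = 1),
               lb = 0, ub = .BOUND_INF),
    HPS = list(name = "hexulose phosphate synthase",
               stoich = c(fald = -1, ru5p = -1, h6p = 1),
               lb = 0, ub = .BOUND_INF),
    PHI = list(name = "phosphohexulose isomerase",
               stoich = c(h6p = -1, f6p = 1),
               lb = 0, ub = .BOUND_INF))
  list(metabolites = metabolites, reactions = reactions)
}

#' Amend a model with the methanol-assimilation pathway
#'
#' Adds the [heterologous_reactions()] metabolites and reactions to a
#' host model. Errors if the host lacks the assumed cofactor species.
#'
#' @param model Host [metabolic_model()] containing `nad`, `nadh`, `h`,
#'   `ru5p` and `f6p`.
#' @param include Character vector of reaction ids to add (default all;
#'   useful for knockout-style omission tests).
#' @return The amended model.
#' @export
amend_with_methanol_pathway <- function(model,
                                        include = c("EX_meoh", "MEOHt", "MDH",
                                                    "HPS", "PHI")) {
  het <- heterologous_reactions()
  needed <- c("nad", "nadh", "h", "ru5p", "f6p")
  missing <- setdiff(needed, model$metabolites$id)
  if (length(missing))
    stop("host model lacks required species: ", paste(missing, collapse = ", "))
  new_mets <- het$metabolites[!het$metabolites$id %in% model$metabolites$id, ]
  model$metabolites <- rbind(model$metabolites, new_mets)
  for (id in include) model$reactions[[id]] <- het$reactions[[id]]
  metabolic_model(model$id, model$metabolites, model$reactions,
                  model$objective)
}

#' Bundled toy RuMP-cycle host model
#'
#' A deliberately small synthetic E. coli stand-in (~13 reactions before
#' amendment): glucose uptake and lumped glycolysis, a reversible lumped
#' transketolase/transaldolase rearrangement (5 F6P <-> 6 Ru5P) that
#' closes the RuMP cycle, NADH reoxidation, and a two-pyruvate biomass
#' reaction. Growth is linear in substrate uptake, so uptake-matching
#' results can be verified by hand. Not a curated reconstruction; used
#' for tests and examples.
#'
#' @param glc_uptake Glucose uptake bound (mmol gDCW-1 h-1 style units);
#'   default 0 (closed).
#' @return A [metabolic_model()].
#' @export
toy_rump_model <- function(glc_uptake = 0) {
  metabolites <- data.frame(
    id = c("glc_e", "glc", "g6p", "f6p", "g3p", "pyr", "ru5p",
           "nad", "nadh", "h", "biomass"),
    formula = c("C6H12O6", "C6H12O6", "C6H11O9P", "C6H11O9P", "C3H5O6P",
                "C3H3O3", "C5H9O8P", "C21H26N7O14P2", "C21H27N7O14P2",
                "H", NA),
    boundary = FALSE,
    stringsAsFactors = FALSE)
  inf <- .BOUND_INF
  reactions <- list(
    EX_glc = list(name = "glucose exchange",
                  stoich = c(glc_e = -1), lb = -abs(glc_uptake), ub = inf),
    GLCt = list(name = "glucose transport",
                stoich = c(glc_e = -1, glc = 1), lb = 0, ub = inf),
    HEX = list(name = "hexokinase (lumped)",
               stoich = c(glc = -1, g6p = 1), lb = 0, ub = inf),
    PGI = list(name = "phosphoglucose isomerase",
               stoich = c(g6p = -1, f6p = 1), lb = -inf, ub = inf),
    UGLY = list(name = "upper glycolysis (lumped F6P -> 2 G3P)",
                stoich = c(f6p = -1, g3p = 2), lb = 0, ub = inf),
    GAPD = list(name = "GAPDH + lower glycolysis (lumped)",
                stoich = c(g3p = -1, nad = -1, pyr = 1, nadh = 1),
                lb = 0, ub = inf),
    TKT = list(name = "non-oxidative PPP rearrangement (lumped 5 F6P <-> 6 Ru5P)",
               stoich = c(f6p = -5, ru5p = 6), lb = -inf, ub = inf),
    NADHOX = list(name = "NADH reoxidation (respiration, lumped)",
                  stoich = c(nadh = -1, h = -1, nad = 1), lb = 0, ub = inf),
    HSRC = list(name = "proton buffering (lumped)",
                stoich = c(h = 1), lb = -inf, ub = inf),
    BIOMASS = list(name = "biomass from pyruvate",
                   stoich = c(pyr = -2, biomass = 1), lb = 0, ub = inf),
    EX_biomass = list(name = "biomass sink",
                      stoich = c(biomass = -1), lb = 0, ub = inf))
  metabolic_model("toy_rump_synthetic", metabolites, reactions, "EX_biomass")
}

# --- LP layer -----------------------------------------------------------

#' Flux balance analysis of a model
#'
#' Maximises the objective reaction subject to S v = 0 and the flux
#' bounds, as the usual LP over the steady-state flux polytope after
#' shifting fluxes to non-negative variables.
#'
#' @param model A [metabolic_model()].
#' @param objective Reaction to optimise (default the model objective).
#' @param maximize Direction.
#' @return List of class `fba_solution`: `status` ("optimal" or
#'   "infeasible"), `objective_value`, `fluxes` (named vector).
#' @export
fba <- function(model, objective = model$objective, maximize = TRUE) {
  s <- stoichiometric_matrix(model)
  rxns <- colnames(s)
  lb <- vapply(model$reactions, function(r) r$lb, numeric(1))[rxns]
  ub <- vapply(model$reactions, function(r) r$ub, numeric(1))[rxns]
  n <- length(rxns)
  obj <- stats::setNames(numeric(n), rxns); obj[objective] <- 1
  # x = v - lb >= 0 ; x <= ub - lb ; S x = -S lb
  out <- .lp_solve(cc = unname(obj),
                   a_ub = diag(n), b_ub = unname(ub - lb),
                   a_eq = unname(s), b_eq = as.numeric(-s %*% lb),
                   maximize = maximize)
  if (out$status != "optimal")
    return(structure(list(status = out$status, objective_value = NA_real_,
                          fluxes = stats::setNames(rep(NA_real_, n), rxns)),
                     class = "fba_solution"))
  v <- stats::setNames(out$x + lb, rxns)
  structure(list(status = "optimal",
                 objective_value = unname(v[objective]),
                 fluxes = v),
            class = "fba_solution")
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("FBA solution:", x$status)
  if (x$status == "optimal") cat(", objective =", signif(x$objective_value, 6))
  cat("\n")
  invisible(x)
}

#' Flux variability at (near-)optimal growth
#'
#' Fixes the objective at `fraction` of its optimum and reports the
#' min/max attainable flux for each requested reaction, guarding flux
#' comparisons against alternate-optima artefacts.
#'
#' @param model A [metabolic_model()].
#' @param reactions Reaction ids to range.
#' @param fraction Fraction of the optimal objective to enforce.
#' @return Data frame `reaction`, `min`, `max`.
#' @export
fva <- function(model, reactions, fraction = 1.0) {
  sol <- fba(model)
  if (sol$status != "optimal") stop("model is infeasible; cannot run FVA")
  target <- sol$objective_value * fraction
  m2 <- set_bounds(model, model$objective, lb = target)
  out <- lapply(reactions, function(r) {
    lo <- fba(m2, objective = r, maximize = FALSE)
    hi <- fba(m2, objective = r, maximize = TRUE)
    data.frame(reaction = r, min = lo$objective_value,
               max = hi$objective_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Find the substrate uptake reproducing a target growth rate
#'
#' Bisects the uptake bound of an exchange reaction (uptake = negative
#' exchange flux) for the smallest uptake whose optimal growth comes
#' within `tol` (relative) of `target_growth`. Growth must be
#' non-decreasing in uptake over `bounds`, which holds for any FBA model
#' (relaxing a bound cannot shrink the feasible set).
#'
#' @param model A [metabolic_model()].
#' @param exchange_id Substrate exchange reaction.
#' @param target_growth Target objective value (> 0).
#' @param tol Relative tolerance (> 0), default 0.02.
#' @param bounds Uptake search interval (positive magnitudes).
#' @return List: `uptake`, `growth`, `solution`.
#' @export
match_growth_by_uptake <- function(model, exchange_id, target_growth,
                                   tol = 0.02, bounds = c(0, .BOUND_INF)) {
  if (tol <= 0) stop("tol must be positive")
  if (target_growth <= 0) stop("target growth must be positive")
  growth_at <- function(u) {
    sol <- fba(set_bounds(model, exchange_id, lb = -u))
    if (sol$status != "optimal") 0 else sol$objective_value
  }
  g_hi <- growth_at(bounds[2])
  if (g_hi < target_growth * (1 - tol))
    stop("target growth unreachable: maximum achievable is ",
         signif(g_hi, 4), " at uptake ", bounds[2])
  lo <- bounds[1]; hi <- bounds[2]
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (growth_at(mid) >= target_growth * (1 - tol)) hi <- mid else lo <- mid
    if ((hi - lo) < 1e-9 * max(1, hi)) break
  }
  sol <- fba(set_bounds(model, exchange_id, lb = -hi))
  list(uptake = hi, growth = sol$objective_value, solution = sol)
}

#' Carbon-normalised (proportional) flux
#'
#' Flux through a reaction divided by the carbon-molar substrate uptake,
#' making flux maps on substrates of different carbon number (glucose
#' C6 vs methanol C1) commensurate. The normalisation choice is recorded
#' on the result.
#'
#' @param solution An [fba()] solution.
#' @param model The model the solution came from (for carbon counts).
#' @param reaction_id Reaction of interest.
#' @param exchange_id Substrate exchange reaction (uptake must be
#'   nonzero in the solution).
#' @return Dimensionless proportional flux (per C-mol substrate
#'   uptake).
#' @export
proportional_flux <- function(solution, model, reaction_id, exchange_id) {
  stopifnot(inherits(solution, "fba_solution"))
  if (solution$status != "optimal") stop("solution is not optimal")
  uptake <- -solution$fluxes[exchange_id]
  if (is.na(uptake) || uptake <= 0) stop("no substrate uptake in solution")
  met <- names(model$reactions[[exchange_id]]$stoich)[1]
  f <- model$metabolites$formula[match(met, model$metabolites$id)]
  nc <- .parse_formula(f)["C"]
  if (is.na(nc) || nc == 0) stop("substrate has no carbon formula")
  unname(abs(solution$fluxes[reaction_id]) / (uptake * nc))
}
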