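# Minimal SBML Level 3 (core + fbc v2) reader/writer for
# metabolic_model objects. Covers exactly the subset the bundled toy
# model uses: species with chemical formulas and boundary flags,
# reactions with reactant/product stoichiometries, flux bounds as fbc
# parameters, and one maximisation objective. Not a general SBML
# implementation.

.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Write a metabolic model as SBML Level 3 with fbc annotations
#'
#' @param model A [metabolic_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", gsub(">", "&gt;", x)))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            .SBML_NS, .FBC_NS),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$id)),
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    frm <- if (is.na(m$formula)) "" else
      sprintf(' fbc:chemicalFormula="%s"', esc(m$formula))
    lines <- c(lines, sprintf(
      '      <species id="%s" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="%s" constant="false"%s/>',
      esc(m$id), tolower(as.character(m$boundary)), frm))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  bound_params <- new.env()
  pid <- function(val) {
    key <- sprintf("B_%s", gsub("[^0-9A-Za-z]", "_", format(val, scientific = FALSE)))
    assign(key, val, envir = bound_params)
    key
  }
  rx_bounds <- lapply(model$reactions, function(r)
    c(lower = pid(r$lb), upper = pid(r$ub)))
  for (key in ls(bound_params))
    lines <- c(lines, sprintf(
      '      <parameter id="%s" value="%s" constant="true"/>',
      key, format(get(key, envir = bound_params), scientific = FALSE)))
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (rid in names(model$reactions)) {
    r <- model$reactions[[rid]]
    bp <- rx_bounds[[rid]]
    lines <- c(lines, sprintf(
      '      <reaction id="%s" name="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      esc(rid), esc(if (is.null(r$name)) rid else r$name),
      tolower(as.character(r$lb < 0)), bp["lower"], bp["upper"]))
    reac <- r$stoich[r$stoich < 0]
    prod <- r$stoich[r$stoich > 0]
    if (length(reac)) {
      lines <- c(lines, '        <listOfReactants>',
                 sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         esc(names(reac)), format(-reac, scientific = FALSE)),
                 '        </listOfReactants>')
    }
    if (length(prod)) {
      lines <- c(lines, '        <listOfProducts>',
                 sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         esc(names(prod)), format(prod, scientific = FALSE)),
                 '        </listOfProducts>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines,
    '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
            esc(model$objective)),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '  </model>',
    '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

#' Read an SBML Level 3 (fbc) model
#'
#' Parses the subset written by [write_sbml()]: species, reaction
#' stoichiometries, fbc flux bounds and the active maximisation
#' objective. Reactions lacking fbc bounds default to
#' (-1000, 1000) if marked reversible, (0, 1000) otherwise.
#'
#' @param path SBML file path.
#' @return A [metabolic_model()].
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = .SBML_NS, fbc = .FBC_NS)
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (is.na(xml2::xml_attr(model_node, "id")) && length(model_node) == 0)
    stop("no <model> element found")
  mid <- xml2::xml_attr(model_node, "id")

  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  metabolites <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    formula = xml2::xml_attr(sp, "fbc:chemicalFormula", ns = ns),
    boundary = xml2::xml_attr(sp, "boundaryCondition") == "true",
    stringsAsFactors = FALSE)

  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                           xml2::xml_attr(pars, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  reactions <- list()
  for (rx in rx_nodes) {
    rid <- xml2::xml_attr(rx, "id")
    get_side <- function(xp, sign) {
      refs <- xml2::xml_find_all(rx, xp, ns)
      if (!length(refs)) return(numeric(0))
      stats::setNames(sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                      xml2::xml_attr(refs, "species"))
    }
    st_r <- get_side("./s:listOfReactants/s:speciesReference", -1)
    st_p <- get_side("./s:listOfProducts/s:speciesReference", +1)
    st <- c(st_r, st_p)
    # merge duplicated species across sides
    st <- tapply(st, names(st), sum)
    st <- stats::setNames(as.numeric(st), names(st))
    lb_id <- xml2::xml_attr(rx, "fbc:lowerFluxBound", ns = ns)
    ub_id <- xml2::xml_attr(rx, "fbc:upperFluxBound", ns = ns)
    rev <- identical(xml2::xml_attr(rx, "reversible"), "true")
    lb <- if (!is.na(lb_id) && lb_id %in% names(pvals)) pvals[[lb_id]]
          else if (rev) -.BOUND_INF else 0
    ub <- if (!is.na(ub_id) && ub_id %in% names(pvals)) pvals[[ub_id]]
          else .BOUND_INF
    reactions[[rid]] <- list(name = xml2::xml_attr(rx, "name"),
                             stoich = st, lb = lb, ub = ub)
  }

  obj_node <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  objective <- xml2::xml_attr(obj_node, "fbc:reaction", ns = ns)
  if (is.na(objective)) stop("no fbc objective found in SBML file")
  metabolic_model(mid, metabolites, reactions, objective)
}
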