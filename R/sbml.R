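SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Default SBML compartment-id mapping
#'
#' Maps SBML compartment ids to the three compartments used here. Pass a
#' modified copy to [read_sbml()] for models with other naming schemes.
#' @return named character vector, SBML id -> compartment.
#' @export
sbml_compartment_map <- function() {
  c(c = "cytoplasm", cyt = "cytoplasm", cytosol = "cytoplasm",
    cytoplasm = "cytoplasm",
    p = "periplasm", per = "periplasm", periplasm = "periplasm",
    e = "extracellular", ext = "extracellular",
    extracellular = "extracellular")
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a model to SBML
#'
#' Emits SBML Level 3 Version 1 with the flux-balance-constraints (fbc)
#' version 2 extension: species, per-reaction bound parameters and the active
#' objective. Refuses models that fail [validate_model()] or have no
#' reactions. Output formatting is deterministic, so writing the same model
#' twice yields byte-identical files.
#'
#' @param model a valid `metabolic_model` with at least one reaction.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  validate_model(model)
  if (length(model$reactions) == 0L) stop("refusing to write a model with no reactions")
  comp_id <- c(cytoplasm = "c", periplasm = "p", extracellular = "e")
  ids <- c(model$mets$id, reaction_ids(model))
  bad <- ids[!grepl("^[A-Za-z_][A-Za-z0-9_]*$", ids)]
  if (length(bad)) stop("ids not valid SBML SIds: ", paste(bad, collapse = ", "))

  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  L <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="', SBML_CORE_NS, '" xmlns:fbc="', SBML_FBC_NS,
           '" level="3" version="1" fbc:required="false">'),
    paste0('  <model id="', esc(model$id), '" fbc:strict="true">'),
    '    <listOfCompartments>')
  for (cp in COMPARTMENTS) {
    if (any(model$mets$compartment == cp))
      L <- c(L, paste0('      <compartment id="', comp_id[[cp]], '" name="', cp,
                       '" constant="true"/>'))
  }
  L <- c(L, '    </listOfCompartments>', '    <listOfSpecies>')
  for (i in seq_len(nrow(model$mets))) {
    m <- model$mets[i, ]
    extra <- ""
    if (!is.na(m$formula))
      extra <- paste0(extra, ' fbc:chemicalFormula="', esc(m$formula), '"')
    if (!is.na(m$charge))
      extra <- paste0(extra, ' fbc:charge="', m$charge, '"')
    L <- c(L, paste0('      <species id="', m$id, '" name="', esc(m$name),
                     '" compartment="', comp_id[[m$compartment]],
                     '" hasOnlySubstanceUnits="false" boundaryCondition="false"',
                     ' constant="false"', extra, '/>'))
  }
  L <- c(L, '    </listOfSpecies>', '    <listOfParameters>')
  for (r in model$reactions) {
    L <- c(L,
      paste0('      <parameter id="bnd_', r$id, '_lb" value="', fmt_num(r$lb),
             '" constant="true"/>'),
      paste0('      <parameter id="bnd_', r$id, '_ub" value="', fmt_num(r$ub),
             '" constant="true"/>'))
  }
  L <- c(L, '    </listOfParameters>', '    <listOfReactions>')
  for (r in model$reactions) {
    L <- c(L, paste0('      <reaction id="', r$id, '" name="', esc(r$name),
                     '" reversible="', tolower(r$lb < 0), '" fast="false"',
                     ' fbc:lowerFluxBound="bnd_', r$id, '_lb"',
                     ' fbc:upperFluxBound="bnd_', r$id, '_ub">'))
    subs <- r$stoich[r$stoich < 0]
    prods <- r$stoich[r$stoich > 0]
    if (length(subs)) {
      L <- c(L, '        <listOfReactants>')
      for (s in names(subs))
        L <- c(L, paste0('          <speciesReference species="', s,
                         '" stoichiometry="', fmt_num(-subs[[s]]),
                         '" constant="true"/>'))
      L <- c(L, '        </listOfReactants>')
    }
    if (length(prods)) {
      L <- c(L, '        <listOfProducts>')
      for (s in names(prods))
        L <- c(L, paste0('          <speciesReference species="', s,
                         '" stoichiometry="', fmt_num(prods[[s]]),
                         '" constant="true"/>'))
      L <- c(L, '        </listOfProducts>')
    }
    L <- c(L, '      </reaction>')
  }
  L <- c(L, '    </listOfReactions>',
         '    <fbc:listOfObjectives fbc:activeObjective="obj">',
         paste0('      <fbc:objective fbc:id="obj" fbc:type="',
                model$objective_sense, '">'),
         '        <fbc:listOfFluxObjectives>',
         paste0('          <fbc:fluxObjective fbc:reaction="',
                model$objective_id, '" fbc:coefficient="1"/>'),
         '        </fbc:listOfFluxObjectives>',
         '      </fbc:objective>',
         '    </fbc:listOfObjectives>',
         '  </model>', '</sbml>')
  writeLines(L, path)
  invisible(path)
}

#' Read a model from SBML
#'
#' Parses SBML Level 3 with the fbc extension. Flux bounds and an active
#' objective are required: models lacking them are rejected rather than
#' silently defaulted.
#'
#' @param path SBML file path.
#' @param compartment_map named character vector translating SBML compartment
#'   ids to `"cytoplasm"`/`"periplasm"`/`"extracellular"`; see
#'   [sbml_compartment_map()].
#' @return a validated `metabolic_model`.
#' @export
read_sbml <- function(path, compartment_map = sbml_compartment_map()) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path,
                                           "': ", conditionMessage(e)))
  x1 <- function(node, xp) xml2::xml_find_first(node, xp)
  xa <- function(node, xp) xml2::xml_find_all(node, xp)
  mdl <- x1(doc, ".//*[local-name()='model']")
  if (inherits(mdl, "xml_missing")) stop("SBML parse failure: no <model> element")
  model_id <- xml2::xml_attr(mdl, "id")
  if (is.na(model_id)) model_id <- "model"

  # compartments
  comp_nodes <- xa(mdl, ".//*[local-name()='listOfCompartments']/*[local-name()='compartment']")
  comp_ids <- xml2::xml_attr(comp_nodes, "id")
  comp_of <- character(0)
  for (cid in comp_ids) {
    if (!cid %in% names(compartment_map))
      stop("compartment '", cid, "' not covered by the compartment map")
    comp_of[cid] <- compartment_map[[cid]]
  }

  # species
  sp <- xa(mdl, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (length(sp) == 0L) stop("SBML parse failure: no species")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = unname(comp_of[xml2::xml_attr(sp, "compartment")]),
    formula = xml2::xml_attr(sp, "chemicalFormula"),
    charge = suppressWarnings(as.integer(xml2::xml_attr(sp, "charge"))),
    stringsAsFactors = FALSE)
  if (any(is.na(mets$id) | !nzchar(mets$id)))
    stop("SBML parse failure: species without id")
  if (any(is.na(mets$compartment)))
    stop("SBML parse failure: species with unmapped compartment")

  # parameters (flux bounds)
  par_nodes <- xa(mdl, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))

  # reactions
  rx_nodes <- xa(mdl, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rx_nodes) == 0L) stop("SBML parse failure: no reactions")
  reactions <- vector("list", length(rx_nodes))
  for (i in seq_along(rx_nodes)) {
    nd <- rx_nodes[[i]]
    rid <- xml2::xml_attr(nd, "id")
    if (is.na(rid)) stop("SBML parse failure: reaction without id")
    lb_ref <- xml2::xml_attr(nd, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(nd, "upperFluxBound")
    if (is.na(lb_ref) || is.na(ub_ref))
      stop("reaction '", rid, "': missing fbc flux bounds (no defaults applied)")
    if (!lb_ref %in% names(par_val) || !ub_ref %in% names(par_val))
      stop("reaction '", rid, "': flux-bound parameter not found")
    refs <- xa(nd, ".//*[local-name()='listOfReactants']/*[local-name()='speciesReference']")
    prods <- xa(nd, ".//*[local-name()='listOfProducts']/*[local-name()='speciesReference']")
    sto <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                      xml2::xml_attr(refs, "species")),
      stats::setNames(as.numeric(xml2::xml_attr(prods, "stoichiometry")),
                      xml2::xml_attr(prods, "species")))
    if (length(sto) == 0L)
      stop("reaction '", rid, "': empty stoichiometry")
    if (any(is.na(sto)))
      stop("reaction '", rid, "': malformed speciesReference")
    nm <- xml2::xml_attr(nd, "name")
    reactions[[i]] <- reaction(rid, sto, par_val[[lb_ref]], par_val[[ub_ref]],
                               name = if (is.na(nm)) rid else nm)
  }

  # objective
  fobj <- x1(mdl, ".//*[local-name()='listOfObjectives']/*[local-name()='objective']")
  if (inherits(fobj, "xml_missing"))
    stop("SBML parse failure: no fbc objective (no defaults applied)")
  sense <- xml2::xml_attr(fobj, "type")
  fo <- x1(fobj, ".//*[local-name()='fluxObjective']")
  if (inherits(fo, "xml_missing"))
    stop("SBML parse failure: objective without fluxObjective")
  obj_rid <- xml2::xml_attr(fo, "reaction")

  new_model(mets, reactions, objective_id = obj_rid,
            objective_sense = match.arg(sense, c("maximize", "minimize")),
            id = model_id)
}
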