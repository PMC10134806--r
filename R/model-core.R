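COMPARTMENTS <- c("cytoplasm", "periplasm", "extracellular")

#' Create a metabolite
#'
#' @param id nonempty metabolite identifier, unique within a model.
#' @param name human-readable name (defaults to `id`).
#' @param compartment one of `"cytoplasm"`, `"periplasm"`, `"extracellular"`.
#' @param formula optional chemical formula string (e.g. `"C6H12O6"`).
#' @param charge optional integer charge.
#' @return a one-row data frame describing the metabolite.
#' @export
metabolite <- function(id, name = id, compartment, formula = NA_character_,
                       charge = NA_integer_) {
  stopifnot(is.character(id), nzchar(id), length(id) == 1L)
  compartment <- match.arg(compartment, COMPARTMENTS)
  data.frame(id = id, name = name, compartment = compartment,
             formula = as.character(formula), charge = as.integer(charge),
             stringsAsFactors = FALSE)
}

#' Create a reaction
#'
#' Stoichiometric coefficients are negative for consumed metabolites and
#' positive for produced ones. Flux bounds are in mmol/gCDW/h (the biomass
#' reaction's flux is in 1/h).
#'
#' @param id reaction identifier, unique within a model.
#' @param stoich named numeric vector: metabolite id -> coefficient.
#' @param lb,ub lower/upper flux bound; `lb <= ub`, both finite in models
#'   meant for FBA (use +-1000 for "unconstrained").
#' @param name human-readable name.
#' @return an object of class `"gem_reaction"`.
#' @export
reaction <- function(id, stoich, lb, ub, name = id) {
  stopifnot(is.character(id), nzchar(id), length(id) == 1L)
  if (length(stoich) == 0L || is.null(names(stoich)) || any(!nzchar(names(stoich))))
    stop("reaction '", id, "': stoichiometry must be a nonempty named vector")
  if (any(!is.finite(stoich)))
    stop("reaction '", id, "': stoichiometric coefficients must be finite")
  if (!is.numeric(lb) || !is.numeric(ub) || is.na(lb) || is.na(ub))
    stop("reaction '", id, "': bounds must be numeric")
  if (lb > ub) stop("reaction '", id, "': lower bound exceeds upper bound")
  structure(list(id = id, name = name, stoich = stoich,
                 lb = as.numeric(lb), ub = as.numeric(ub)),
            class = "gem_reaction")
}

#' Assemble a metabolic model
#'
#' @param metabolites data frame of metabolites (rows from [metabolite()]).
#' @param reactions list of [reaction()] objects.
#' @param objective_id id of the objective reaction (typically biomass).
#' @param objective_sense `"maximize"` or `"minimize"`.
#' @param id model identifier.
#' @return an object of class `"metabolic_model"`.
#' @export
new_model <- function(metabolites, reactions, objective_id,
                      objective_sense = c("maximize", "minimize"),
                      id = "model") {
  objective_sense <- match.arg(objective_sense)
  model <- structure(list(id = id, mets = metabolites, reactions = reactions,
                          objective_id = objective_id,
                          objective_sense = objective_sense),
                     class = "metabolic_model")
  names(model$reactions) <- vapply(reactions, `[[`, "", "id")
  validate_model(model)
  model
}

#' Validate model invariants
#'
#' Checks id uniqueness, referenced metabolites, bound ordering and the
#' existence of the objective reaction. Called by constructors and the SBML
#' reader; exported for use on hand-edited models.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; stops on violation.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mids <- model$mets$id
  if (anyDuplicated(mids)) stop("duplicate metabolite ids")
  if (any(!model$mets$compartment %in% COMPARTMENTS))
    stop("metabolite compartments must be one of: ",
         paste(COMPARTMENTS, collapse = ", "))
  rids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(rids)) stop("duplicate reaction ids")
  for (r in model$reactions) {
    miss <- setdiff(names(r$stoich), mids)
    if (length(miss))
      stop("reaction '", r$id, "' references unknown metabolites: ",
           paste(miss, collapse = ", "))
    if (r$lb > r$ub) stop("reaction '", r$id, "': lb > ub")
  }
  if (!model$objective_id %in% rids)
    stop("objective reaction '", model$objective_id, "' not in model")
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  st <- model_stats(x)
  cat("<metabolic_model> ", x$id, "\n",
      "  reactions:   ", st$total_reactions,
      " (", st$internal_reactions, " internal, ",
      st$transport_reactions, " transport, ",
      st$exchange_reactions, " exchange)\n",
      "  metabolites: ", st$total_metabolites,
      " (", st$intracellular, "c / ", st$periplasmic, "p / ",
      st$extracellular, "e)\n",
      "  objective:   ", x$objective_sense, " ", x$objective_id, "\n",
      sep = "")
  invisible(x)
}

reaction_ids <- function(model) unname(vapply(model$reactions, `[[`, "", "id"))

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix, metabolites x reactions, dimnames set.
#' @export
stoichiometric_matrix <- function(model) {
  mids <- model$mets$id
  rids <- reaction_ids(model)
  S <- matrix(0, length(mids), length(rids), dimnames = list(mids, rids))
  for (r in model$reactions) S[names(r$stoich), r$id] <- r$stoich
  S
}

#' Add, replace or remove reactions
#'
#' `add_reaction()` appends (or, with `replace = TRUE`, overwrites) a reaction;
#' `remove_reaction()` drops one. Both return a modified copy.
#'
#' @param model a `metabolic_model`.
#' @param rxn a [reaction()].
#' @param replace overwrite an existing reaction of the same id.
#' @return the modified model.
#' @export
add_reaction <- function(model, rxn, replace = FALSE) {
  stopifnot(inherits(rxn, "gem_reaction"))
  if (rxn$id %in% reaction_ids(model) && !replace)
    stop("reaction '", rxn$id, "' already in model")
  model$reactions[[rxn$id]] <- rxn
  validate_model(model)
}

#' @rdname add_reaction
#' @param id reaction id to remove.
#' @export
remove_reaction <- function(model, id) {
  if (!id %in% reaction_ids(model)) stop("no reaction '", id, "' in model")
  model$reactions[[id]] <- NULL
  model
}

#' Add a metabolite to a model
#' @param model a `metabolic_model`.
#' @param met a one-row data frame from [metabolite()].
#' @return the modified model.
#' @export
add_metabolite <- function(model, met) {
  if (met$id %in% model$mets$id) stop("metabolite '", met$id, "' already in model")
  model$mets <- rbind(model$mets, met)
  model
}

#' Flux balance analysis
#'
#' Solves the linear program `max c'v  s.t.  S v = 0, lb <= v <= ub` where the
#' objective selects the model's objective reaction (growth maximisation for a
#' biomass objective). Infeasibility and unboundedness are reported as
#' statuses, not errors.
#'
#' @param model a valid `metabolic_model`.
#' @return a `flux_solution`: list with `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`), `objective_value`, and `fluxes` (named vector,
#'   mmol/gCDW/h; the biomass flux in 1/h).
#' @export
fba <- function(model) {
  validate_model(model)
  S <- stoichiometric_matrix(model)
  lb <- vapply(model$reactions, `[[`, 0, "lb")
  ub <- vapply(model$reactions, `[[`, 0, "ub")
  obj <- as.numeric(colnames(S) == model$objective_id)
  res <- lp_solve(obj, S, rep(0, nrow(S)), lb, ub,
                  maximize = model$objective_sense == "maximize")
  fl <- if (res$status == "optimal") stats::setNames(res$x, colnames(S)) else NULL
  structure(list(status = res$status,
                 objective_value = if (res$status == "optimal") res$objective else NA_real_,
                 fluxes = fl),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status:", x$status,
      if (x$status == "optimal") paste0(" objective: ", signif(x$objective_value, 6)),
      "\n")
  invisible(x)
}

#' Exchange reaction ids of a model
#'
#' An exchange reaction touches exactly one metabolite (boundary
#' pseudo-reaction `metabolite <-> nothing`).
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids.
#' @export
exchanges <- function(model) {
  rids <- reaction_ids(model)
  rids[vapply(model$reactions, function(r) length(r$stoich) == 1L, TRUE)]
}

#' Set the growth medium
#'
#' Overrides bounds on exchange reactions; uptake is a negative flux, so a
#' medium that supplies a substrate sets a negative lower bound on its
#' exchange. Returns a modified copy; the input model is untouched.
#'
#' @param model a `metabolic_model`.
#' @param exchange_bounds named list: exchange reaction id -> `c(lb, ub)`.
#' @return the modified model.
#' @export
set_medium <- function(model, exchange_bounds) {
  ex <- exchanges(model)
  for (id in names(exchange_bounds)) {
    if (!id %in% ex) stop("'", id, "' is not an exchange reaction of the model")
    bd <- exchange_bounds[[id]]
    if (length(bd) != 2L || any(!is.finite(bd))) stop("bounds for '", id,
                                                      "' must be c(lb, ub)")
    if (bd[1] > bd[2]) stop("bounds for '", id, "': lb > ub")
    model$reactions[[id]]$lb <- bd[1]
    model$reactions[[id]]$ub <- bd[2]
  }
  model
}

#' Model summary statistics
#'
#' Classifies reactions as exchange (touching exactly one metabolite),
#' transport (non-exchange, metabolites spanning at least two compartments) or
#' internal, and counts metabolites per compartment.
#'
#' @param model a `metabolic_model`.
#' @return list with `total_reactions`, `internal_reactions`,
#'   `transport_reactions`, `exchange_reactions`, `total_metabolites`,
#'   `intracellular`, `periplasmic`, `extracellular`.
#' @export
model_stats <- function(model) {
  comp <- stats::setNames(model$mets$compartment, model$mets$id)
  n_ex <- 0L; n_tr <- 0L; n_in <- 0L
  for (r in model$reactions) {
    if (length(r$stoich) == 1L) n_ex <- n_ex + 1L
    else if (length(unique(comp[names(r$stoich)])) >= 2L) n_tr <- n_tr + 1L
    else n_in <- n_in + 1L
  }
  tab <- table(factor(model$mets$compartment, levels = COMPARTMENTS))
  list(total_reactions = length(model$reactions),
       internal_reactions = n_in,
       transport_reactions = n_tr,
       exchange_reactions = n_ex,
       total_metabolites = nrow(model$mets),
       intracellular = unname(tab[["cytoplasm"]]),
       periplasmic = unname(tab[["periplasm"]]),
       extracellular = unname(tab[["extracellular"]]))
}
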