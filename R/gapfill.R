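#' A plate-reader growth curve
#'
#' @param substrate carbon source name.
#' @param times reading times (h), increasing.
#' @param od OD600 readings, nonnegative.
#' @param replicate replicate number.
#' @return a `plate_curve` object.
#' @export
plate_curve <- function(substrate, times, od, replicate = 1L) {
  stopifnot(length(times) == length(od))
  if (any(diff(times) <= 0)) stop("times must be increasing")
  if (any(od < 0)) stop("OD readings must be nonnegative")
  structure(list(substrate = substrate, times = as.numeric(times),
                 od = as.numeric(od), replicate = as.integer(replicate)),
            class = "plate_curve")
}

#' Growth call from a plate curve
#'
#' Growth means an OD600 increase of at least 0.9 within 20 h of inoculation.
#' Plates are read at most a few times a day, so the OD at exactly 20 h is
#' obtained by linear interpolation between the neighbouring readings; the
#' threshold is inclusive.
#'
#' @param curve a [plate_curve()] spanning at least 20 h.
#' @param threshold OD600 increase required (default 0.9).
#' @param within hours within which it must be reached (default 20).
#' @return logical growth call.
#' @export
call_growth <- function(curve, threshold = 0.9, within = 20) {
  stopifnot(inherits(curve, "plate_curve"))
  if (length(curve$times) < 2L || max(curve$times) < within)
    stop("curve must span at least ", within, " h")
  inside <- curve$od[curve$times <= within]
  od_at <- stats::approx(curve$times, curve$od, xout = within)$y
  max(c(inside, od_at)) - curve$od[1] >= threshold
}

#' A universal reaction database for gap-filling
#'
#' @param reactions list of candidate [reaction()]s (ids must be disjoint
#'   from any target model's).
#' @param source character tag(s) recording provenance (recycled).
#' @return a `universal_db` object.
#' @export
universal_db <- function(reactions, source = "universal") {
  ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate candidate reaction ids")
  structure(list(reactions = stats::setNames(reactions, ids),
                 source = rep_len(source, length(reactions))),
            class = "universal_db")
}

gapfill_feasible <- function(model, db, ids, min_biomass) {
  m <- model
  for (id in ids) m$reactions[[id]] <- db$reactions[[id]]
  m$reactions[[m$objective_id]]$lb <-
    max(m$reactions[[m$objective_id]]$lb, min_biomass)
  sol <- fba(m)
  list(ok = sol$status == "optimal", flux = sol$objective_value)
}

#' Parsimonious gap-filling
#'
#' Finds a provably minimum-cardinality set of database reactions whose
#' addition lets the biomass reaction carry at least `min_biomass` flux on
#' the given medium. Candidate subsets are searched in order of increasing
#' size and, within a size, in lexicographic order of reaction ids, so ties
#' are broken lexicographically and the first feasible subset found is a
#' certified optimum (all smaller subsets having been refuted). With a time
#' limit, the best incumbent is returned with `optimal = FALSE`.
#'
#' @param model a `metabolic_model` currently unable to grow on the medium.
#' @param db a [universal_db()]; candidate ids must be disjoint from the
#'   model's.
#' @param medium optional exchange bounds applied first (see [set_medium()]).
#' @param min_biomass biomass flux defining in silico growth (1/h).
#' @param time_limit seconds before falling back to the incumbent.
#' @return a `gapfill_result`: list with `added` (reaction ids),
#'   `achieved_biomass_flux` (optimal biomass flux with the additions) and
#'   `optimal` (minimality proven).
#' @export
gapfill <- function(model, db, medium = NULL, min_biomass = 1e-6,
                    time_limit = Inf) {
  stopifnot(inherits(db, "universal_db"))
  if (!is.null(medium)) model <- set_medium(model, medium)
  clash <- intersect(names(db$reactions), reaction_ids(model))
  if (length(clash))
    stop("candidate ids already in model: ", paste(clash, collapse = ", "))
  base <- fba(model)
  if (base$status == "optimal" && base$objective_value >= min_biomass) {
    return(structure(list(added = character(0),
                          achieved_biomass_flux = base$objective_value,
                          optimal = TRUE),
                     class = "gapfill_result"))
  }
  ids <- sort(names(db$reactions))
  full <- gapfill_feasible(model, db, ids, min_biomass)
  if (!full$ok)
    stop("unfillable gap: even the full candidate set does not enable growth")
  t0 <- Sys.time()
  incumbent <- ids
  for (k in seq_along(ids)) {
    sets <- utils::combn(ids, k, simplify = FALSE)
    for (s in sets) {
      if (as.numeric(Sys.time() - t0, units = "secs") > time_limit) {
        r <- gapfill_feasible(model, db, incumbent, min_biomass)
        return(structure(list(added = incumbent,
                              achieved_biomass_flux = r$flux,
                              optimal = FALSE),
                         class = "gapfill_result"))
      }
      r <- gapfill_feasible(model, db, s, min_biomass)
      if (r$ok) {
        return(structure(list(added = s, achieved_biomass_flux = r$flux,
                              optimal = TRUE),
                         class = "gapfill_result"))
      }
    }
  }
  stop("unfillable gap")  # unreachable: the full set was feasible
}

#' @export
print.gapfill_result <- function(x, ...) {
  cat("<gapfill_result>", length(x$added), "reaction(s) added",
      if (x$optimal) "(minimal)" else "(incumbent)", "\n")
  if (length(x$added)) cat("  ", paste(x$added, collapse = ", "), "\n")
  invisible(x)
}

derive_compartment_id <- function(met_id, from, to) {
  if (grepl(paste0("_", from, "$"), met_id))
    sub(paste0("_", from, "$"), paste0("_", to), met_id)
  else paste0(met_id, "_", to)
}

#' Compare in vivo and in silico growth phenotypes
#'
#' Evaluates in silico growth on each substrate under one of three transport
#' assumptions:
#' * `transporter_required` - only transport reactions already in the model;
#' * `free_diffusion_periplasm` - additionally an uncatalysed reversible
#'   diffusion of the substrate across the outer membrane into the periplasm;
#' * `free_diffusion_cytoplasm` - additionally a reversible diffusion across
#'   the inner membrane into the cytoplasm.
#' Diffusion reactions are plain translocations: they never phosphorylate or
#' otherwise transform the substrate, so substrates whose catabolism starts
#' with a transporter-coupled phosphorylation still require that transporter.
#' Substrates absent from the model get transient extracellular metabolites
#' and exchange reactions for the test; nothing is added permanently.
#'
#' @param model a `metabolic_model`.
#' @param records data frame with columns `substrate` and `in_vivo`
#'   (logical).
#' @param mode one of the three transport assumptions.
#' @param substrate_mets named character mapping substrate name ->
#'   extracellular metabolite id; substrates without a mapping get a
#'   per-record error message, not a global failure.
#' @param medium_base optional exchange bounds defining the medium backbone.
#' @param uptake_cap substrate uptake bound (mmol/gCDW/h); the plate assay
#'   normalises carbon concentration, but FBA needs a rate.
#' @param min_biomass biomass flux defining in silico growth (1/h).
#' @return list with `records` (data frame: substrate, in_vivo, in_silico,
#'   error) and `summary` (counts: `both`, `neither`, `in_silico_only`,
#'   `in_vivo_only`).
#' @export
phenotype_compare <- function(model, records,
                              mode = c("transporter_required",
                                       "free_diffusion_periplasm",
                                       "free_diffusion_cytoplasm"),
                              substrate_mets, medium_base = NULL,
                              uptake_cap = 10, min_biomass = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(records),
            all(c("substrate", "in_vivo") %in% names(records)))
  if (!is.null(medium_base)) model <- set_medium(model, medium_base)
  out <- data.frame(substrate = records$substrate,
                    in_vivo = records$in_vivo,
                    in_silico = NA, error = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(records))) {
    sub_name <- records$substrate[i]
    if (!sub_name %in% names(substrate_mets)) {
      out$error[i] <- "no substrate-metabolite mapping"
      next
    }
    met_e <- substrate_mets[[sub_name]]
    m <- model
    if (!met_e %in% m$mets$id)
      m <- add_metabolite(m, metabolite(met_e, compartment = "extracellular"))
    ex_id <- {
      ex <- exchanges(m)
      hits <- ex[vapply(m$reactions[ex],
                        function(r) names(r$stoich) == met_e, TRUE)]
      if (length(hits)) hits[1] else NULL
    }
    if (is.null(ex_id)) {
      ex_id <- paste0("EX_", met_e, "_phen")
      m <- add_reaction(m, reaction(ex_id, stats::setNames(-1, met_e),
                                    lb = -uptake_cap, ub = 1000))
    } else {
      m <- set_medium(m, stats::setNames(list(c(-uptake_cap, 1000)), ex_id))
    }
    if (mode %in% c("free_diffusion_periplasm", "free_diffusion_cytoplasm")) {
      met_p <- derive_compartment_id(met_e, "e", "p")
      if (!met_p %in% m$mets$id)
        m <- add_metabolite(m, metabolite(met_p, compartment = "periplasm"))
      m <- add_reaction(m, reaction(paste0("DIFF_om_", met_e),
                                    stats::setNames(c(-1, 1), c(met_e, met_p)),
                                    lb = -1000, ub = 1000))
      if (mode == "free_diffusion_cytoplasm") {
        met_c <- derive_compartment_id(met_e, "e", "c")
        if (!met_c %in% m$mets$id)
          m <- add_metabolite(m, metabolite(met_c, compartment = "cytoplasm"))
        m <- add_reaction(m, reaction(paste0("DIFF_im_", met_e),
                                      stats::setNames(c(-1, 1),
                                                      c(met_p, met_c)),
                                      lb = -1000, ub = 1000))
      }
    }
    sol <- fba(m)
    out$in_silico[i] <- sol$status == "optimal" &&
      sol$objective_value >= min_biomass
  }
  ok <- !is.na(out$in_silico)
  summary <- c(both = sum(ok & out$in_vivo & out$in_silico),
               neither = sum(ok & !out$in_vivo & !out$in_silico),
               in_silico_only = sum(ok & !out$in_vivo & out$in_silico),
               in_vivo_only = sum(ok & out$in_vivo & !out$in_silico))
  list(records = out, summary = summary, mode = mode)
}
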