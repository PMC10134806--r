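#' Growth-rate-dependent FBA by fixed-point iteration
#'
#' Biomass composition varies with growth rate, but FBA needs a biomass
#' reaction to predict the growth rate. This routine iterates the coupling:
#' from a guessed growth rate it builds the composition-appropriate biomass
#' reaction, solves FBA, feeds the predicted growth rate back in, and repeats
#' until input and output growth rates agree to `tol`. Composition varies
#' slowly with growth rate, so plain fixed-point iteration is a mild
#' contraction; an optional damping factor is available should a model
#' oscillate.
#'
#' @param model a `metabolic_model`; its objective reaction is rebuilt each
#'   iteration with [build_biomass_reaction()].
#' @param fits a [growth_rate_fits()].
#' @param osmo an [osmolyte_spec()].
#' @param remainder a [reference_remainder()].
#' @param profiles,lumped_species,lumped_masses,gam_species,biomass_species
#'   passed to [build_biomass_reaction()].
#' @param gam growth-associated maintenance carried into each rebuilt biomass
#'   reaction (mmol ATP/gCDW); defaults to the current biomass reaction's
#'   recorded GAM.
#' @param medium optional exchange bounds applied once up front.
#' @param gr0 initial growth-rate guess (1/h), in `[0, gr_max]`.
#' @param tol convergence tolerance on the growth rate (1/h).
#' @param max_iter iteration cap.
#' @param damping in `[0, 1)`: next guess is
#'   `(1 - damping) * predicted + damping * previous`; 0 reproduces plain
#'   iteration.
#' @return a `grfba_result`: list with `fixed_point_gr`, `iterations`,
#'   `converged`, `trajectory` (growth rate per iteration, starting at
#'   `gr0`), and `solution` (the final `flux_solution`).
#' @export
gr_fba <- function(model, fits, osmo = osmolyte_spec(),
                   remainder = default_reference_remainder(),
                   profiles, lumped_species, lumped_masses = NULL,
                   gam_species = c(atp = "atp_c", h2o = "h2o_c",
                                   adp = "adp_c", pi = "pi_c"),
                   biomass_species = "biomass_c",
                   gam = NULL, medium = NULL,
                   gr0 = 0.1, tol = 1e-4, max_iter = 50L, damping = 0) {
  stopifnot(tol > 0, gr0 >= 0, gr0 <= fits$gr_max, damping >= 0, damping < 1)
  if (!is.null(medium)) model <- set_medium(model, medium)
  if (is.null(gam)) {
    gam <- attr(model$reactions[[model$objective_id]], "gam")
    if (is.null(gam)) stop("no GAM recorded on the biomass reaction; pass gam=")
  }
  bio_id <- model$objective_id
  rebuild <- function(gr) {
    comp <- composition_at(gr, fits, osmo, remainder, gam = gam)
    rxn <- build_biomass_reaction(comp, profiles, lumped_species,
                                  lumped_masses, gam_species,
                                  biomass_species, id = bio_id)
    m <- model
    m$reactions[[bio_id]] <- rxn
    m
  }
  traj <- gr0
  gr <- gr0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    sol <- fba(rebuild(gr))
    if (sol$status != "optimal")
      stop("FBA ", sol$status, " at iteration ", it, " (gr = ",
           signif(gr, 5), ")")
    gr_new <- min(max(sol$objective_value, 0), fits$gr_max)
    traj <- c(traj, gr_new)
    if (abs(gr_new - gr) < tol) {
      gr <- gr_new
      converged <- TRUE
      break
    }
    gr <- (1 - damping) * gr_new + damping * gr
  }
  structure(list(fixed_point_gr = gr, iterations = length(traj) - 1L,
                 converged = converged, trajectory = traj, solution = sol),
            class = "grfba_result")
}

#' @export
print.grfba_result <- function(x, ...) {
  cat("<grfba_result>",
      if (x$converged) "converged to" else "NOT converged; last",
      signif(x$fixed_point_gr, 5), "/h in", x$iterations, "iterations\n")
  invisible(x)
}

#' Compare two flux distributions
#'
#' Per-reaction percent difference `100 |v_a - v_b| / max(|v_a|, |v_b|)`,
#' defined as 0 when both magnitudes are below `zero_tol` (alternate optima
#' make individual fluxes non-unique; only summary statistics of this
#' comparison are stable).
#'
#' @param a,b `flux_solution`s over identical reaction sets.
#' @param threshold percent difference counted as "large" (default 20).
#' @param zero_tol magnitude below which a flux counts as zero.
#' @return a `flux_comparison`: list with `per_reaction` (named percent
#'   differences) and `fraction_over_threshold`.
#' @export
flux_compare <- function(a, b, threshold = 20, zero_tol = 1e-9) {
  stopifnot(inherits(a, "flux_solution"), inherits(b, "flux_solution"))
  if (a$status != "optimal" || b$status != "optimal")
    stop("both solutions must be optimal")
  if (!setequal(names(a$fluxes), names(b$fluxes)))
    stop("flux solutions cover different reaction sets")
  va <- a$fluxes
  vb <- b$fluxes[names(va)]
  denom <- pmax(abs(va), abs(vb))
  pd <- ifelse(denom < zero_tol, 0, 100 * abs(va - vb) / denom)
  structure(list(per_reaction = pd,
                 fraction_over_threshold = mean(pd >= threshold),
                 threshold = threshold),
            class = "flux_comparison")
}
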