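#!/usr/bin/env Rscript
# Growth-rate-dependent FBA. The biomass reaction is rebuilt from the
# composition fits at each iterate until the predicted growth rate equals the
# one the composition was built for. The fixed point is checked for
# independence of the initial guess, and the resulting flux distribution is
# compared against standard FBA with the fixed glucose-derived biomass
# reaction.

suppressMessages(library(gemcurate))
dir.create("results", showWarnings = FALSE)

spec <- toy_network_spec()
model <- tag_biomass_gam(read_sbml("results/toy_model.xml"), gam = spec$gam)
m_gal <- toy_medium(model, spec, "galactose")
fits <- default_growth_rate_fits()

runs <- lapply(c(0.01, 0.5, 1.0), function(g0)
  gr_fba(m_gal, fits, osmo = osmolyte_spec(),
         remainder = default_reference_remainder(),
         profiles = toy_profiles(), lumped_species = toy_lumped_species(),
         lumped_masses = toy_lumped_masses(), gr0 = g0, tol = 1e-4))

traj <- do.call(rbind, lapply(runs, function(r)
  data.frame(gr0 = r$trajectory[1], iteration = seq_along(r$trajectory) - 1,
             growth_rate = r$trajectory)))
write.csv(traj, "results/grfba_trajectories.csv", row.names = FALSE)

for (r in runs) {
  cat(sprintf("guess %.2f -> fixed point %.5f /h in %d iterations (converged: %s)\n",
              r$trajectory[1], r$fixed_point_gr, r$iterations, r$converged))
}
fps <- vapply(runs, `[[`, 0, "fixed_point_gr")
cat(sprintf("Spread across guesses: %.2e /h\n", max(fps) - min(fps)))

## flux comparison: growth-rate-appropriate vs glucose-derived biomass
ref <- fba(m_gal)
cmp <- flux_compare(ref, runs[[1]]$solution)
write.csv(data.frame(reaction = names(cmp$per_reaction),
                     percent_difference = cmp$per_reaction),
          "results/grfba_flux_comparison.csv", row.names = FALSE)
cat(sprintf("Growth rate: %.4f (GR-dependent) vs %.4f (glucose-derived biomass)\n",
            runs[[1]]$fixed_point_gr, ref$objective_value))
cat(sprintf("%.0f%% of fluxes differ by at least 20%% between the two solutions\n",
            100 * cmp$fraction_over_threshold))
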