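#!/usr/bin/env Rscript
# Build the toy metabolic network with known energetics (GAM 20 mmol/gCDW,
# NGAM 5 mmol/gCDW/h, respiration 3 ATP per carbon), write it to SBML, and
# tabulate its structure. Everything downstream re-reads this file.

suppressMessages(library(gemcurate))
dir.create("results", showWarnings = FALSE)

spec <- toy_network_spec()
model <- make_toy_model(spec)
write_sbml(model, "results/toy_model.xml")

st <- model_stats(model)
cat("Toy network written to results/toy_model.xml\n")
cat(sprintf("  %d reactions (%d internal / %d transport / %d exchange), %d metabolites\n",
            st$total_reactions, st$internal_reactions, st$transport_reactions,
            st$exchange_reactions, st$total_metabolites))

growth <- do.call(rbind, lapply(spec$substrates$name, function(su) {
  sol <- fba(toy_medium(model, spec, su))
  data.frame(substrate = su,
             uptake_cap = spec$substrates$uptake_cap[spec$substrates$name == su],
             overflow_fraction = spec$overflow[[su]],
             growth_rate = sol$objective_value)
}))
write.csv(growth, "results/toy_growth_rates.csv", row.names = FALSE)
cat("Predicted growth rates (1/h):\n")
print(growth, row.names = FALSE)

# round-trip sanity: the SBML file reproduces the same optimum
back <- read_sbml("results/toy_model.xml")
stopifnot(abs(fba(toy_medium(back, spec, "glucose"))$objective_value -
                growth$growth_rate[1]) < 1e-9)
cat("SBML round trip preserves the FBA optimum.\n")
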