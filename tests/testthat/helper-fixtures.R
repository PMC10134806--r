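# Shared fixtures, built once per test session.

reaction_ids_for_test <- function(m) vapply(m$reactions, `[[`, "", "id")

# A linear pathway LP fixture: uptake of S (capped), R1: S -> P + 2 E,
# biomass drain BIO: P + E ->, plus free drains for excess P and E. The
# E-drain's lower bound models an ATP-hydrolysis (maintenance) demand.
fixture_chain_model <- function(uptake_cap = 5, e_drain_lb = 0) {
  mets <- rbind(
    metabolite("S", "substrate", "extracellular"),
    metabolite("P", "precursor", "cytoplasm"),
    metabolite("E", "energy", "cytoplasm"))
  rxns <- list(
    reaction("EX_S", c(S = -1), -uptake_cap, 0),
    reaction("R1", c(S = -1, P = 1, E = 2), 0, 1000),
    reaction("BIO", c(P = -1, E = -1), 0, 1000),
    reaction("DR_P", c(P = -1), 0, 1000),
    reaction("DR_E", c(E = -1), e_drain_lb, 1000))
  new_model(mets, rxns, objective_id = "BIO", id = "chain")
}

the_toy_spec <- toy_network_spec()
the_toy_model <- make_toy_model(the_toy_spec)

toy_glc <- function() toy_medium(the_toy_model, the_toy_spec, "glucose")
toy_gal <- function() toy_medium(the_toy_model, the_toy_spec, "galactose")

# closed-form growth rate of the toy network:
# mu = (uptake * carbons * (1 - overflow) - ngam/a) / (c_b + gam/a)
toy_mu_closed_form <- function(spec, substrate, uptake = NULL) {
  i <- which(spec$substrates$name == substrate)
  if (is.null(uptake)) uptake <- spec$substrates$uptake_cap[i]
  a <- spec$atp_per_c1
  q <- uptake * spec$substrates$carbons[i] * (1 - spec$overflow[[substrate]])
  cb <- toy_biomass_carbon(spec)
  (q - spec$ngam / a) / (cb + spec$gam / a)
}

# decoy candidates for gap-fill fixtures: an isolated two-metabolite cycle
# that can never feed biomass
make_decoys <- function(n, offset = 0) {
  lapply(seq_len(n), function(i) {
    reaction(sprintf("DECOY_%02d", i + offset),
             stats::setNames(c(-1, 1), c("dummy1_c", "dummy2_c")), 0, 1000)
  })
}

with_decoy_mets <- function(model) {
  model <- add_metabolite(model, metabolite("dummy1_c", compartment = "cytoplasm"))
  model <- add_metabolite(model, metabolite("dummy2_c", compartment = "cytoplasm"))
  add_reaction(model, reaction("DM_dummy", c(dummy2_c = -1, dummy1_c = 1),
                               0, 0))
}

# carbon consumed by the biomass reaction per gCDW (mmol C), from the
# composition and the toy monomer bookkeeping -- independent of the model
toy_biomass_carbon <- function(spec) {
  fr <- spec$composition$fractions
  mono <- list(protein = c(100, 2), rna = c(320, 4), dna = c(310, 3),
               glutamate = c(147.13, 5), glutamine = c(146.15, 5),
               lps = c(80, 2), lipid = c(80, 2), murein = c(80, 2),
               inorganic_ions = c(80, 2), soluble_pool = c(80, 2))
  sum(vapply(names(fr), function(k)
    1000 * fr[[k]] / mono[[k]][1] * mono[[k]][2], 0))
}
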