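#' Specification of the toy metabolic network
#'
#' A small, fully determined metabolic network with known energetics, used as
#' the shared fixture across the whole pipeline. Each substrate is taken up,
#' catabolised into single-carbon units (a fixed fraction of its carbon
#' rerouted to acetate overflow, hard-wired in the catabolic stoichiometry),
#' and the carbon units are either respired for ATP or assembled into biomass
#' monomers. Monomer synthesis is ATP-neutral, so the network's entire energy
#' demand is the explicit GAM and NGAM — which makes growth, yields and
#' maintenance all available in closed form for testing.
#'
#' @param substrates data frame with columns `name`, `carbons`, `atp_yield`
#'   (ATP per substrate molecule when fully respired), `uptake_cap`
#'   (mmol/gCDW/h). All substrates must share one per-carbon ATP yield
#'   (`atp_yield / carbons`), since respiration is a single lumped reaction.
#' @param overflow named numeric: fraction of each substrate's carbon
#'   excreted as acetate, in `[0, 1)`.
#' @param composition a [composition_at()] result for the biomass reaction
#'   (defaults to the reference fits evaluated at 0.79/h).
#' @param gam growth-associated maintenance (mmol ATP/gCDW).
#' @param ngam non-growth-associated maintenance (mmol ATP/gCDW/h).
#' @return a `toy_network_spec`.
#' @export
toy_network_spec <- function(substrates = data.frame(
                               name = c("glucose", "galactose"),
                               carbons = c(6L, 6L),
                               atp_yield = c(18, 18),
                               uptake_cap = c(5.6, 0.6)),
                             overflow = c(glucose = 0.3, galactose = 0),
                             composition = NULL,
                             gam = 20, ngam = 5) {
  stopifnot(all(c("name", "carbons", "atp_yield", "uptake_cap") %in%
                  names(substrates)))
  if (any(substrates$atp_yield <= 0)) stop("atp_yield must be positive")
  if (!all(substrates$name %in% names(overflow)))
    stop("overflow fraction missing for some substrate")
  if (any(overflow < 0 | overflow >= 1)) stop("overflow fractions in [0,1)")
  per_c <- substrates$atp_yield / substrates$carbons
  if (max(per_c) - min(per_c) > 1e-12)
    stop("all substrates must share one per-carbon ATP yield")
  if (gam < 0 || ngam < 0) stop("gam and ngam must be nonnegative")
  if (is.null(composition))
    composition <- composition_at(0.79, default_growth_rate_fits(), gam = gam)
  composition$gam <- gam
  structure(list(substrates = substrates, overflow = overflow,
                 composition = composition, gam = gam, ngam = ngam,
                 atp_per_c1 = per_c[1]),
            class = "toy_network_spec")
}

# monomer bookkeeping for the toy network: metabolite, residue/free mass,
# carbons per monomer
TOY_MONOMERS <- list(
  aa = list(met = "aa_c", mass = 100, carbons = 2),
  nt = list(met = "nt_c", mass = 320, carbons = 4),
  dnt = list(met = "dnt_c", mass = 310, carbons = 3),
  glu = list(met = "glu_c", mass = 147.13, carbons = 5),
  gln = list(met = "gln_c", mass = 146.15, carbons = 5),
  rem = list(met = "rem_c", mass = 80, carbons = 2))

#' Monomer profiles of the toy network
#'
#' Degenerate single-monomer profiles (one generic amino acid, one RNA and
#' one DNA nucleotide) matching the toy network's metabolites.
#' @return named list of [monomer_profile()]s (`protein`, `rna`, `dna`).
#' @export
toy_profiles <- function() {
  list(protein = monomer_profile("amino_acid", c(aa_c = 1),
                                 c(aa_c = TOY_MONOMERS$aa$mass)),
       rna = monomer_profile("rna_nucleotide", c(nt_c = 1),
                             c(nt_c = TOY_MONOMERS$nt$mass)),
       dna = monomer_profile("dna_nucleotide", c(dnt_c = 1),
                             c(dnt_c = TOY_MONOMERS$dnt$mass)))
}

#' @rdname toy_profiles
#' @export
toy_lumped_species <- function() {
  c(glutamate = "glu_c", glutamine = "gln_c", lps = "rem_c", lipid = "rem_c",
    murein = "rem_c", inorganic_ions = "rem_c", soluble_pool = "rem_c")
}

#' @rdname toy_profiles
#' @export
toy_lumped_masses <- function() {
  c(glutamate = TOY_MONOMERS$glu$mass, glutamine = TOY_MONOMERS$gln$mass,
    lps = TOY_MONOMERS$rem$mass, lipid = TOY_MONOMERS$rem$mass,
    murein = TOY_MONOMERS$rem$mass, inorganic_ions = TOY_MONOMERS$rem$mass,
    soluble_pool = TOY_MONOMERS$rem$mass)
}

#' Build the toy metabolic model
#'
#' Assembles the ~25-reaction network of [toy_network_spec()]: per-substrate
#' exchange, outer-membrane diffusion and inner-membrane transport;
#' catabolism to single-carbon units with the stoichiometric acetate
#' overflow; lumped respiration (fixed ATP per carbon unit); ATP-neutral
#' monomer syntheses; an ATP-hydrolysis maintenance reaction with lower bound
#' NGAM; and a biomass reaction from [build_biomass_reaction()] carrying the
#' GAM. Metabolite formulas carry carbon counts so carbon balances can be
#' audited.
#'
#' @param spec a [toy_network_spec()].
#' @return a `metabolic_model`, FBA-feasible on each substrate alone.
#' @export
make_toy_model <- function(spec = toy_network_spec()) {
  stopifnot(inherits(spec, "toy_network_spec"))
  a <- spec$atp_per_c1
  mets <- do.call(rbind, c(list(
    metabolite("ac_c", "acetate", "cytoplasm", "C2H4O2"),
    metabolite("ac_p", "acetate", "periplasm", "C2H4O2"),
    metabolite("ac_e", "acetate", "extracellular", "C2H4O2"),
    metabolite("co2_c", "CO2", "cytoplasm", "CO2"),
    metabolite("co2_e", "CO2", "extracellular", "CO2"),
    metabolite("c1_c", "carbon unit", "cytoplasm", "CH2O"),
    metabolite("atp_c", "ATP", "cytoplasm"),
    metabolite("adp_c", "ADP", "cytoplasm"),
    metabolite("pi_c", "phosphate", "cytoplasm"),
    metabolite("h2o_c", "water", "cytoplasm"),
    metabolite("h2o_e", "water", "extracellular"),
    metabolite("biomass_c", "biomass", "cytoplasm"),
    metabolite("aa_c", "generic amino acid", "cytoplasm", "C2"),
    metabolite("nt_c", "generic RNA nucleotide", "cytoplasm", "C4"),
    metabolite("dnt_c", "generic DNA nucleotide", "cytoplasm", "C3"),
    metabolite("glu_c", "glutamate", "cytoplasm", "C5"),
    metabolite("gln_c", "glutamine", "cytoplasm", "C5"),
    metabolite("rem_c", "lumped remainder", "cytoplasm", "C2")),
    unlist(lapply(seq_len(nrow(spec$substrates)), function(i) {
      nm <- spec$substrates$name[i]
      fml <- paste0("C", spec$substrates$carbons[i])
      list(metabolite(paste0(nm, "_e"), nm, "extracellular", fml),
           metabolite(paste0(nm, "_p"), nm, "periplasm", fml),
           metabolite(paste0(nm, "_c"), nm, "cytoplasm", fml))
    }), recursive = FALSE)))

  rxns <- list(
    reaction("EX_ac", c(ac_e = -1), 0, 1000, "acetate exchange"),
    reaction("EX_co2", c(co2_e = -1), 0, 1000, "CO2 exchange"),
    reaction("EX_h2o", c(h2o_e = -1), -1000, 1000, "water exchange"),
    reaction("EX_biomass", c(biomass_c = -1), 0, 1000, "biomass drain"),
    reaction("ACt_cp", c(ac_c = -1, ac_p = 1), 0, 1000),
    reaction("ACt_pe", c(ac_p = -1, ac_e = 1), 0, 1000),
    reaction("CO2t", c(co2_c = -1, co2_e = 1), 0, 1000),
    reaction("H2Ot", c(h2o_e = -1, h2o_c = 1), -1000, 1000),
    reaction("RESP", c(c1_c = -1, adp_c = -a, pi_c = -a,
                       co2_c = 1, atp_c = a, h2o_c = a), 0, 1000,
             "lumped respiration"),
    reaction("ATPM", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1),
             spec$ngam, 1000, "ATP hydrolysis (maintenance)"),
    reaction("AASYN", c(c1_c = -TOY_MONOMERS$aa$carbons, aa_c = 1), 0, 1000),
    reaction("NTSYN", c(c1_c = -TOY_MONOMERS$nt$carbons, nt_c = 1), 0, 1000),
    reaction("DNTSYN", c(c1_c = -TOY_MONOMERS$dnt$carbons, dnt_c = 1),
             0, 1000),
    reaction("GLUSYN", c(c1_c = -TOY_MONOMERS$glu$carbons, glu_c = 1),
             0, 1000),
    reaction("GLNSYN", c(c1_c = -TOY_MONOMERS$gln$carbons, gln_c = 1),
             0, 1000),
    reaction("REMSYN", c(c1_c = -TOY_MONOMERS$rem$carbons, rem_c = 1),
             0, 1000))
  for (i in seq_len(nrow(spec$substrates))) {
    nm <- spec$substrates$name[i]
    nC <- spec$substrates$carbons[i]
    f <- spec$overflow[[nm]]
    e <- paste0(nm, "_e"); p <- paste0(nm, "_p"); cc <- paste0(nm, "_c")
    cat_sto <- stats::setNames(c(-1, nC * (1 - f)), c(cc, "c1_c"))
    if (f > 0) cat_sto <- c(cat_sto, c(ac_c = nC * f / 2))
    rxns <- c(rxns, list(
      reaction(paste0("EX_", nm), stats::setNames(-1, e),
               -spec$substrates$uptake_cap[i], 0,
               paste(nm, "exchange")),
      reaction(paste0(toupper(substr(nm, 1, 3)), "t_ep"),
               stats::setNames(c(-1, 1), c(e, p)), -1000, 1000),
      reaction(paste0(toupper(substr(nm, 1, 3)), "t_pc"),
               stats::setNames(c(-1, 1), c(p, cc)), 0, 1000),
      reaction(paste0("CAT_", nm), cat_sto, 0, 1000)))
  }
  bio <- build_biomass_reaction(spec$composition, toy_profiles(),
                                toy_lumped_species(), toy_lumped_masses())
  rxns <- c(rxns, list(bio))
  model <- new_model(mets, rxns, objective_id = "BIOMASS", id = "toy")
  # sanity: every substrate alone must support nonzero flux balance
  for (nm in spec$substrates$name) {
    m <- toy_medium(model, spec, nm)
    sol <- fba(m)
    if (sol$status != "optimal")
      stop("inconsistent spec: FBA ", sol$status, " on ", nm)
  }
  model
}

#' Medium with a single toy substrate open
#'
#' @param model the toy model.
#' @param spec its [toy_network_spec()].
#' @param substrate substrate name to open at its uptake cap; all other
#'   substrates closed.
#' @return the model with bounds set.
#' @export
toy_medium <- function(model, spec, substrate) {
  stopifnot(substrate %in% spec$substrates$name)
  bounds <- lapply(spec$substrates$name, function(nm) {
    if (nm == substrate)
      c(-spec$substrates$uptake_cap[spec$substrates$name == nm], 0)
    else c(0, 0)
  })
  set_medium(model, stats::setNames(bounds, paste0("EX_", spec$substrates$name)))
}

#' Simulation configuration
#'
#' @param seed RNG seed (must be set explicitly; generators are
#'   bit-reproducible given seed and configuration).
#' @param od0 inoculation OD600.
#' @param sample_times sampling times (h) for batch simulations; `NULL` picks
#'   40 points spanning growth to 250x the inoculum on the given substrate
#'   (dense sampling across the whole exponential phase keeps the yield
#'   regressions precise).
#' @param s0 initial substrate concentration (mM); `NULL` doses the culture
#'   so ~70% of the substrate is consumed by the last sample.
#' @param noise named list of noise levels: `od` (multiplicative sd),
#'   `conc_rel` (relative sd on substrate/acetate concentrations, as for an
#'   HPLC assay), `conc_floor` (absolute sd floor, mM), `composition`
#'   (additive sd, mg/(OD600*mL)), `plate` (multiplicative sd).
#' @param cdw_conv mg CDW/(OD600*mL) used to translate fluxes into
#'   concentration changes.
#' @return a `sim_config`.
#' @export
sim_config <- function(seed, od0 = 0.02, sample_times = NULL, s0 = NULL,
                       noise = list(od = 0.01, conc_rel = 0.01,
                                    conc_floor = 0.02, composition = 0.01,
                                    plate = 0.02),
                       cdw_conv = 0.55) {
  if (missing(seed)) stop("sim_config: seed must be set explicitly")
  defaults <- list(od = 0.01, conc_rel = 0.01, conc_floor = 0.02,
                   composition = 0.01, plate = 0.02)
  noise <- utils::modifyList(defaults, as.list(noise))
  if (any(unlist(noise) < 0)) stop("noise sds must be nonnegative")
  structure(list(seed = as.integer(seed), od0 = od0,
                 sample_times = sample_times, s0 = s0, noise = noise,
                 cdw_conv = cdw_conv),
            class = "sim_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Simulate an exponential batch culture on the toy network
#'
#' Solves FBA on the toy model with the chosen substrate open; the optimal
#' growth rate and exchange fluxes define exponential OD growth and linear
#' substrate-depletion/acetate-accumulation yields per OD. Gaussian noise is
#' multiplicative on OD and additive on concentrations; the substrate
#' exhausting before the last sample truncates the series with a warning.
#'
#' @param spec a [toy_network_spec()].
#' @param substrate substrate name.
#' @param cfg a [sim_config()].
#' @return a [batch_series()]; attribute `"truth"` records the noiseless
#'   generating quantities (growth rate, fluxes, yields).
#' @export
simulate_batch <- function(spec, substrate, cfg) {
  stopifnot(inherits(spec, "toy_network_spec"), inherits(cfg, "sim_config"))
  model <- make_toy_model(spec)
  m <- toy_medium(model, spec, substrate)
  sol <- fba(m)
  if (sol$status != "optimal") stop("toy model infeasible on ", substrate)
  mu <- sol$objective_value
  if (mu <= 0) stop("toy model does not grow on ", substrate)
  upt <- -sol$fluxes[[paste0("EX_", substrate)]]
  ace <- sol$fluxes[["EX_ac"]]
  co2 <- sol$fluxes[["EX_co2"]]
  kap <- cfg$cdw_conv
  y_s <- upt * kap / mu          # mM substrate per OD600
  y_a <- ace * kap / mu
  times <- cfg$sample_times
  if (is.null(times)) times <- seq(0, log(250) / mu, length.out = 40)
  od_true <- cfg$od0 * exp(mu * times)
  s0 <- cfg$s0
  if (is.null(s0)) s0 <- y_s * (max(od_true) - cfg$od0) / 0.7
  s_true <- s0 - y_s * (od_true - cfg$od0)
  a_true <- y_a * (od_true - cfg$od0)
  if (any(s_true < 0)) {
    warning("substrate exhausted before the last sample; series truncated")
    keep <- s_true >= 0
    times <- times[keep]; od_true <- od_true[keep]
    s_true <- s_true[keep]; a_true <- a_true[keep]
  }
  sd_conc <- function(v) pmax(cfg$noise$conc_rel * abs(v), cfg$noise$conc_floor)
  out <- with_seed(cfg$seed, {
    od <- od_true * (1 + stats::rnorm(length(times), 0, cfg$noise$od))
    s_obs <- s_true + stats::rnorm(length(times)) * sd_conc(s_true)
    a_obs <- a_true + stats::rnorm(length(times)) * sd_conc(a_true)
    list(od = od, s = pmax(s_obs, 0), a = if (ace > 0) pmax(a_obs, 0)
                                          else rep(0, length(times)))
  })
  nC <- spec$substrates$carbons[spec$substrates$name == substrate]
  max_sd <- max(sd_conc(s_true))
  series <- batch_series(times, out$od, out$s, out$a, nC,
                         medium_label = substrate,
                         noise_tol = max(0.05, 8 * max_sd /
                                           max(diff(range(out$s)), 1e-9)))
  attr(series, "truth") <- list(growth_rate = mu, uptake = upt,
                                acetate_flux = ace, co2_flux = co2,
                                yield_substrate = y_s, yield_acetate = y_a,
                                fluxes = sol$fluxes)
  series
}

#' Simulate growth-rate-resolved composition measurements
#'
#' Draws RNA/protein/CDW content per OD600*mL at each growth rate from the
#' linear fits plus Gaussian noise (resampling the rare negative draw).
#'
#' @param fits a [growth_rate_fits()].
#' @param gr_values growth rates to sample at (within the fit range).
#' @param replicates replicates per growth rate.
#' @param cfg a [sim_config()]; `noise$composition` is the additive sd.
#' @return data frame with columns `growth_rate`, `replicate`, `rna`,
#'   `protein`, `cdw` (mg/(OD600*mL)).
#' @export
simulate_composition <- function(fits, gr_values, replicates, cfg) {
  stopifnot(inherits(fits, "growth_rate_fits"), inherits(cfg, "sim_config"))
  if (any(gr_values < 0 | gr_values > fits$gr_max))
    stop("growth rates outside the fit range")
  sd <- cfg$noise$composition
  draw <- function(mean_val) {
    for (i in 1:100) {
      v <- mean_val + stats::rnorm(1, 0, sd)
      if (v > 0) return(v)
    }
    stop("could not draw a positive measurement (noise sd too large?)")
  }
  with_seed(cfg$seed, {
    rows <- expand.grid(replicate = seq_len(replicates),
                        growth_rate = gr_values)[, 2:1]
    rows$rna <- vapply(rows$growth_rate,
                       function(g) draw(eval_fit(fits$rna, g)), 0)
    rows$protein <- vapply(rows$growth_rate,
                           function(g) draw(eval_fit(fits$protein, g)), 0)
    rows$cdw <- vapply(rows$growth_rate,
                       function(g) draw(eval_fit(fits$cdw, g)), 0)
    rows[, c("growth_rate", "replicate", "rna", "protein", "cdw")]
  })
}

#' Forward-generate an add-back pellet series
#'
#' Applies the pellet mass balance exactly (no noise): dry weight
#' `x = alpha w + rho z` and wet weight `y = x + beta alpha w + z` for each
#' added-back extracellular water weight `z`.
#'
#' @param alpha true CDW per OD600*mL (mg/(OD600*mL)).
#' @param beta cellular water per CDW (mg/mg).
#' @param rho wash-solution salinity (mg NaCl per mg water).
#' @param w harvested amount per aliquot (OD600*mL).
#' @param z_values added-back extracellular water weights (mg).
#' @return an [addback_series()].
#' @export
simulate_pellets <- function(alpha, beta, rho, w, z_values) {
  stopifnot(alpha > 0, beta >= 0, rho >= 0, rho < 1, w > 0,
            all(z_values >= 0), rho * beta < 1)
  x <- alpha * w + rho * z_values
  y <- x + beta * alpha * w + z_values
  addback_series(x, y, w, beta)
}

#' Simulate plate-reader phenotyping curves
#'
#' Growers follow a logistic curve crossing the growth-call threshold well
#' before 20 h; non-growers stay below 0.3 OD throughout. Multiplicative
#' Gaussian noise per reading.
#'
#' @param truth named logical: substrate -> grows.
#' @param cfg a [sim_config()]; `noise$plate` is the multiplicative sd.
#' @param times reading times (h), spanning 10 days by default.
#' @param replicates curves per substrate.
#' @return list of [plate_curve()]s.
#' @export
simulate_plate <- function(truth, cfg, times = seq(0, 240, by = 6),
                           replicates = 1L) {
  stopifnot(length(truth) >= 1, !is.null(names(truth)))
  with_seed(cfg$seed, {
    curves <- list()
    for (nm in names(truth)) {
      for (rep_i in seq_len(replicates)) {
        if (truth[[nm]]) {
          K <- 1.5; od0 <- 0.05; r <- 0.6
          od <- K / (1 + ((K - od0) / od0) * exp(-r * times))
        } else {
          od <- 0.05 + 0.1 * (1 - exp(-times / 100))
        }
        od <- od * (1 + stats::rnorm(length(times), 0, cfg$noise$plate))
        curves[[length(curves) + 1L]] <-
          plate_curve(nm, times, pmax(od, 0), rep_i)
      }
    }
    curves
  })
}

#' Carbon atoms per metabolite from its formula
#'
#' Parses `C<n>` out of formula strings (e.g. `"C6H12O6"` -> 6, `"CO2"` ->
#' 1); metabolites without a formula count as carbon-free.
#'
#' @param model a `metabolic_model`.
#' @return named numeric vector over metabolite ids.
#' @export
metabolite_carbons <- function(model) {
  f <- model$mets$formula
  n <- vapply(f, function(s) {
    if (is.na(s)) return(0)
    m <- regmatches(s, regexpr("C(?![a-z])[0-9]*", s, perl = TRUE))
    if (length(m) == 0) return(0)
    d <- sub("^C", "", m)
    if (d == "") 1 else as.numeric(d)
  }, 0, USE.NAMES = FALSE)
  stats::setNames(n, model$mets$id)
}
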