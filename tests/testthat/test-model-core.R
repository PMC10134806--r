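test_that("model constructors enforce invariants", {
  expect_error(reaction("r", numeric(0), 0, 1), "nonempty")
  expect_error(reaction("r", c(a = Inf), 0, 1), "finite")
  expect_error(reaction("r", c(a = -1), 2, 1), "lower bound exceeds")
  mets <- rbind(metabolite("a", compartment = "cytoplasm"),
                metabolite("b", compartment = "cytoplasm"))
  expect_error(new_model(mets, list(reaction("r1", c(zz = -1), 0, 1)),
                         objective_id = "r1"), "unknown metabolites")
  expect_error(new_model(mets, list(reaction("r1", c(a = -1), 0, 1)),
                         objective_id = "nope"), "objective")
  expect_error(new_model(rbind(mets, metabolite("a", compartment = "periplasm")),
                         list(reaction("r1", c(a = -1), 0, 1)),
                         objective_id = "r1"), "duplicate")
})

test_that("FBA solves the bottleneck chain and maintenance-drain variants", {
  # single bottleneck: uptake cap is the only constraint
  m <- fixture_chain_model(uptake_cap = 10)
  sol <- fba(m)
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
  expect_mass_balanced(m, sol)

  # precursor-limited: uptake 5, biomass 5, excess energy drained
  m5 <- fixture_chain_model(uptake_cap = 5)
  sol5 <- fba(m5)
  expect_equal(sol5$objective_value, 5, tolerance = 1e-9)
  expect_equal(oracle_fba(m5)$objective, 5, tolerance = 1e-9)

  # energy budget 2*uptake minus a forced drain of 7 leaves biomass 3
  m7 <- fixture_chain_model(uptake_cap = 5, e_drain_lb = 7)
  sol7 <- fba(m7)
  expect_equal(sol7$objective_value, 3, tolerance = 1e-9)
  expect_equal(oracle_fba(m7)$objective, 3, tolerance = 1e-9)
  expect_mass_balanced(m7, sol7)
})

test_that("FBA reports infeasible and unbounded as statuses", {
  # forced drain beyond what pinned uptake can supply
  m <- fixture_chain_model(uptake_cap = 2, e_drain_lb = 7)
  m$reactions[["BIO"]]$lb <- 1
  expect_equal(fba(m)$status, "infeasible")

  # a reversible pair with infinite bounds and reward for cycling
  mets <- rbind(metabolite("a", compartment = "cytoplasm"),
                metabolite("b", compartment = "cytoplasm"))
  m2 <- new_model(mets, list(reaction("f", c(a = -1, b = 1), -Inf, Inf),
                             reaction("g", c(b = -1, a = 1), -Inf, Inf)),
                  objective_id = "f")
  expect_equal(fba(m2)$status, "unbounded")
})

test_that("FBA optimum matches vertex enumeration on random small networks", {
  set.seed(101)
  n_checked <- 0
  for (trial in 1:40) {
    nmet <- sample(2:4, 1)
    nrx <- sample(3:6, 1)
    mets <- do.call(rbind, lapply(seq_len(nmet), function(i)
      metabolite(paste0("m", i), compartment = "cytoplasm")))
    rxns <- lapply(seq_len(nrx), function(j) {
      k <- sample(seq_len(nmet), sample(1:min(3, nmet), 1))
      sto <- stats::setNames(sample(c(-2, -1, 1, 2), length(k), TRUE),
                             paste0("m", k))
      lb <- sample(c(-10, -5, 0), 1)
      reaction(paste0("r", j), sto, lb, sample(c(0, 5, 10), 1) + 10)
    })
    m <- new_model(mets, rxns, objective_id = "r1")
    sol <- fba(m)
    orc <- oracle_fba(m)
    expect_equal(sol$status, orc$status, info = paste("trial", trial))
    if (sol$status == "optimal") {
      expect_equal(sol$objective_value, orc$objective, tolerance = 1e-6,
                   info = paste("trial", trial))
      expect_mass_balanced(m, sol)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 10)
})

test_that("optimal biomass scales linearly with the sole uptake bound", {
  spec <- toy_network_spec(gam = 0, ngam = 0)
  model <- make_toy_model(spec)
  base <- fba(toy_medium(model, spec, "glucose"))$objective_value
  for (k in c(0.5, 1, 2)) {
    m <- set_medium(model, list(
      EX_glucose = c(-k * spec$substrates$uptake_cap[1], 0),
      EX_galactose = c(0, 0)))
    expect_equal(fba(m)$objective_value, k * base, tolerance = 1e-9)
  }
})

test_that("set_medium validates, pins, and leaves the input model untouched", {
  m <- toy_glc()
  expect_error(set_medium(m, list(RESP = c(-1, 1))), "not an exchange")
  expect_error(set_medium(m, list(EX_glucose = c(1, -1))), "lb > ub")

  # starvation: all carbon exchanges closed but NGAM demanded -> infeasible
  starved <- set_medium(the_toy_model, list(EX_glucose = c(0, 0),
                                            EX_galactose = c(0, 0)))
  expect_equal(fba(starved)$status, "infeasible")
  # without the NGAM demand, zero growth is a feasible optimum
  spec0 <- toy_network_spec(ngam = 0)
  starved0 <- set_medium(make_toy_model(spec0),
                         list(EX_glucose = c(0, 0), EX_galactose = c(0, 0)))
  sol0 <- fba(starved0)
  expect_equal(sol0$status, "optimal")
  expect_equal(sol0$objective_value, 0, tolerance = 1e-9)

  # reopening the substrate restores growth
  regrow <- set_medium(starved, list(EX_glucose = c(-10, 0)))
  expect_gt(fba(regrow)$objective_value, 0)
  # original untouched
  expect_equal(starved$reactions$EX_glucose$lb, 0)

  # equality-pinned uptake is carried exactly into the solution
  pinned <- set_medium(the_toy_model, list(EX_glucose = c(-5, -5),
                                           EX_galactose = c(0, 0)))
  sol <- fba(pinned)
  expect_equal(unname(sol$fluxes["EX_glucose"]), -5, tolerance = 1e-8)
})

test_that("model_stats classifies reactions and counts compartments", {
  mets <- rbind(
    metabolite("glc_e", compartment = "extracellular"),
    metabolite("ac_e", compartment = "extracellular"),
    metabolite("glc_p", compartment = "periplasm"),
    metabolite("glc_c", compartment = "cytoplasm"),
    metabolite("p_c", compartment = "cytoplasm"),
    metabolite("e_c", compartment = "cytoplasm"))
  rxns <- list(
    reaction("EX_glc", c(glc_e = -1), -5, 0),
    reaction("EX_ac", c(ac_e = -1), 0, 1000),
    reaction("T1", c(glc_e = -1, glc_p = 1), 0, 1000),
    reaction("I1", c(glc_c = -1, p_c = 1, e_c = 2), 0, 1000),
    reaction("I2", c(p_c = -1, e_c = -1), 0, 1000),
    reaction("I3", c(e_c = -2, p_c = 1), 0, 1000))
  m <- new_model(mets, rxns, objective_id = "I2")
  st <- model_stats(m)
  expect_equal(st$exchange_reactions, 2)
  expect_equal(st$transport_reactions, 1)
  expect_equal(st$internal_reactions, 3)
  expect_equal(st$total_reactions,
               st$internal_reactions + st$transport_reactions +
                 st$exchange_reactions)
  expect_equal(st$intracellular, 3)
  expect_equal(st$periplasmic, 1)
  expect_equal(st$extracellular, 2)
  expect_equal(st$total_metabolites,
               st$intracellular + st$periplasmic + st$extracellular)
})

test_that("SBML round trip preserves model content bit for bit", {
  m <- fixture_small_model()
  f1 <- withr::local_tempfile(fileext = ".xml")
  f2 <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f1)
  back <- read_sbml(f1)
  expect_equal(length(back$reactions), length(m$reactions))
  expect_equal(stoichiometric_matrix(back)[rownames(stoichiometric_matrix(m)),
                                           colnames(stoichiometric_matrix(m))],
               stoichiometric_matrix(m))
  expect_equal(vapply(back$reactions, `[[`, 0, "lb"),
               vapply(m$reactions, `[[`, 0, "lb"))
  expect_equal(vapply(back$reactions, `[[`, 0, "ub"),
               vapply(m$reactions, `[[`, 0, "ub"))
  expect_equal(back$objective_id, m$objective_id)
  expect_equal(back$objective_sense, m$objective_sense)
  # second write is byte-identical
  write_sbml(back, f2)
  expect_identical(readLines(f1), readLines(f2))

  # reversible bounds (lb < 0 < ub) survive exactly
  expect_equal(back$reactions$T_s$lb, -1000)
  expect_equal(back$reactions$T_s$ub, 1000)
  # formulas and charges survive
  expect_equal(back$mets$formula[back$mets$id == "s_e"], "C6H12O6")
  expect_equal(back$mets$charge[back$mets$id == "e_c"], -1L)
})

test_that("SBML round trip preserves the full toy network and its FBA optimum", {
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(toy_glc(), f)
  back <- read_sbml(f)
  expect_equal(sort(reaction_ids_for_test(back)),
               sort(reaction_ids_for_test(toy_glc())))
  expect_equal(fba(back)$objective_value,
               fba(toy_glc())$objective_value, tolerance = 1e-9)
})

test_that("SBML writer and reader reject invalid input", {
  # refuse unvalidatable model
  m <- fixture_small_model()
  m$reactions <- list()
  expect_error(write_sbml(m, tempfile()), "objective")

  f <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model></badly", f)
  expect_error(read_sbml(f), "parse failure")
  expect_error(read_sbml(tempfile("nonexistent")), "no such file")

  # missing fbc bounds are an error, not a default
  write_sbml(fixture_small_model(), f)
  txt <- readLines(f)
  txt <- sub(' fbc:lowerFluxBound="bnd_R1_lb"', "", txt)
  f3 <- withr::local_tempfile(fileext = ".xml")
  writeLines(txt, f3)
  expect_error(read_sbml(f3), "missing fbc flux bounds")

  # missing objective is an error
  txt2 <- readLines(f)
  drop <- grep("bjective", txt2)
  f4 <- withr::local_tempfile(fileext = ".xml")
  writeLines(txt2[-drop], f4)
  expect_error(read_sbml(f4), "no fbc objective")
})
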