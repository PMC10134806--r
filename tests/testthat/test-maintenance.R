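noiseless_cfg <- function(seed = 1) {
  sim_config(seed, noise = list(od = 0, conc_rel = 0, conc_floor = 0,
                                composition = 0, plate = 0))
}

test_that("growth_rate recovers exponential slopes", {
  t5 <- seq(0, 4, by = 1)
  s <- batch_series(t5, 0.01 * exp(0.5 * t5), rep(10, 5) - 0.001 * t5,
                    rep(0, 5), 6)
  expect_equal(growth_rate(s), 0.5, tolerance = 1e-12)

  # constant OD: zero growth
  s0 <- batch_series(t5, rep(0.2, 5), rep(10, 5), rep(0, 5), 6)
  expect_equal(growth_rate(s0), 0, tolerance = 1e-12)

  # 2% multiplicative noise: within 5% of generator truth
  set.seed(9)
  tt <- seq(0, 5, length.out = 12)
  for (i in 1:10) {
    od <- 0.02 * exp(0.6 * tt) * (1 + rnorm(12, 0, 0.02))
    sn <- batch_series(tt, od, 10 - 0.5 * tt, rep(0, 12), 6)
    expect_equal(growth_rate(sn), 0.6, tolerance = 0.05)
  }
})

test_that("batch_series enforces its invariants", {
  expect_error(batch_series(c(0, 1, 2), c(1, 1, 1), c(5, 5, 5), c(0, 0, 0), 6),
               "at least 4")
  expect_error(batch_series(c(0, 1, 1, 2), rep(1, 4), rep(5, 4), rep(0, 4), 6),
               "strictly increasing")
  expect_error(batch_series(0:3, c(1, -1, 1, 1), rep(5, 4), rep(0, 4), 6),
               "positive")
  expect_error(batch_series(0:3, rep(1, 4), c(5, 1, 8, 0), rep(0, 4), 6),
               "increase beyond")
})

test_that("yields reads consumption and excretion off the OD regressions", {
  tt <- seq(0, 3, length.out = 6)
  od <- 0.05 * exp(0.8 * tt)
  s <- batch_series(tt, od, 10 - 3 * (od - od[1]), 1.5 * (od - od[1]), 6)
  y <- yields(s)
  expect_equal(y$consumption_yield, 18, tolerance = 1e-9)   # 3 mM/OD x 6 C
  expect_equal(y$excretion_yield, 3, tolerance = 1e-9)      # 1.5 mM/OD x 2 C
  expect_equal(y$growth_rate, 0.8, tolerance = 1e-9)
  expect_equal(unname(y$r_squared["substrate"]), 1, tolerance = 1e-9)

  # no acetate at all: excretion yield is exactly zero
  s2 <- batch_series(tt, od, 10 - 3 * (od - od[1]), rep(0, 6), 6)
  expect_equal(yields(s2)$excretion_yield, 0)

  # substrate increasing with OD is not a consumption series
  s3 <- batch_series(tt, od, 10 + 3 * (od - od[1]), rep(0, 6), 6,
                     noise_tol = 2)
  expect_error(yields(s3), "increases with OD")
})

test_that("carbon utilization combines yields and growth rate", {
  y <- structure(list(growth_rate = 0.5, consumption_yield = 18,
                      excretion_yield = 0,
                      r_squared = c(substrate = 1, acetate = NA)),
                 class = "yield_estimate")
  expect_equal(carbon_utilization(y), 9)
  y$excretion_yield <- 20
  expect_error(carbon_utilization(y), "exceeds consumption")
})

test_that("carbon utilization is invariant to the sampling grid (noiseless)", {
  make_series <- function(tt) {
    od <- 0.02 * exp(0.7 * tt)
    batch_series(tt, od, 15 - 2.5 * (od - od[1]), 0.8 * (od - od[1]), 6)
  }
  cu1 <- carbon_utilization(yields(make_series(seq(0, 4, length.out = 8))))
  cu2 <- carbon_utilization(yields(make_series(sort(c(0.1, 0.5, 1.3, 2.2,
                                                      2.9, 3.7, 4.4)))))
  expect_equal(cu1, cu2, tolerance = 1e-9)
})

test_that("maintenance_line matches the two-point closed form", {
  # two points constructed by inverting a slope-23.3, intercept-4.22 line
  pts <- data.frame(growth_rate = c(0.79, 0.29),
                    carbon_utilization = c(22.627, 10.977))
  line <- maintenance_line(pts)
  expect_equal(line$slope, 23.3, tolerance = 1e-3)
  expect_equal(line$intercept, 4.22, tolerance = 1e-3)

  # three collinear points: same line, R^2 = 1
  pts3 <- rbind(pts, data.frame(growth_rate = 0.5,
                                carbon_utilization = 23.3 * 0.5 + 4.22))
  line3 <- maintenance_line(pts3)
  expect_equal(line3$slope, line$slope, tolerance = 1e-9)
  expect_equal(line3$r_squared, 1, tolerance = 1e-9)

  expect_error(maintenance_line(pts[c(1, 1), ]), "distinct growth rates")
  expect_warning(maintenance_line(
    data.frame(growth_rate = c(0.2, 0.8),
               carbon_utilization = c(1, 9))), "negative maintenance intercept")

  # noisy 4-point recovery within 10% of generating line
  set.seed(31)
  for (i in 1:10) {
    gr <- c(0.1, 0.35, 0.6, 0.85)
    cu <- 20 * gr + 5 + rnorm(4, 0, 0.2)
    ln <- maintenance_line(data.frame(growth_rate = gr,
                                      carbon_utilization = cu))
    expect_equal(ln$slope, 20, tolerance = 0.1)
    expect_equal(ln$intercept, 5, tolerance = 0.1)
  }
})

test_that("NGAM from the intercept matches the toy closed form", {
  # on an overflow-free substrate, pinned uptake u yields ATP a_mol * u with
  # biomass shut off; u = b / (kappa * n_C) -> NGAM = a_mol * b / (kappa * n_C)
  kappa <- 0.55
  b <- kappa * the_toy_spec$ngam / the_toy_spec$atp_per_c1
  line <- structure(list(slope = 15, intercept = b, r_squared = 1),
                    class = "maintenance_line")
  ngam <- ngam_from_intercept(the_toy_model, line, kappa, "EX_galactose", 6,
                              closed_exchanges = "EX_glucose")
  expect_equal(ngam, 18 * b / (kappa * 6), tolerance = 1e-9)
  expect_equal(ngam, the_toy_spec$ngam, tolerance = 1e-9)

  # doubling the conversion halves the NGAM
  ngam2 <- ngam_from_intercept(the_toy_model, line, 2 * kappa,
                               "EX_galactose", 6,
                               closed_exchanges = "EX_glucose")
  expect_equal(ngam2, ngam / 2, tolerance = 1e-9)

  # zero intercept: no maintenance carbon, no NGAM
  line0 <- structure(list(slope = 15, intercept = 0, r_squared = 1),
                     class = "maintenance_line")
  expect_equal(ngam_from_intercept(the_toy_model, line0, kappa,
                                   "EX_galactose", 6,
                                   closed_exchanges = "EX_glucose"),
               0, tolerance = 1e-9)

  expect_error(ngam_from_intercept(the_toy_model, line, kappa,
                                   "EX_galactose", 6, atpm = "NOPE"),
               "no ATP-hydrolysis")
})

test_that("fit_gam recovers a forward-simulated GAM by bisection", {
  obs <- lapply(c("glucose", "galactose"), function(su) {
    cap <- the_toy_spec$substrates$uptake_cap[
      the_toy_spec$substrates$name == su]
    med <- stats::setNames(list(c(-cap, -cap)), paste0("EX_", su))
    med[[paste0("EX_", setdiff(c("glucose", "galactose"), su))]] <- c(0, 0)
    list(medium = med,
         growth_rate = fba(toy_medium(the_toy_model, the_toy_spec,
                                      su))$objective_value)
  })
  fit <- fit_gam(the_toy_model, obs, search_interval = c(0, 200))
  expect_equal(fit$gam, 20, tolerance = 0.01 / 20)
  expect_equal(length(fit$residuals), 2)
  expect_lt(max(abs(fit$residuals)), 1e-3)

  # interval that excludes the truth
  expect_error(fit_gam(the_toy_model, obs, search_interval = c(50, 200)),
               "outside the reachable range")
})

test_that("predicted growth is monotone nonincreasing in GAM and NGAM", {
  mu_at <- function(gam, ngam) {
    m <- set_gam(the_toy_model, gam)
    m$reactions[["ATPM"]]$lb <- ngam
    fba(toy_medium(m, the_toy_spec, "glucose"))$objective_value
  }
  mus_gam <- vapply(seq(0, 90, length.out = 10), mu_at, 0, ngam = 5)
  expect_true(all(diff(mus_gam) <= 1e-9))
  mus_ngam <- vapply(seq(0, 60, length.out = 10), function(n) mu_at(20, n), 0)
  expect_true(all(diff(mus_ngam) <= 1e-9))
})

test_that("a model read back from SBML can be re-tagged for GAM fitting", {
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(the_toy_model, f)
  back <- read_sbml(f)
  expect_error(set_gam(back, 10), "GAM metadata")
  tagged <- tag_biomass_gam(back, gam = the_toy_spec$gam)
  m10 <- set_gam(tagged, 10)
  expect_equal(unname(m10$reactions$BIOMASS$stoich["atp_c"]), -10,
               tolerance = 1e-12)
  expect_error(tag_biomass_gam(back, 20, c(atp = "nonexistent_c",
                                           h2o = "h2o_c", adp = "adp_c",
                                           pi = "pi_c")),
               "lacks the hydrolysis species")
})

test_that("noiseless end-to-end maintenance estimation is exact", {
  glc <- simulate_batch(the_toy_spec, "glucose", noiseless_cfg())
  gal <- simulate_batch(the_toy_spec, "galactose", noiseless_cfg())
  est <- estimate_maintenance(the_toy_model, list(glc, gal),
                              cdw_conv = 0.55,
                              substrate_ids = c("EX_glucose", "EX_galactose"))
  expect_equal(est$ngam, the_toy_spec$ngam, tolerance = 1e-6)
  expect_equal(est$gam, the_toy_spec$gam, tolerance = 0.01 / 20)
})
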