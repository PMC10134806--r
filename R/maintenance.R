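#' A batch-culture time series
#'
#' Timed OD600, substrate and acetate measurements for one exponential batch
#' culture, used to estimate consumption/excretion yields and, across several
#' substrates, maintenance energy.
#'
#' @param times sampling times (h), strictly increasing, >= 4 points.
#' @param od OD600 readings, positive.
#' @param substrate_mM substrate concentrations (mM), nonincreasing within
#'   noise.
#' @param acetate_mM acetate concentrations (mM).
#' @param substrate_carbons carbon atoms per substrate molecule.
#' @param medium_label free-text label (e.g. the substrate name).
#' @param noise_tol tolerated upward substrate excursion, as a fraction of
#'   the observed concentration range (measurement noise).
#' @return a `batch_series` object.
#' @export
batch_series <- function(times, od, substrate_mM, acetate_mM,
                         substrate_carbons, medium_label = "",
                         noise_tol = 0.05) {
  n <- length(times)
  stopifnot(length(od) == n, length(substrate_mM) == n,
            length(acetate_mM) == n)
  if (n < 4L) stop("a batch series needs at least 4 time points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(od <= 0)) stop("OD readings must be positive")
  rng <- diff(range(substrate_mM))
  if (any(diff(substrate_mM) > noise_tol * max(rng, .Machine$double.eps)))
    stop("substrate concentrations increase beyond measurement noise")
  stopifnot(substrate_carbons >= 1)
  structure(list(times = as.numeric(times), od = as.numeric(od),
                 substrate_mM = as.numeric(substrate_mM),
                 acetate_mM = as.numeric(acetate_mM),
                 substrate_carbons = as.integer(substrate_carbons),
                 medium_label = medium_label),
            class = "batch_series")
}

#' Exponential growth rate of a batch series
#'
#' Slope of the ordinary-least-squares fit of `ln(OD600)` against time over
#' the series (all points are assumed to lie in exponential phase).
#'
#' @param s a [batch_series()].
#' @return growth rate (1/h).
#' @export
growth_rate <- function(s) {
  stopifnot(inherits(s, "batch_series"))
  if (any(s$od <= 0)) stop("OD must be positive to take logarithms")
  unname(stats::coef(stats::lm(log(s$od) ~ s$times))[2])
}

#' Consumption and excretion yields of a batch series
#'
#' Regresses concentrations against OD600 (not time): the substrate slope,
#' negated and converted to carbon atoms, is the consumption yield; the
#' acetate slope times its 2 carbons is the excretion yield. Both in
#' mM-C/OD600.
#'
#' @param s a [batch_series()].
#' @return a `yield_estimate`: list with `growth_rate` (1/h),
#'   `consumption_yield`, `excretion_yield` (mM-C/OD600) and `r_squared`
#'   (named, per regression; acetate NA when never observed).
#' @export
yields <- function(s) {
  stopifnot(inherits(s, "batch_series"))
  fs <- stats::lm(s$substrate_mM ~ s$od)
  slope_s <- unname(stats::coef(fs)[2])
  if (slope_s > 0)
    stop("substrate concentration increases with OD; not a consumption series")
  cons <- -slope_s * s$substrate_carbons
  if (all(s$acetate_mM == 0)) {
    exc <- 0
    r2a <- NA_real_
  } else {
    fa <- stats::lm(s$acetate_mM ~ s$od)
    exc <- max(0, unname(stats::coef(fa)[2])) * 2
    r2a <- r2_of(fa)
  }
  structure(list(growth_rate = growth_rate(s),
                 consumption_yield = cons, excretion_yield = exc,
                 r_squared = c(substrate = r2_of(fs),
                               acetate = r2a)),
            class = "yield_estimate")
}

#' Carbon utilization rate
#'
#' The rate at which carbon atoms are either incorporated into biomass or
#' burned for energy: `(consumption - excretion) x growth rate`, in
#' mM-C/OD600/h.
#'
#' @param y a [yields()] estimate.
#' @return carbon utilization rate (mM-C/OD600/h).
#' @export
carbon_utilization <- function(y) {
  stopifnot(inherits(y, "yield_estimate"))
  d <- y$consumption_yield - y$excretion_yield
  if (d < 0) stop("excretion yield exceeds consumption yield; ",
                  "net carbon intake would be negative")
  d * y$growth_rate
}

#' Maintenance line across growth rates
#'
#' Ordinary least squares of carbon utilization rate against growth rate
#' across substrates. The y-intercept is the carbon spent at zero growth
#' (non-growth maintenance); the slope combines biomass carbon and
#' growth-associated maintenance.
#'
#' @param points data frame with columns `growth_rate` (1/h) and
#'   `carbon_utilization` (mM-C/OD600/h); >= 2 distinct growth rates.
#' @return a `maintenance_line`: list with `slope` (mM-C/OD600), `intercept`
#'   (mM-C/OD600/h) and `r_squared`.
#' @export
maintenance_line <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("growth_rate", "carbon_utilization") %in% names(points)))
  if (length(unique(points$growth_rate)) < 2L)
    stop("need at least 2 distinct growth rates")
  fit <- stats::lm(carbon_utilization ~ growth_rate, data = points)
  ic <- unname(stats::coef(fit)[1])
  if (ic < 0) warning("negative maintenance intercept (", signif(ic, 3),
                      " mM-C/OD600/h); not clamped")
  structure(list(slope = unname(stats::coef(fit)[2]), intercept = ic,
                 r_squared = r2_of(fit)),
            class = "maintenance_line")
}

#' Non-growth-associated maintenance from the line intercept
#'
#' Converts the maintenance-line intercept into a substrate uptake flux
#' (`intercept / (cdw_conv x substrate_carbons)` mmol/gCDW/h), pins uptake to
#' it, fixes flux through the biomass reaction to zero, and maximises flux
#' through the ATP-hydrolysis reaction. The optimum is the NGAM, to be
#' installed as that reaction's lower bound. Acetate secretion (all exchange
#' secretion) stays free.
#'
#' @param model a `metabolic_model` whose objective is the biomass reaction.
#' @param line a [maintenance_line()].
#' @param cdw_conv CDW per OD600*mL (mg/(OD600*mL)) used for unit conversion;
#'   for a zero-growth quantity, the CDW fit evaluated at zero growth.
#' @param substrate exchange reaction id of the substrate.
#' @param substrate_carbons carbon atoms per substrate molecule.
#' @param atpm id of the ATP-hydrolysis (maintenance) reaction.
#' @param closed_exchanges exchange reaction ids whose uptake is shut off
#'   (lower bound 0) so the pinned substrate is the sole carbon source;
#'   secretion through them stays open.
#' @return NGAM (mmol ATP/gCDW/h).
#' @export
ngam_from_intercept <- function(model, line, cdw_conv, substrate,
                                substrate_carbons, atpm = "ATPM",
                                closed_exchanges = character(0)) {
  stopifnot(inherits(line, "maintenance_line"))
  if (!atpm %in% reaction_ids(model))
    stop("model has no ATP-hydrolysis reaction '", atpm, "'")
  uptake <- line$intercept / (cdw_conv * substrate_carbons)
  closures <- lapply(closed_exchanges, function(id)
    c(0, max(0, model$reactions[[id]]$ub)))
  m <- set_medium(model, c(stats::setNames(closures, closed_exchanges),
                           stats::setNames(list(c(-uptake, -uptake)),
                                           substrate)))
  m$reactions[[m$objective_id]]$lb <- 0
  m$reactions[[m$objective_id]]$ub <- 0
  m$reactions[[atpm]]$lb <- 0
  m$reactions[[atpm]]$ub <- 1000
  m$objective_id <- atpm
  m$objective_sense <- "maximize"
  sol <- fba(m)
  if (sol$status != "optimal")
    stop("NGAM problem ", sol$status, " with uptake pinned to ",
         signif(uptake, 4), " mmol/gCDW/h on '", substrate, "'")
  sol$objective_value
}

#' Tag a model's biomass reaction with its GAM term
#'
#' [build_biomass_reaction()] records the GAM and the ATP-hydrolysis species
#' on the reaction as attributes, which [set_gam()], [fit_gam()] and
#' [gr_fba()] rely on. SBML stores only stoichiometry, bounds and the
#' objective, so a model read back from file must be re-tagged before those
#' functions can adjust its GAM.
#'
#' @param model a `metabolic_model` whose objective is the biomass reaction.
#' @param gam the GAM currently embedded in the biomass stoichiometry
#'   (mmol ATP/gCDW).
#' @param gam_species named character with entries `atp`, `h2o`, `adp`, `pi`
#'   (optionally `h`) naming the hydrolysis species.
#' @return the model with the metadata attached.
#' @export
tag_biomass_gam <- function(model, gam,
                            gam_species = c(atp = "atp_c", h2o = "h2o_c",
                                            adp = "adp_c", pi = "pi_c")) {
  bio <- model$reactions[[model$objective_id]]
  miss <- setdiff(unname(gam_species), names(bio$stoich))
  if (length(miss))
    stop("biomass reaction lacks the hydrolysis species: ",
         paste(miss, collapse = ", "))
  attr(bio, "gam") <- gam
  attr(bio, "gam_species") <- gam_species
  model$reactions[[model$objective_id]] <- bio
  model
}

#' Set the growth-associated maintenance of a model
#'
#' Adjusts the GAM term of a biomass reaction built by
#' [build_biomass_reaction()] (which records its current GAM and the species
#' it acts on).
#'
#' @param model a `metabolic_model`.
#' @param gam new GAM (mmol ATP/gCDW).
#' @return the modified model.
#' @export
set_gam <- function(model, gam) {
  bio <- model$reactions[[model$objective_id]]
  old <- attr(bio, "gam")
  gsp <- attr(bio, "gam_species")
  if (is.null(old) || is.null(gsp))
    stop("biomass reaction does not carry GAM metadata; build it with ",
         "build_biomass_reaction()")
  gdir <- c(atp = -1, h2o = -1, adp = 1, pi = 1, h = 1)
  delta <- (gam - old) * gdir[names(gsp)]
  bio$stoich[unname(gsp)] <- bio$stoich[unname(gsp)] + unname(delta)
  attr(bio, "gam") <- gam
  g <- attr(bio, "component_groups")
  if (!is.null(g)) {
    g$gam <- stats::setNames(gam * gdir[names(gsp)], unname(gsp))
    attr(bio, "component_groups") <- g
  }
  model$reactions[[model$objective_id]] <- bio
  model
}

#' Fit the growth-associated maintenance to observed growth rates
#'
#' Bisects on the GAM coefficient of the biomass reaction until the summed
#' signed difference between FBA-predicted and observed growth rates crosses
#' zero. FBA-predicted growth must be monotone nonincreasing in GAM over the
#' search interval (checked on a coarse grid); the fit cannot in general be
#' made exact for several observations at once, so per-observation residuals
#' are reported.
#'
#' @param model a `metabolic_model` with a [build_biomass_reaction()] biomass
#'   reaction.
#' @param observations list of `list(medium = <exchange bounds as in
#'   [set_medium()]>, growth_rate = <observed 1/h>)`.
#' @param search_interval GAM bracket (mmol ATP/gCDW).
#' @param tol_gam terminal bracket width (mmol ATP/gCDW).
#' @return list with `gam`, `predicted` and `residuals` (per observation).
#' @export
fit_gam <- function(model, observations, search_interval = c(0, 200),
                    tol_gam = 0.01) {
  stopifnot(length(observations) >= 1)
  predict_all <- function(gam) {
    m <- set_gam(model, gam)
    vapply(observations, function(ob) {
      sol <- fba(set_medium(m, ob$medium))
      if (sol$status != "optimal")
        stop("FBA ", sol$status, " at GAM = ", signif(gam, 5))
      sol$objective_value
    }, 0)
  }
  obs <- vapply(observations, `[[`, 0, "growth_rate")
  resid_sum <- function(gam) sum(predict_all(gam) - obs)
  grid <- seq(search_interval[1], search_interval[2], length.out = 5)
  mu_grid <- vapply(grid, function(g) sum(predict_all(g)), 0)
  if (any(diff(mu_grid) > 1e-9)) {
    stop("predicted growth is not monotone nonincreasing in GAM; ",
         "diagnostic grid: ",
         paste(sprintf("GAM=%.3g mu=%.5g", grid, mu_grid), collapse = "; "))
  }
  lo <- search_interval[1]; hi <- search_interval[2]
  r_lo <- resid_sum(lo); r_hi <- resid_sum(hi)
  if (r_lo < 0 || r_hi > 0) {
    stop("observed growth rates outside the reachable range on this ",
         "interval (residual ", signif(r_lo, 4), " at GAM=", lo,
         ", ", signif(r_hi, 4), " at GAM=", hi, ")")
  }
  while (hi - lo > tol_gam) {
    mid <- (lo + hi) / 2
    if (resid_sum(mid) >= 0) lo <- mid else hi <- mid
  }
  gam <- (lo + hi) / 2
  pred <- predict_all(gam)
  list(gam = gam, predicted = pred, residuals = pred - obs)
}

#' Maintenance parameters from batch series, end to end
#'
#' Runs the full estimation chain on a set of batch cultures: growth rates
#' and yields per series, carbon utilization, the maintenance line across
#' series, NGAM from its intercept (installed as the ATP-hydrolysis lower
#' bound before the GAM fit), and GAM by fitting FBA-predicted to observed
#' growth rates with per-series substrate uptake pinned to its measured
#' value.
#'
#' @param model a `metabolic_model` (biomass objective built by
#'   [build_biomass_reaction()]).
#' @param series list of [batch_series()].
#' @param cdw_conv mg CDW/(OD600*mL) conversion used throughout.
#' @param substrate_ids character: exchange reaction id per series.
#' @param atpm ATP-hydrolysis reaction id.
#' @param ngam_series index of the series used for the NGAM conversion
#'   (defaults to the one without measurable acetate excretion, where gross
#'   uptake equals net carbon intake).
#' @return list with `ngam` (mmol ATP/gCDW/h), `gam` (mmol ATP/gCDW),
#'   `cdw_conversion`, `line` (the [maintenance_line()]), `yields` and
#'   `gam_fit` details.
#' @export
estimate_maintenance <- function(model, series, cdw_conv, substrate_ids,
                                 atpm = "ATPM", ngam_series = NULL) {
  stopifnot(length(series) == length(substrate_ids), length(series) >= 2)
  ys <- lapply(series, yields)
  pts <- data.frame(
    growth_rate = vapply(ys, `[[`, 0, "growth_rate"),
    carbon_utilization = vapply(ys, carbon_utilization, 0))
  line <- maintenance_line(pts)
  if (is.null(ngam_series)) {
    no_overflow <- which(vapply(ys, `[[`, 0, "excretion_yield") == 0)
    ngam_series <- if (length(no_overflow)) no_overflow[1] else 1L
  }
  ngam <- ngam_from_intercept(model, line, cdw_conv,
                              substrate_ids[ngam_series],
                              series[[ngam_series]]$substrate_carbons,
                              atpm = atpm,
                              closed_exchanges =
                                setdiff(substrate_ids, substrate_ids[ngam_series]))
  m <- model
  m$reactions[[atpm]]$lb <- ngam
  observations <- lapply(seq_along(series), function(i) {
    upt <- ys[[i]]$consumption_yield * ys[[i]]$growth_rate /
      (cdw_conv * series[[i]]$substrate_carbons)
    med <- stats::setNames(list(c(-upt, -upt)), substrate_ids[i])
    for (other in setdiff(substrate_ids, substrate_ids[i]))
      med[[other]] <- c(0, max(0, model$reactions[[other]]$ub))
    list(medium = med, growth_rate = ys[[i]]$growth_rate)
  })
  fit <- fit_gam(m, observations)
  list(ngam = ngam, gam = fit$gam, cdw_conversion = cdw_conv,
       line = line, yields = ys, gam_fit = fit)
}
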