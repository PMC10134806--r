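# Independent oracles used across the suite. These deliberately avoid the
# package's own solution paths: the LP oracle enumerates polytope vertices by
# brute force, and the gap-fill oracle enumerates candidate subsets.

# Brute-force LP oracle: max/min c'v s.t. S v = 0, lb <= v <= ub (finite
# bounds). Enumerates all vertices: every choice of (n - rank(S)) variables
# fixed at a bound, solving for the rest. Only practical for n <= ~8.
oracle_lp <- function(obj, S, lb, ub, maximize = TRUE) {
  S <- as.matrix(S)
  n <- ncol(S)
  stopifnot(all(is.finite(lb)), all(is.finite(ub)))
  rk <- qr(S)$rank
  nf <- n - rk
  best <- NULL
  feasible <- FALSE
  check_point <- function(v) {
    if (any(v < lb - 1e-7) || any(v > ub + 1e-7)) return()
    if (max(abs(S %*% v)) > 1e-7) return()
    feasible <<- TRUE
    val <- sum(obj * v)
    if (is.null(best) ||
        (maximize && val > best) || (!maximize && val < best)) best <<- val
  }
  if (nf == 0L) {
    v <- tryCatch(qr.solve(S, rep(0, nrow(S))), error = function(e) NULL)
    if (!is.null(v)) check_point(v)
  } else {
    fixed_sets <- utils::combn(n, nf, simplify = FALSE)
    for (Fidx in fixed_sets) {
      Bidx <- setdiff(seq_len(n), Fidx)
      for (mask in 0:(2^nf - 1)) {
        at_ub <- as.logical(bitwAnd(mask, 2^(seq_len(nf) - 1)))
        vF <- ifelse(at_ub, ub[Fidx], lb[Fidx])
        rhs <- -S[, Fidx, drop = FALSE] %*% vF
        vB <- tryCatch(qr.solve(S[, Bidx, drop = FALSE], rhs),
                       error = function(e) NULL)
        if (is.null(vB)) next
        v <- numeric(n)
        v[Fidx] <- vF
        v[Bidx] <- vB
        check_point(v)
      }
    }
  }
  if (!feasible) list(status = "infeasible", objective = NA_real_)
  else list(status = "optimal", objective = best)
}

# Oracle FBA via vertex enumeration on a model (small models only).
oracle_fba <- function(model) {
  S <- stoichiometric_matrix(model)
  lb <- vapply(model$reactions, `[[`, 0, "lb")
  ub <- vapply(model$reactions, `[[`, 0, "ub")
  obj <- as.numeric(colnames(S) == model$objective_id)
  oracle_lp(obj, S, lb, ub, maximize = model$objective_sense == "maximize")
}

# Assert that an optimal flux solution is mass-balanced and within bounds.
expect_mass_balanced <- function(model, sol, tol = 1e-6) {
  expect_equal(sol$status, "optimal")
  S <- stoichiometric_matrix(model)
  v <- sol$fluxes[colnames(S)]
  expect_lt(max(abs(S %*% v)), tol)
  lb <- vapply(model$reactions, `[[`, 0, "lb")
  ub <- vapply(model$reactions, `[[`, 0, "ub")
  expect_true(all(v >= lb - tol & v <= ub + tol))
}

# Brute-force gap-fill oracle: enumerate subsets by increasing cardinality
# (lexicographic within a level); return all feasible subsets of the first
# feasible cardinality.
oracle_gapfill_sets <- function(model, db, min_biomass = 1e-6) {
  ids <- sort(names(db$reactions))
  is_ok <- function(subset) {
    m <- model
    for (id in subset) m$reactions[[id]] <- db$reactions[[id]]
    m$reactions[[m$objective_id]]$lb <- min_biomass
    sol <- fba(m)
    sol$status == "optimal"
  }
  for (k in 0:length(ids)) {
    sets <- if (k == 0) list(character(0))
            else utils::combn(ids, k, simplify = FALSE)
    hits <- Filter(is_ok, sets)
    if (length(hits)) return(hits)
  }
  NULL
}

# A tiny 3-compartment fixture model used for stats/SBML tests:
# 2 exchanges, 1 transport, 3 internal reactions; metabolites 3 cyt / 1 per /
# 2 ext.
fixture_small_model <- function() {
  mets <- rbind(
    metabolite("s_e", "substrate", "extracellular", "C6H12O6"),
    metabolite("s_p", "substrate", "periplasm", "C6H12O6"),
    metabolite("s_c", "substrate", "cytoplasm", "C6H12O6"),
    metabolite("p_c", "product", "cytoplasm"),
    metabolite("e_c", "energy", "cytoplasm", NA, -1L),
    metabolite("b_e", "biomass out", "extracellular"))
  rxns <- list(
    reaction("EX_s", c(s_e = -1), -5, 0),
    reaction("T_s", c(s_e = -1, s_p = 1, s_c = 1, p_c = -1), -1000, 1000),
    reaction("R1", c(s_c = -1, p_c = 1, e_c = 2), 0, 1000),
    reaction("BIO", c(p_c = -1, e_c = -1, b_e = 1), 0, 1000),
    reaction("DR_e", c(e_c = -1), 0, 1000),
    reaction("EX_b", c(b_e = -1), 0, 1000))
  new_model(mets, rxns, objective_id = "BIO", id = "fixture6")
}
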