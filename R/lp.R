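#' Solve a bounded-variable linear program
#'
#' Solves `max (or min) c'x  subject to  A x = b,  lb <= x <= ub` with a dense
#' two-phase primal simplex supporting variable bounds directly. This is the
#' numerical core behind [fba()] and everything built on it. Bounds may be
#' infinite; equality-pinned variables (`lb == ub`) are handled.
#'
#' The solver refactorises the basis at every iteration (problems here are
#' small, tens of variables), uses a Dantzig pricing rule and switches to
#' Bland's anti-cycling rule when progress stalls.
#'
#' @param obj numeric objective coefficients, length `n`.
#' @param A constraint matrix (`m` x `n`).
#' @param b right-hand side, length `m`.
#' @param lb,ub variable bounds, length `n`; `-Inf`/`Inf` allowed.
#' @param maximize logical; maximize (default) or minimize.
#' @param tol primal feasibility tolerance (default `1e-9`).
#' @param max_iter simplex iteration cap per phase.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `objective` (NA unless optimal) and `x` (primal solution, NA unless
#'   optimal).
#' @keywords internal
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE,
                     tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) stop("lp_solve: lb > ub")
  cc <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  # drop numerically empty rows (0 = 0); infeasible if rhs nonzero
  rn <- rowSums(abs(A))
  if (any(rn < .Machine$double.eps)) {
    bad <- rn < .Machine$double.eps
    if (any(abs(b[bad]) > tol)) {
      return(list(status = "infeasible", objective = NA_real_, x = NULL))
    }
    A <- A[!bad, , drop = FALSE]; b <- b[!bad]; m <- nrow(A)
    if (m == 0L) {
      # unconstrained box problem: each variable at its best bound
      x <- ifelse(cc >= 0, lb, ub)
      x[cc == 0 & !is.finite(x)] <- 0
      if (any(!is.finite(x[cc != 0]))) {
        return(list(status = "unbounded", objective = NA_real_, x = NULL))
      }
      f <- sum(cc * x)
      return(list(status = "optimal",
                  objective = if (maximize) -f else f, x = x))
    }
  }

  # every nonbasic variable sits at a finite bound (or 0 if fully free):
  # the bound of smaller magnitude when both are finite
  start_upper <- !is.finite(lb) & is.finite(ub)
  both <- is.finite(lb) & is.finite(ub)
  start_upper[both] <- abs(ub[both]) < abs(lb[both])
  x0 <- ifelse(start_upper, ub, ifelse(is.finite(lb), lb, 0))

  # artificials: one per row, column sign(residual) * e_i, bounds [0, Inf)
  r0 <- as.numeric(b - A %*% x0)
  sgn <- ifelse(r0 >= 0, 1, -1)
  Aext <- cbind(A, diag(sgn, m))
  lbe <- c(lb, rep(0, m))
  ube <- c(ub, rep(Inf, m))
  ntot <- n + m
  art <- (n + 1L):ntot

  basis <- art
  # nonbasic status: 1 = at lower, 2 = at upper (free vars rest at value 0,
  # tracked via xval); we track values of all nonbasic vars explicitly.
  xval <- c(x0, abs(r0))
  at_upper <- logical(ntot)
  at_upper[seq_len(n)] <- start_upper

  run_phase <- function(cost, basis, xval, at_upper, allow) {
    it <- 0L; bland <- FALSE; stall <- 0L; last_obj <- Inf
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(err = "iter", basis = basis,
                                     xval = xval, at_upper = at_upper))
      B <- Aext[, basis, drop = FALSE]
      Binv_b <- tryCatch(solve(B, b - Aext[, -basis, drop = FALSE] %*%
                                    xval[-basis]),
                         error = function(e) NULL)
      if (is.null(Binv_b)) return(list(err = "singular", basis = basis,
                                       xval = xval, at_upper = at_upper))
      xval[basis] <- as.numeric(Binv_b)
      yv <- tryCatch(solve(t(B), cost[basis]), error = function(e) NULL)
      if (is.null(yv)) return(list(err = "singular", basis = basis,
                                   xval = xval, at_upper = at_upper))
      nb <- setdiff(seq_len(ntot), basis)
      nb <- nb[allow[nb]]
      d <- cost[nb] - as.numeric(crossprod(Aext[, nb, drop = FALSE], yv))
      # eligibility: at lower wants d < 0; at upper wants d > 0; a fully free
      # variable can move either way, so any nonzero reduced cost qualifies
      free_nb <- !is.finite(lbe[nb]) & !is.finite(ube[nb])
      movable <- free_nb | (ube[nb] - lbe[nb] > tol)  # pinned vars cannot move
      lower_ok <- !at_upper[nb] & !free_nb & d < -tol
      upper_ok <- at_upper[nb] & d > tol
      free_ok <- free_nb & abs(d) > tol
      elig <- which(movable & (lower_ok | upper_ok | free_ok))
      if (length(elig) == 0L) {
        return(list(err = NULL, basis = basis, xval = xval,
                    at_upper = at_upper,
                    obj = sum(cost * xval)))
      }
      obj_now <- sum(cost * xval)
      if (obj_now < last_obj - tol) { stall <- 0L; last_obj <- obj_now }
      else stall <- stall + 1L
      if (stall > 2L * ntot) bland <- TRUE
      j_rel <- if (bland) elig[which.min(nb[elig])]
               else elig[which.max(abs(d[elig]))]
      j <- nb[j_rel]
      # entering direction: up from a lower bound, down from an upper bound,
      # and downhill in reduced cost for a free variable
      dirn <- if (free_nb[j_rel]) -sign(d[j_rel]) else if (at_upper[j]) -1 else 1
      w <- as.numeric(solve(B, Aext[, j]))
      # basic vars move by -w * dirn * t ; entering moves dirn * t
      step <- Inf; leave <- 0L; leave_to_upper <- FALSE
      for (k in seq_len(m)) {
        delta <- -w[k] * dirn
        if (delta < -tol) {           # basic k decreasing toward its lb
          if (is.finite(lbe[basis[k]])) {
            t_k <- (lbe[basis[k]] - xval[basis[k]]) / delta
            if (t_k < step - 1e-12 ||
                (t_k < step + 1e-12 && basis[k] < if (leave) basis[leave] else Inf)) {
              step <- t_k; leave <- k; leave_to_upper <- FALSE
            }
          }
        } else if (delta > tol) {     # basic k increasing toward its ub
          if (is.finite(ube[basis[k]])) {
            t_k <- (ube[basis[k]] - xval[basis[k]]) / delta
            if (t_k < step - 1e-12 ||
                (t_k < step + 1e-12 && basis[k] < if (leave) basis[leave] else Inf)) {
              step <- t_k; leave <- k; leave_to_upper <- TRUE
            }
          }
        }
      }
      # entering variable's own opposite bound (bound flip)
      span <- ube[j] - lbe[j]
      flip <- FALSE
      if (is.finite(span) && span < step) { step <- span; flip <- TRUE }
      if (!is.finite(step)) {
        return(list(err = "unbounded", basis = basis, xval = xval,
                    at_upper = at_upper))
      }
      step <- max(step, 0)
      xval[basis] <- xval[basis] - w * dirn * step
      xval[j] <- xval[j] + dirn * step
      if (flip) {
        at_upper[j] <- !at_upper[j]
      } else {
        lv <- basis[leave]
        xval[lv] <- if (leave_to_upper) ube[lv] else lbe[lv]
        at_upper[lv] <- leave_to_upper
        basis[leave] <- j
      }
    }
  }

  # ---- phase 1: minimize sum of artificials
  cost1 <- c(rep(0, n), rep(1, m))
  allow1 <- rep(TRUE, ntot)
  p1 <- run_phase(cost1, basis, xval, at_upper, allow1)
  if (!is.null(p1$err)) {
    if (p1$err == "unbounded") {
      # phase-1 objective is bounded below by 0; treat as numerical failure
      stop("lp_solve: phase-1 failure (", p1$err, ")")
    }
    stop("lp_solve: phase-1 failure (", p1$err, ")")
  }
  art_sum <- sum(p1$xval[art])
  if (art_sum > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  basis <- p1$basis; xval <- p1$xval; at_upper <- p1$at_upper
  # freeze artificials at zero so they cannot re-enter or drift
  lbe[art] <- 0; ube[art] <- 0
  xval[art][abs(xval[art]) < 1e-7] <- 0

  # ---- phase 2: original objective, artificials barred from entering
  cost2 <- c(cc, rep(0, m))
  allow2 <- c(rep(TRUE, n), rep(FALSE, m))
  p2 <- run_phase(cost2, basis, xval, at_upper, allow2)
  if (!is.null(p2$err)) {
    if (p2$err == "unbounded") {
      return(list(status = "unbounded", objective = NA_real_, x = NULL))
    }
    stop("lp_solve: phase-2 failure (", p2$err, ")")
  }
  x <- p2$xval[seq_len(n)]
  # clip roundoff outside bounds
  x <- pmin(pmax(x, lb), ub)
  f <- sum(cc * x)
  list(status = "optimal", objective = if (maximize) -f else f, x = x)
}
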