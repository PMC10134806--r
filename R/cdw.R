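# R^2 without summary.lm's perfect-fit warning (noiseless fixtures are routine
# here)
r2_of <- function(fit) {
  y <- stats::model.response(stats::model.frame(fit))
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(1)
  1 - sum(stats::residuals(fit)^2) / tss
}

#' A pellet-weighing record
#'
#' One dry/wet pellet weighing for salt-corrected cell dry weight (CDW)
#' estimation. Cultures grown at seawater osmolarity must be washed in NaCl
#' solution rather than water (washing in water lyses the cells), so the dry
#' pellet contains salt from the residual wash solution; the estimator
#' corrects for it.
#'
#' @param x dry pellet weight (mg).
#' @param y wet pellet weight (mg); must exceed `x`.
#' @param w harvested culture amount (OD600*mL).
#' @param rho wash-solution salinity: mg NaCl per mg water (dimensionless;
#'   e.g. 0.0306 for a 0.52 M NaCl wash).
#' @param beta assumed cellular water per CDW (mg/mg); ~2 for rod-shaped
#'   Gram-negative bacteria.
#' @return an object of class `"pellet_weighing"`.
#' @export
pellet_weighing <- function(x, y, w, rho, beta = 2) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(w),
            is.numeric(rho), is.numeric(beta))
  if (x <= 0) stop("dry weight x must be positive")
  if (y <= x) stop("wet weight y must exceed dry weight x")
  if (w <= 0) stop("harvested amount w must be positive")
  if (rho < 0 || rho >= 1) stop("salinity rho must be in [0, 1)")
  if (beta < 0) stop("beta must be nonnegative")
  if (rho * beta >= 1) stop("rho * beta must be below 1")
  structure(list(x = x, y = y, w = w, rho = rho, beta = beta),
            class = "pellet_weighing")
}

#' Upper bound on cellular water per CDW
#'
#' The wet-minus-dry weight difference caps the cellular water a pellet can
#' hold, giving `beta_max = y/x - 1`. With carefully removed supernatant this
#' is typically below 5.
#'
#' @param p a [pellet_weighing()].
#' @return `beta_max` (mg water per mg CDW).
#' @export
beta_max <- function(p) {
  stopifnot(inherits(p, "pellet_weighing"))
  p$y / p$x - 1
}

#' Direct salt-corrected CDW estimate from one pellet
#'
#' Solves the water/salt mass balance of a washed pellet for `alpha`, the CDW
#' per OD600*mL:
#' `alpha = (x (1 + rho) - rho y) / (w (1 - rho beta))`.
#' At `rho = 0` this reduces to the classic `x / w`. The dependence on the
#' assumed `beta` is weak for dilute washes (the `1/(1 - rho beta)` factor).
#'
#' @param p a [pellet_weighing()].
#' @return a `cdw_estimate`: list with `alpha` (mg/(OD600*mL)), `beta_max`,
#'   and `alpha_interval` (alpha evaluated at `beta +- 1`, clamped to the
#'   admissible beta range).
#' @export
alpha_direct <- function(p) {
  stopifnot(inherits(p, "pellet_weighing"))
  bmax <- beta_max(p)
  # beta enters only through the rho*beta product, so a salt-free wash makes
  # the assumed beta irrelevant; beta == beta_max (no extracellular water) is
  # the admissible boundary
  if (p$rho > 0 && p$beta > bmax)
    stop("assumed cellular water exceeds total pellet water (beta > beta_max = ",
         signif(bmax, 4), ")")
  num <- p$x * (1 + p$rho) - p$rho * p$y
  if (num <= 0)
    stop("inconsistent record: wash salt outweighs pellet solids ",
         "(x(1+rho) - rho*y <= 0)")
  alpha_at <- function(b) num / (p$w * (1 - p$rho * b))
  blo <- max(0, p$beta - 1)
  bhi <- min(p$beta + 1, bmax * (1 - 1e-9))
  structure(list(alpha = alpha_at(p$beta),
                 rho_hat = NULL, r_squared = NULL,
                 beta_max = bmax,
                 alpha_interval = c(alpha_at(blo), alpha_at(bhi))),
            class = "cdw_estimate")
}

#' @export
print.cdw_estimate <- function(x, ...) {
  cat("<cdw_estimate> alpha =", signif(x$alpha, 4), "mg/(OD600*mL)")
  if (!is.null(x$rho_hat)) cat(", rho_hat =", signif(x$rho_hat, 4))
  if (!is.null(x$r_squared)) cat(", R^2 =", signif(x$r_squared, 6))
  cat("\n")
  invisible(x)
}

#' Alpha as a function of assumed beta
#'
#' Evaluates the direct estimator over a range of assumed cellular water
#' contents, to show how weakly `alpha` depends on `beta`.
#'
#' @param p a [pellet_weighing()].
#' @param betas numeric vector of beta values, all in `[0, beta_max)`.
#' @return data frame with columns `beta`, `alpha`.
#' @export
alpha_beta_curve <- function(p, betas) {
  stopifnot(inherits(p, "pellet_weighing"))
  bmax <- beta_max(p)
  if (any(betas < 0 | betas >= bmax))
    stop("all betas must lie in [0, beta_max = ", signif(bmax, 4), ")")
  alpha <- vapply(betas, function(b) {
    q <- p; q$beta <- b
    # beta = bmax exactly is excluded above; reuse the direct estimator
    alpha_direct(q)$alpha
  }, 0)
  data.frame(beta = betas, alpha = alpha)
}

#' An add-back dilution series of pellet weighings
#'
#' Aliquots of one culture are washed identically, then different volumes of
#' wash solution are added back before drying. Dry weight then grows linearly
#' in the added-back salt while wet weight grows in salt plus water, so
#' plotting `y` against `x` across the series separates `rho` (from the
#' slope) and `alpha` (from the x-intercept) without assuming `rho` known.
#'
#' @param x,y vectors of dry and wet pellet weights (mg), same length >= 2.
#' @param w harvested culture amount per aliquot (OD600*mL), common to all.
#' @param beta assumed cellular water per CDW (mg/mg).
#' @return an object of class `"addback_series"`.
#' @export
addback_series <- function(x, y, w, beta = 2) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (any(x <= 0)) stop("dry weights must be positive")
  if (any(y <= x)) stop("wet weights must exceed dry weights")
  if (w <= 0) stop("w must be positive")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 w = as.numeric(w), beta = as.numeric(beta)),
            class = "addback_series")
}

#' Joint (rho, alpha) estimate from an add-back series
#'
#' Ordinary least squares of wet weight `y` on dry weight `x` across the
#' series. The fitted slope `s` gives `rho_hat = 1/(s - 1)`; the x-intercept
#' `x0` gives `alpha = x0 (1 + rho_hat) / ((1 - rho_hat beta) w)`.
#'
#' @param s an [addback_series()].
#' @return a `cdw_estimate` with `alpha`, `rho_hat`, `r_squared`, `beta_max`
#'   (from the least-diluted pellet, i.e. smallest `x`).
#' @export
alpha_regression <- function(s) {
  stopifnot(inherits(s, "addback_series"))
  if (length(unique(s$x)) < 2L) stop("add-back series needs distinct dry weights")
  fit <- stats::lm(y ~ x, data = data.frame(x = s$x, y = s$y))
  sl <- unname(stats::coef(fit)[2])
  ic <- unname(stats::coef(fit)[1])
  if (sl <= 1) stop("fitted slope <= 1 implies nonpositive salinity; ",
                    "series inconsistent with the wash mass balance")
  rho_hat <- 1 / (sl - 1)
  x0 <- -ic / sl
  if (rho_hat * s$beta >= 1) stop("estimated rho * beta >= 1")
  alpha <- x0 * (1 + rho_hat) / ((1 - rho_hat * s$beta) * s$w)
  r2 <- r2_of(fit)
  i0 <- which.min(s$x)
  structure(list(alpha = alpha, rho_hat = rho_hat, r_squared = r2,
                 beta_max = s$y[i0] / s$x[i0] - 1,
                 alpha_interval = NULL),
            class = "cdw_estimate")
}
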