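# Regular-solution (fully connected / Curie-Weiss) baselines.
#
# Coupling convention: the fully connected free energy uses an effective
# coupling J_eff = C * J_micro with C = K + 1 the lattice connectivity, so
# that the classical binary spinodal betaJ = 1/[(K+1) phi (1-phi)] emerges
# with the *microscopic* J on the axis and the curves are directly
# comparable with the cavity results at the same J.

#' Regular-solution free energy
#'
#' \deqn{F(\varphi) = -\tfrac12\sum_{k,l} J^{eff}_{kl}\varphi_k\varphi_l
#'   + \sum_k \mu_k\varphi_k + \tfrac1\beta\sum_k \varphi_k\log\varphi_k}
#' with \eqn{J^{eff} = (K+1)J} (see the coupling convention above).
#' Components with \eqn{\varphi_k = 0} contribute no entropy
#' (\eqn{x\log x \to 0}).
#'
#' @param phis length-q vector of volume fractions in internal state order
#'   (solvent first, then states ordered as [state_labels()]); must sum to 1.
#' @param model an [interaction_model()].
#' @param connectivity effective connectivity C multiplying J
#'   (default `model$K + 1`); pass 1 to use the matrix J as the fully
#'   connected coupling itself.
#' @return scalar free energy per site, in kBT.
#' @export
rs_free_energy <- function(phis, model, connectivity = model$K + 1) {
  stopifnot(inherits(model, "interaction_model"))
  if (length(phis) != model$q) stop("phis must have length q = ", model$q)
  if (any(phis < 0)) stop("volume fractions must be >= 0")
  if (abs(sum(phis) - 1) > 1e-9) stop("volume fractions must sum to 1")
  Jeff <- connectivity * model$J
  ent <- sum(ifelse(phis > 0, phis * log(phis), 0))
  -0.5 * drop(phis %*% Jeff %*% phis) + sum(model$mu * phis) +
    ent / model$beta
}

#' Curie-Weiss binary spinodal
#'
#' The classical one-factor mean-field spinodal
#' \deqn{\beta J = \frac{1}{(K+1)\varphi(1-\varphi)}}
#' symmetric about its minimum 4/(K+1) at \eqn{\varphi = 1/2}.
#'
#' @param phi_grid densities in (0, 1).
#' @param K branching number (connectivity K + 1).
#' @return data frame of class `spinodal_curve` with columns `phi`, `betaJ`.
#' @export
cw_binary_spinodal <- function(phi_grid, K) {
  if (any(phi_grid <= 0 | phi_grid >= 1)) stop("phi must lie in (0, 1)")
  out <- data.frame(phi = phi_grid,
                    betaJ = 1 / ((K + 1) * phi_grid * (1 - phi_grid)))
  class(out) <- c("spinodal_curve", "data.frame")
  out
}

#' Curie-Weiss binary isotherm
#'
#' \deqn{\beta\mu = \log(1-\varphi) - \log\varphi + \beta J (K+1) \varphi}
#'
#' @param model binary model.
#' @param phi_grid densities in (0, 1) (default a fine uniform grid).
#' @return data frame with columns `phi`, `beta_mu`, sorted by `phi`.
#' @export
cw_isotherm <- function(model, phi_grid = seq(1e-4, 1 - 1e-4, length.out = 1e4)) {
  stopifnot(model$q == 2L)
  b <- model$beta; J <- model$J[2, 2]; K <- model$K
  data.frame(phi = phi_grid,
             beta_mu = log(1 - phi_grid) - log(phi_grid) +
               b * J * (K + 1) * phi_grid)
}

#' Cavity (Bethe-Peierls) binary isotherm
#'
#' Convenience wrapper around [binary_state_equation()] producing a dense
#' \eqn{(\varphi, \beta\mu)} isotherm covering almost all of (0, 1); the
#' message grid is spaced uniformly in log-odds so both density tails are
#' well resolved.
#'
#' @param model binary model with J > 0.
#' @param n number of samples.
#' @param span log-odds half-width of the u grid (controls how far into the
#'   tails the isotherm reaches).
#' @return data frame with columns `u`, `phi`, `beta_mu`, sorted by `phi`.
#' @export
bp_isotherm <- function(model, n = 2e4, span = 30) {
  J <- model$J[2, 2]
  u <- J * stats::plogis(seq(-span, span, length.out = n))
  binary_state_equation(u, model)
}

#' Regular-solution ternary stability
#'
#' Analytic Routh-Hurwitz stability map of the regular-solution (fully
#' connected) ternary model.  The de-mixing free-energy gradients are
#' \eqn{\beta g_\pm = -\beta J^{eff}_{\pm\pm}\varphi_\pm
#'   - \beta J^{eff}_{+-}\varphi_\mp + \log\varphi_\pm - \log\varphi_0}
#' and the Hessian is closed form:
#' \eqn{\partial g_\pm/\partial\varphi_\pm = -J^{eff}_{\pm\pm}
#'   + (1/\beta)(1/\varphi_\pm + 1/\varphi_0)},
#' \eqn{\partial g_\pm/\partial\varphi_\mp = -J^{eff}_{+-} + 1/(\beta\varphi_0)}.
#' Mixed iff det H > 0 and tr H > 0.  Vectorized over points.
#'
#' @inheritParams ternary_stability
#' @param connectivity effective connectivity multiplying J (default K + 1).
#' @return data frame with the same columns as [ternary_stability()].
#' @export
rs_ternary_stability <- function(phi_plus, phi_minus, model,
                                 connectivity = model$K + 1) {
  stopifnot(model$q == 3L, length(phi_plus) == length(phi_minus))
  if (any(phi_plus <= 0 | phi_minus <= 0 | phi_plus + phi_minus >= 1))
    stop("densities must lie strictly inside the simplex")
  b <- model$beta
  Jmm <- connectivity * model$J[2, 2]
  Jpp <- connectivity * model$J[3, 3]
  Jpm <- connectivity * model$J[2, 3]
  phi0 <- 1 - phi_plus - phi_minus
  h11 <- -Jpp + (1 / phi_plus + 1 / phi0) / b
  h22 <- -Jmm + (1 / phi_minus + 1 / phi0) / b
  h12 <- -Jpm + (1 / phi0) / b
  det <- h11 * h22 - h12^2
  tr <- h11 + h22
  mu_plus <- Jpp * phi_plus + Jpm * phi_minus -
    (log(phi_plus) - log(phi0)) / b
  mu_minus <- Jmm * phi_minus + Jpm * phi_plus -
    (log(phi_minus) - log(phi0)) / b
  label <- factor(ifelse(det > 0 & tr > 0, "mixed", "separated"),
                  levels = c("mixed", "separated"))
  data.frame(phi_plus = phi_plus, phi_minus = phi_minus,
             mu_plus = mu_plus, mu_minus = mu_minus,
             h11 = h11, h12 = h12, h22 = h22, det = det, trace = tr,
             label = label, converged = TRUE)
}

#' Regular-solution ternary phase map
#'
#' Grid version of [rs_ternary_stability()], mirroring [ternary_phase_map()].
#'
#' @inheritParams ternary_phase_map
#' @param connectivity effective connectivity multiplying J (default K + 1).
#' @export
rs_phase_map <- function(phi_plus_grid, phi_minus_grid, model,
                         margin = 1e-3, connectivity = model$K + 1) {
  g <- expand.grid(phi_plus = phi_plus_grid, phi_minus = phi_minus_grid)
  g <- g[g$phi_plus > 0 & g$phi_minus > 0 &
           g$phi_plus + g$phi_minus < 1 - margin, , drop = FALSE]
  out <- rs_ternary_stability(g$phi_plus, g$phi_minus, model,
                              connectivity = connectivity)
  class(out) <- c("phase_diagram", "data.frame")
  out
}

#' Maxwell equal-area construction for one isotherm
#'
#' Finds the coexistence chemical potential \eqn{\mu^*} of a non-monotone
#' (van der Waals loop) isotherm \eqn{\beta\mu(\varphi)}: the value at which
#' the signed area between the isotherm and the horizontal line
#' \eqn{\beta\mu = \beta\mu^*} between the outer crossings vanishes.  The
#' outer crossings are the binodal densities.  Solved as a root find on the
#' equal-area integral (trapezoidal quadrature on a uniform density grid).
#' A monotone isotherm yields an empty result (no transition), not an error.
#'
#' @param isotherm data frame with columns `phi`, `beta_mu` (from
#'   [bp_isotherm()], [cw_isotherm()], or [binary_state_equation()]).
#' @param n_grid number of uniform density points for quadrature
#'   (default 1e4).
#' @param tol tolerance on the equal-area residual (default 1e-10).
#' @return one-row data frame with `mu_star` (coexistence beta*mu),
#'   `phi_low`, `phi_high`, `residual`; zero rows if the isotherm is
#'   monotone.
#' @export
maxwell_binodal <- function(isotherm, n_grid = 1e4, tol = 1e-10) {
  stopifnot(all(c("phi", "beta_mu") %in% names(isotherm)))
  iso <- isotherm[order(isotherm$phi), ]
  phi <- seq(min(iso$phi), max(iso$phi), length.out = n_grid)
  bmu <- stats::approx(iso$phi, iso$beta_mu, xout = phi, ties = "ordered")$y
  d <- diff(bmu)
  empty <- data.frame(mu_star = numeric(), phi_low = numeric(),
                      phi_high = numeric(), residual = numeric())
  if (all(d <= 0) || all(d >= 0)) return(empty)   # monotone: no transition
  # loop extrema bracket mu*
  loc_max <- max(bmu[which(c(d, -1) > 0)])
  loc_min <- min(bmu[which(c(1, d) > 0)])
  if (!is.finite(loc_max) || !is.finite(loc_min) || loc_max <= loc_min)
    return(empty)
  area <- function(mu) {
    y <- bmu - mu
    s <- which(y[-1] * y[-n_grid] < 0)
    s <- c(s, which(y == 0))
    if (length(s) < 2) return(NA_real_)
    cross <- sort(vapply(s, function(i) {
      if (y[i] == 0) phi[i]
      else phi[i] + (phi[i + 1] - phi[i]) * y[i] / (y[i] - y[i + 1])
    }, numeric(1)))
    lo <- cross[1]; hi <- cross[length(cross)]
    inside <- phi > lo & phi < hi
    xs <- c(lo, phi[inside], hi)
    ys <- c(0, y[inside], 0)
    sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
  }
  eps <- (loc_max - loc_min) * 1e-9
  root <- stats::uniroot(area, c(loc_min + eps, loc_max - eps),
                         tol = .Machine$double.eps^0.75, extendInt = "no")
  mu_star <- root$root
  y <- bmu - mu_star
  s <- which(y[-1] * y[-n_grid] < 0)
  cross <- sort(vapply(s, function(i)
    phi[i] + (phi[i + 1] - phi[i]) * y[i] / (y[i] - y[i + 1]), numeric(1)))
  data.frame(mu_star = mu_star, phi_low = cross[1],
             phi_high = cross[length(cross)], residual = abs(area(mu_star)))
}

#' Binodal curve over a coupling grid
#'
#' Runs the Maxwell construction along a grid of couplings for either the
#' cavity (BP) or the Curie-Weiss isotherm.  Both isotherms depend on the
#' coupling only through \eqn{\beta J} (and K), so the curve is reported
#' against \eqn{\beta J}.
#'
#' @param betaJ_grid couplings to scan.
#' @param K branching number.
#' @param theory "bp" (cavity) or "cw" (Curie-Weiss).
#' @param ... passed to [maxwell_binodal()].
#' @return data frame of class `binodal_curve` with columns `betaJ`,
#'   `phi_low`, `phi_high`, `mu_star`, `residual` (couplings without a
#'   transition are omitted).
#' @export
binodal_curve <- function(betaJ_grid, K, theory = c("bp", "cw"), ...) {
  theory <- match.arg(theory)
  rows <- list()
  for (x in betaJ_grid) {
    model <- binary_model(x, 0, beta = 1, K = K)
    iso <- if (theory == "bp") bp_isotherm(model) else cw_isotherm(model)
    mb <- maxwell_binodal(iso, ...)
    if (nrow(mb)) rows[[length(rows) + 1L]] <- cbind(betaJ = x, mb)
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(betaJ = numeric(), mu_star = numeric(), phi_low = numeric(),
               phi_high = numeric(), residual = numeric())
  class(res) <- c("binodal_curve", "data.frame")
  res
}
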