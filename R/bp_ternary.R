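# Ternary homogeneous cavity equations.
#
# Messages (u-, u+) on a Cayley tree of branching K:
#   u_s = (1/beta) log[ e^{beta(J_ss - mu_s + K u_s)} + 1
#                       + e^{beta(J_pm - mu_t + K u_t)} ]  -  (same, J = 0)
# Densities follow from the three-state softmax with connectivity C = K + 1.

# vectorized log-sum-exp of three same-length vectors
lse3 <- function(a, b, c) {
  m <- pmax(a, b, c)
  m + log(exp(a - m) + exp(b - m) + exp(c - m))
}

ternary_rhs <- function(um, up, model) {
  b <- model$beta; K <- model$K
  Jmm <- model$J[2, 2]; Jpp <- model$J[3, 3]; Jpm <- model$J[2, 3]
  mum <- model$mu[2]; mup <- model$mu[3]
  hm <- b * (-mum + K * um); hp <- b * (-mup + K * up)
  den <- lse3(hm, 0, hp)
  list(um = (lse3(b * Jmm + hm, 0, b * Jpm + hp) - den) / b,
       up = (lse3(b * Jpm + hm, 0, b * Jpp + hp) - den) / b)
}

#' Homogeneous cavity fixed point, ternary solution
#'
#' Solves the coupled message equations for the two solutes of a ternary
#' solution on a Cayley tree.  Damped iteration from a grid of starting
#' points locates the dynamically stable solutions; a Newton sweep (with a
#' numerical Jacobian) over the same start grid then picks up any
#' remaining roots, including the dynamically unstable ones that coexist
#' between binodal and spinodal.  All distinct solutions are returned.
#'
#' @param model a ternary [interaction_model()] (q = 3).
#' @param tol joint residual tolerance (default 1e-12).
#' @param max_iter maximum iterations per start.
#' @param damping damping factor (default 0.5).
#' @param n_start starting points per message axis (default 5).
#' @return list of `cavity_state` objects with fields `u_minus`, `u_plus`,
#'   `residual`, `iterations`.
#' @export
ternary_fixed_point <- function(model, tol = 1e-12, max_iter = 1e5,
                                damping = 0.5, n_start = 5) {
  stopifnot(inherits(model, "interaction_model"), model$q == 3L)
  Js <- c(model$J[2, 2], model$J[3, 3], model$J[2, 3])
  lo <- min(0, Js); hi <- max(0, Js)
  gfun <- function(um, up) {
    r <- ternary_rhs(um, up, model)
    c(um - r$um, up - r$up)
  }
  roots <- list()
  add_root <- function(um, up, it) {
    r <- ternary_rhs(um, up, model)
    res <- max(abs(r$um - um), abs(r$up - up))
    if (!is.finite(res) || res > sqrt(tol)) return(invisible(NULL))
    for (rt in roots)
      if (abs(rt$u_minus - um) < 1e-7 && abs(rt$u_plus - up) < 1e-7)
        return(invisible(NULL))
    roots[[length(roots) + 1L]] <<- new_cavity_state(
      list(u_minus = um, u_plus = up, residual = res, iterations = it))
  }
  newton_polish <- function(um, up) {
    for (it in 1:60) {
      g0 <- gfun(um, up)
      if (max(abs(g0)) < tol) return(c(um, up))
      h <- 1e-7
      Jm <- cbind((gfun(um + h, up) - g0) / h, (gfun(um, up + h) - g0) / h)
      step <- tryCatch(solve(Jm, g0), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) return(NULL)
      # guard against wild steps outside the message range
      step <- pmin(pmax(step, -(hi - lo + 1)), hi - lo + 1)
      um <- um - step[1]; up <- up - step[2]
    }
    if (max(abs(gfun(um, up))) < sqrt(tol)) c(um, up) else NULL
  }
  starts <- expand.grid(um = seq(lo, hi, length.out = max(2, n_start)),
                        up = seq(lo, hi, length.out = max(2, n_start)))
  # damped iteration: finds the stable solutions
  corner <- starts[starts$um %in% c(lo, 0, hi) & starts$up %in% c(lo, 0, hi), ]
  for (s in seq_len(nrow(corner))) {
    um <- corner$um[s]; up <- corner$up[s]; it <- 0L
    repeat {
      it <- it + 1L
      r <- ternary_rhs(um, up, model)
      dn <- max(abs(r$um - um), abs(r$up - up))
      um <- (1 - damping) * um + damping * r$um
      up <- (1 - damping) * up + damping * r$up
      if (dn < tol) break
      if (it >= max_iter)
        stop("ternary fixed point did not converge: residual ", format(dn),
             " after ", max_iter, " iterations")
    }
    add_root(um, up, it)
  }
  # Newton sweep: picks up unstable roots as well
  for (s in seq_len(nrow(starts))) {
    sol <- newton_polish(starts$um[s], starts$up[s])
    if (!is.null(sol)) add_root(sol[1], sol[2], 0L)
  }
  if (!length(roots)) stop("no ternary fixed point found")
  roots
}

#' Solute densities from a ternary cavity state
#'
#' \deqn{\varphi_\pm = \frac{e^{-\beta\mu_\pm+\beta(K+1)u_\pm}}
#'   {e^{-\beta\mu_-+\beta(K+1)u_-} + 1 + e^{-\beta\mu_++\beta(K+1)u_+}}}
#'
#' @param state a `cavity_state` with `u_minus`, `u_plus`.
#' @param model the ternary model.
#' @return named vector `c(phi_plus, phi_minus)`.
#' @export
ternary_densities <- function(state, model) {
  stopifnot(model$q == 3L)
  b <- model$beta; C <- model$K + 1
  hm <- b * (-model$mu[2] + C * state$u_minus)
  hp <- b * (-model$mu[3] + C * state$u_plus)
  den <- lse3(hm, 0, hp)
  c(phi_plus = exp(hp - den), phi_minus = exp(hm - den))
}

#' Chemical potentials at prescribed ternary densities
#'
#' Inverts the ternary state equations: given volume fractions
#' \eqn{(\varphi_+, \varphi_-)} it returns the fields \eqn{(\mu_+, \mu_-)}
#' that produce them.  Uses the transformed variables
#' \eqn{m_\pm = -\mu_\pm + C u_\pm} (C = K + 1), for which
#' \eqn{\varphi_\pm = e^{\beta m_\pm}/(1 + e^{\beta m_-} + e^{\beta m_+})}
#' inverts in closed form, \eqn{\beta m_\pm = \log(\varphi_\pm/\varphi_0)}
#' with \eqn{\varphi_0 = 1-\varphi_+-\varphi_-}.  The message equations at
#' fixed \eqn{m_\pm},
#' \deqn{u_\pm = \tfrac1\beta\log\frac{e^{\beta(J_{\pm\pm}+m_\pm-u_\pm)}
#'  + e^{\beta(J_{+-}+m_\mp-u_\mp)} + 1}{e^{\beta(m_--u_-)}+e^{\beta(m_+-u_+)}+1}}
#' are then solved by damped iteration, and \eqn{\mu_\pm = -m_\pm + Cu_\pm}.
#' All arguments are vectorized over points.
#'
#' @param phi_plus,phi_minus volume fractions (vectors of equal length),
#'   each > 0 with `phi_plus + phi_minus < 1`.
#' @param model ternary model.
#' @param tol message residual tolerance.
#' @param max_iter maximum damped iterations.
#' @param damping damping factor.
#' @return list of vectors `mu_plus`, `mu_minus`, `u_plus`, `u_minus`,
#'   `m_plus`, `m_minus`, `converged` (logical), `iterations`, `residual`.
#' @export
ternary_fields_from_densities <- function(phi_plus, phi_minus, model,
                                          tol = 1e-12, max_iter = 2e4,
                                          damping = 0.5) {
  stopifnot(inherits(model, "interaction_model"), model$q == 3L,
            length(phi_plus) == length(phi_minus))
  if (any(phi_plus <= 0 | phi_minus <= 0 | phi_plus + phi_minus >= 1))
    stop("densities must satisfy phi_plus > 0, phi_minus > 0, phi_plus + phi_minus < 1")
  b <- model$beta; C <- model$K + 1
  Jmm <- model$J[2, 2]; Jpp <- model$J[3, 3]; Jpm <- model$J[2, 3]
  phi0 <- 1 - phi_plus - phi_minus
  mp <- log(phi_plus / phi0) / b          # m+ (closed-form inversion)
  mm <- log(phi_minus / phi0) / b         # m-
  um <- rep(0, length(mp)); up <- um
  it <- 0L; res <- Inf
  while (it < max_iter) {
    it <- it + 1L
    am <- b * (mm - um); ap <- b * (mp - up)
    den <- lse3(am, 0, ap)
    num_m <- lse3(b * Jmm + am, 0, b * Jpm + ap)
    num_p <- lse3(b * Jpm + am, 0, b * Jpp + ap)
    num <- (num_m - den) / b; nup <- (num_p - den) / b
    res <- max(abs(num - um), abs(nup - up))
    um <- (1 - damping) * um + damping * num
    up <- (1 - damping) * up + damping * nup
    if (res < tol) break
  }
  am <- b * (mm - um); ap <- b * (mp - up)
  den <- lse3(am, 0, ap)
  resv <- pmax(abs((lse3(b * Jmm + am, 0, b * Jpm + ap) - den) / b - um),
               abs((lse3(b * Jpm + am, 0, b * Jpp + ap) - den) / b - up))
  conv <- resv < sqrt(tol)
  if (!any(conv))
    stop("message stage of the density -> field inversion failed to converge ",
         "(max residual ", format(max(resv)), ")")
  list(mu_plus = -mp + C * up, mu_minus = -mm + C * um,
       u_plus = up, u_minus = um, m_plus = mp, m_minus = mm,
       converged = conv, iterations = it, residual = resv)
}

#' Local thermodynamic stability of a ternary mixture (cavity method)
#'
#' Classifies a composition as mixed (locally stable) or separated
#' (spinodally unstable) from the Hessian of the de-mixing free energy.
#' The fields \eqn{g_\pm = -\mu_\pm} returned by
#' [ternary_fields_from_densities()] are the gradients of the free energy
#' of de-mixing with respect to \eqn{(\varphi_+, \varphi_-)} (the
#' Hamiltonian carries \eqn{+\mu}, so the thermodynamic conjugate of the
#' density is \eqn{-\mu}).  The Hessian
#' \deqn{H = \begin{pmatrix}\partial g_+/\partial\varphi_+ &
#'   \partial g_+/\partial\varphi_- \\ \partial g_-/\partial\varphi_+ &
#'   \partial g_-/\partial\varphi_-\end{pmatrix}}
#' is evaluated by central finite differences, symmetrized, and tested by
#' the Routh-Hurwitz criterion: mixed iff det H > 0 and tr H > 0.  Ties
#' (det H = 0) are labeled separated — the boundary is the spinodal — and
#' the raw det/trace are returned so users can re-threshold.
#'
#' @inheritParams ternary_fields_from_densities
#' @param fd_step central-difference step in volume fraction (default 1e-4);
#'   automatically shrunk per point where the stencil would leave the
#'   simplex, down to `min_step`.
#' @param min_step smallest admissible step before the point is flagged.
#' @return data frame with columns `phi_plus`, `phi_minus`, `mu_plus`,
#'   `mu_minus`, `h11`, `h12`, `h22` (symmetrized), `asym` (the raw
#'   off-diagonal asymmetry before symmetrization, a discretization
#'   diagnostic), `det`, `trace`, `label` (factor mixed/separated),
#'   `converged`.
#' @export
ternary_stability <- function(phi_plus, phi_minus, model, fd_step = 1e-4,
                              min_step = 1e-7, tol = 1e-12, max_iter = 2e4,
                              damping = 0.5) {
  np <- length(phi_plus)
  stopifnot(length(phi_minus) == np)
  # per-point admissible step
  room <- pmin(phi_plus, phi_minus, 1 - phi_plus - phi_minus) / 2
  h <- pmin(fd_step, room * 0.9)
  if (any(h < min_step))
    stop("finite-difference stencil leaves the simplex even at the minimum step; ",
         "point(s) too close to the boundary")
  fld <- function(pp, pm) ternary_fields_from_densities(
    pp, pm, model, tol = tol, max_iter = max_iter, damping = damping)
  fpp <- fld(phi_plus + h, phi_minus); fpm <- fld(phi_plus - h, phi_minus)
  fmp <- fld(phi_plus, phi_minus + h); fmm <- fld(phi_plus, phi_minus - h)
  f0  <- fld(phi_plus, phi_minus)
  # g = -mu is the free-energy gradient
  h11 <- -(fpp$mu_plus  - fpm$mu_plus)  / (2 * h)
  h21 <- -(fpp$mu_minus - fpm$mu_minus) / (2 * h)
  h12 <- -(fmp$mu_plus  - fmm$mu_plus)  / (2 * h)
  h22 <- -(fmp$mu_minus - fmm$mu_minus) / (2 * h)
  hs <- (h12 + h21) / 2                      # Maxwell symmetry
  det <- h11 * h22 - hs^2
  tr <- h11 + h22
  conv <- f0$converged & fpp$converged & fpm$converged & fmp$converged &
    fmm$converged
  label <- factor(ifelse(det > 0 & tr > 0, "mixed", "separated"),
                  levels = c("mixed", "separated"))
  data.frame(phi_plus = phi_plus, phi_minus = phi_minus,
             mu_plus = f0$mu_plus, mu_minus = f0$mu_minus,
             h11 = h11, h12 = hs, h22 = h22, asym = h12 - h21,
             det = det, trace = tr, label = label, converged = conv)
}

#' Ternary phase map over a density grid
#'
#' Applies [ternary_stability()] over a grid of volume fractions,
#' returning the mixed/separated classification at every admissible grid
#' point (those with `phi_plus + phi_minus < 1 - margin`).
#'
#' @param phi_plus_grid,phi_minus_grid grid coordinates.
#' @param model ternary model.
#' @param margin simplex margin excluded near `phi_plus + phi_minus = 1`.
#' @param ... passed to [ternary_stability()].
#' @return data frame of class `phase_diagram` (see [ternary_stability()]).
#' @export
ternary_phase_map <- function(phi_plus_grid, phi_minus_grid, model,
                              margin = 1e-3, ...) {
  g <- expand.grid(phi_plus = phi_plus_grid, phi_minus = phi_minus_grid)
  g <- g[g$phi_plus > 0 & g$phi_minus > 0 &
           g$phi_plus + g$phi_minus < 1 - margin, , drop = FALSE]
  if (!nrow(g)) stop("no admissible grid points inside the simplex")
  out <- ternary_stability(g$phi_plus, g$phi_minus, model, ...)
  class(out) <- c("phase_diagram", "data.frame")
  out
}
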