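# log(1 + exp(x)) without overflow
log1pexp <- function(x) ifelse(x > 35, x + log1p(exp(-x)), log1p(exp(x)))

# RHS of the homogeneous binary message equation
# u = (1/beta) log[(1 + e^{beta(J - mu + K u)}) / (1 + e^{beta(-mu + K u)})]
binary_rhs <- function(u, model) {
  b <- model$beta; J <- model$J[2, 2]; mu <- model$mu[2]; K <- model$K
  (log1pexp(b * (J - mu + K * u)) - log1pexp(b * (-mu + K * u))) / b
}

new_cavity_state <- function(fields) structure(fields, class = "cavity_state")

#' @export
print.cavity_state <- function(x, ...) {
  cat("<cavity_state>")
  if (!is.null(x$u)) cat(" u =", format(x$u))
  if (!is.null(x$u_minus))
    cat(" u- =", format(x$u_minus), " u+ =", format(x$u_plus))
  cat("  (residual", format(x$residual), "in", x$iterations, "iterations)\n")
  invisible(x)
}

#' Homogeneous cavity fixed point, binary solution
#'
#' Solves the self-consistent message equation
#' \deqn{u = \frac{1}{\beta}\log\frac{1 + e^{\beta(J-\mu+Ku)}}{1 + e^{\beta(-\mu+Ku)}}}
#' for a binary solution on a Cayley tree of branching K.  Damped iteration
#' is started from several initial values; because damped iteration can only
#' reach dynamically stable solutions, a dense sign-change scan of
#' `u - RHS(u)` (followed by a bisection polish) supplements it, so all
#' coexisting fixed points are returned.  Multiple fixed points signal the
#' binodal-to-spinodal window.
#'
#' @param model a binary [interaction_model()] (q = 2).
#' @param tol residual tolerance |u - RHS(u)| (default 1e-12).
#' @param max_iter maximum damped-iteration count (default 1e5).
#' @param damping damping factor alpha in `u <- (1-alpha) u + alpha RHS(u)`.
#' @param n_scan number of points in the supplementary sign-change scan.
#' @return list of `cavity_state` objects (fields `u`, `residual`,
#'   `iterations`), ordered by increasing u.  Length 1 when the fixed point
#'   is unique.
#' @export
binary_fixed_point <- function(model, tol = 1e-12, max_iter = 1e5,
                               damping = 0.5, n_scan = 2000) {
  stopifnot(inherits(model, "interaction_model"), model$q == 2L)
  J <- model$J[2, 2]
  lo <- min(0, J); hi <- max(0, J)           # RHS maps R into [min(0,J), max(0,J)]
  roots <- list()
  add_root <- function(u, it) {
    res <- abs(u - binary_rhs(u, model))
    for (r in roots) if (abs(r$u - u) < 1e-8) return(invisible(NULL))
    roots[[length(roots) + 1L]] <<- new_cavity_state(
      list(u = u, residual = res, iterations = it))
  }
  # damped iteration from multiple starts
  for (u0 in unique(c(lo, 0, hi, (lo + hi) / 2))) {
    u <- u0; it <- 0L; converged <- FALSE
    while (it < max_iter) {
      it <- it + 1L
      un <- (1 - damping) * u + damping * binary_rhs(u, model)
      if (abs(un - u) < tol * damping) { u <- un; converged <- TRUE; break }
      u <- un
    }
    if (!converged && abs(u - binary_rhs(u, model)) > tol)
      stop("binary fixed point did not converge: residual ",
           format(abs(u - binary_rhs(u, model))), " after ", max_iter,
           " iterations")
    # polish to the target residual
    g <- function(x) x - binary_rhs(x, model)
    if (abs(g(u)) > tol) {
      br <- c(u - 1e-3, u + 1e-3)
      if (g(br[1]) * g(br[2]) < 0)
        u <- stats::uniroot(g, br, tol = 1e-15)$root
    }
    add_root(u, it)
  }
  # dense scan for any root (including dynamically unstable ones)
  if (hi > lo) {
    g <- function(x) x - binary_rhs(x, model)
    pad <- 1e-9 * (hi - lo)
    xs <- seq(lo - pad, hi + pad, length.out = n_scan)
    gs <- vapply(xs, g, numeric(1))
    sc <- which(gs[-1] * gs[-n_scan] < 0)
    for (i in sc) {
      u <- stats::uniroot(g, c(xs[i], xs[i + 1]), tol = 1e-15)$root
      add_root(u, 0L)
    }
  }
  roots[order(vapply(roots, `[[`, numeric(1), "u"))]
}

#' Solute density from a binary cavity state
#'
#' \deqn{\varphi = \frac{e^{-\beta\mu+\beta(K+1)u}}{1 + e^{-\beta\mu+\beta(K+1)u}}}
#'
#' @param state a `cavity_state` from [binary_fixed_point()] (or any list
#'   with a `u` field).
#' @param model the binary model.
#' @return volume fraction in (0, 1).
#' @export
binary_density <- function(state, model) {
  stopifnot(model$q == 2L)
  u <- if (is.list(state)) state$u else state
  stats::plogis(model$beta * (-model$mu[2] + (model$K + 1) * u))
}

#' Critical point of the binary cavity spinodal
#'
#' Closed form: the spinodal discriminant vanishes at
#' \eqn{\beta J_c = 2\log\frac{K+1}{K-1}} (equivalently
#' \eqn{4\,\mathrm{atanh}(1/K)} through the lattice-gas/Ising mapping), at
#' density 1/2.
#'
#' @param K branching number (K >= 2).
#' @return list with `betaJ_c` and `phi_c`.
#' @export
bp_critical_point <- function(K) {
  if (K < 2) stop("K >= 2 required: a K = 1 chain has no finite-temperature transition")
  list(betaJ_c = 2 * log((K + 1) / (K - 1)), phi_c = 0.5)
}

#' Binary cavity spinodal curve
#'
#' Parametric spinodal of the binary solution on a Cayley tree: for each
#' \eqn{\beta J} the quadratic
#' \eqn{-Kw^2 + bw - Ke^{\beta J} = 0,\; b = Ke^{\beta J}+K-e^{\beta J}+1}
#' yields branches \eqn{w_{1,2}}, converted to densities through
#' \eqn{\varphi/(1-\varphi) = w(w-1)/(e^{\beta J}-w)}.  Below the critical
#' coupling the discriminant is negative and no points are emitted.  Branch
#' admissibility \eqn{1 < w < e^{\beta J}} is enforced so all densities lie
#' in (0, 1).
#'
#' @param betaJ_grid vector of dimensionless couplings beta*J.
#' @param K branching number (K >= 2; K = 1 chains have no transition).
#' @return data frame of class `spinodal_curve` with columns `betaJ`, `phi`,
#'   `branch` ("w1" low-density, "w2" high-density), `w`.
#' @export
binary_spinodal <- function(betaJ_grid, K) {
  if (K < 2) stop("K >= 2 required: a K = 1 chain has no finite-temperature transition")
  out <- list()
  for (x in betaJ_grid) {
    ex <- exp(x)
    b <- K * ex + K - ex + 1
    disc <- b^2 - 4 * K^2 * ex
    if (disc < 0) next
    for (br in 1:2) {
      w <- (b + c(-1, 1)[br] * sqrt(disc)) / (2 * K)
      if (w <= 1 || w >= ex) next
      r <- w * (w - 1) / (ex - w)
      out[[length(out) + 1L]] <- data.frame(
        betaJ = x, phi = r / (1 + r), branch = c("w1", "w2")[br], w = w)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(betaJ = numeric(), phi = numeric(), branch = character(),
               w = numeric())
  class(res) <- c("spinodal_curve", "data.frame")
  res
}

#' Parametric binary state equation (isotherm)
#'
#' The state equation of the binary cavity solution parameterized by the
#' message u:
#' \deqn{\beta\mu(u) = -\log(e^{\beta u}-1) + \beta K u + \log(e^{\beta J}-e^{\beta u})}
#' \deqn{\frac{\varphi}{1-\varphi} = \frac{e^{\beta u}(e^{\beta u}-1)}{e^{\beta J}-e^{\beta u}}}
#' valid on the domain \eqn{0 < u < J} (for J > 0), where both logarithms
#' are defined.  The resulting \eqn{(\varphi, \beta\mu)} curve is the
#' isotherm used in the Maxwell construction.
#'
#' @param u_grid message values inside (0, J).
#' @param model binary model.
#' @return data frame with columns `u`, `phi`, `beta_mu`, sorted by `phi`.
#' @export
binary_state_equation <- function(u_grid, model) {
  stopifnot(model$q == 2L)
  b <- model$beta; J <- model$J[2, 2]; K <- model$K
  if (J <= 0) stop("the isotherm parameterization requires J > 0")
  if (any(u_grid <= 0 | u_grid >= J))
    stop("u must lie strictly inside (0, J) so that e^{beta u} - 1 > 0 and e^{beta J} - e^{beta u} > 0")
  ebu <- exp(b * u_grid)
  beta_mu <- -log(ebu - 1) + b * K * u_grid + log(exp(b * J) - ebu)
  r <- ebu * (ebu - 1) / (exp(b * J) - ebu)
  out <- data.frame(u = u_grid, phi = r / (1 + r), beta_mu = beta_mu)
  out[order(out$phi), , drop = FALSE]
}
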