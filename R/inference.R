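# Inverse modeling: fit ternary couplings to a binary-labeled phase diagram
# (mixed/separated observations on a concentration grid) by differential
# evolution, the fit quality being the fraction of misclassified points.

#' Map bench concentrations to lattice volume fractions
#'
#' Linear mapping \eqn{\varphi_\pm = s_\pm c_\pm} from molar concentrations
#' to lattice volume fractions.  The scales s_plus/s_minus are free fit
#' parameters by default (the correspondence between a real solution and
#' lattice occupancy is not known a priori).  Points mapped onto or beyond
#' the simplex boundary are flagged invalid rather than clipped.
#'
#' @param c_plus,c_minus concentrations (e.g. mM), positive.
#' @param s_plus,s_minus positive scale factors (volume fraction per
#'   concentration unit).
#' @param eps simplex safety margin (default 1e-4).
#' @return list with `phi_plus`, `phi_minus`, `valid` (logical vector).
#' @export
map_concentrations <- function(c_plus, c_minus, s_plus, s_minus,
                               eps = 1e-4) {
  if (!is.finite(s_plus) || !is.finite(s_minus) || s_plus <= 0 || s_minus <= 0)
    stop("mapping scales must be positive")
  if (any(c_plus <= 0) || any(c_minus <= 0))
    stop("concentrations must be positive")
  pp <- s_plus * c_plus; pm <- s_minus * c_minus
  valid <- pp > eps & pm > eps & (pp + pm) < 1 - eps
  list(phi_plus = pp, phi_minus = pm, valid = valid)
}

#' Misclassification loss of a ternary parameter vector
#'
#' For each record of a binary-labeled phase dataset, maps concentrations
#' to volume fractions, computes the cavity-method stability label at the
#' specified branching K, and returns the fraction of mismatches with the
#' observed labels.  Parameter vectors that push any observation outside
#' the composition simplex get infinite loss.  Points where the field
#' solver fails to converge count as mismatches (conservative).
#'
#' @param params named vector with `J_pp`, `J_mm`, `J_pm`, `s_plus`,
#'   `s_minus`.
#' @param dataset data frame with columns `c_plus`, `c_minus`, `label`
#'   (0 = mixed, 1 = separated).
#' @param beta inverse temperature of the model (default 1).
#' @param K branching number (default 5: a 3D cubic lattice).
#' @param fd_step finite-difference step for the stability Hessian.
#' @return scalar error rate in \[0, 1\] (or Inf for invalid mappings).
#' @export
classification_loss <- function(params, dataset, beta = 1, K = 5,
                                fd_step = 1e-4) {
  stopifnot(all(c("c_plus", "c_minus", "label") %in% names(dataset)),
            nrow(dataset) > 0)
  p <- as.list(params)
  mp <- tryCatch(
    map_concentrations(dataset$c_plus, dataset$c_minus, p$s_plus, p$s_minus),
    error = function(e) NULL)
  if (is.null(mp) || !all(mp$valid)) return(Inf)
  model <- ternary_model(J_mm = p$J_mm, J_pp = p$J_pp, J_pm = p$J_pm,
                         beta = beta, K = K)
  st <- tryCatch(
    ternary_stability(mp$phi_plus, mp$phi_minus, model, fd_step = fd_step,
                      tol = 1e-10, max_iter = 5e3),
    error = function(e) NULL)
  if (is.null(st)) return(Inf)
  pred <- as.integer(st$label == "separated")
  pred[!st$converged] <- NA
  mean(pred != dataset$label | is.na(pred))
}

#' Fit specification for the differential-evolution search
#'
#' @param bounds 5 x 2 matrix of lower/upper box bounds, rows named
#'   `J_pp`, `J_mm`, `J_pm`, `s_plus`, `s_minus`.  Defaults: couplings in
#'   \[-5, 5\], scales in \[1e-3, 0.3\].
#' @param constraint de-mixing region constraint: "none", "associative"
#'   (J+- > 0 > J++, J--) or "segregative" (J++, J-- > 0 > J+-),
#'   implemented by tightening the box bounds.
#' @param population DE population size (default 32).
#' @param F_weight differential weight (default 0.7).
#' @param CR crossover rate (default 0.9).
#' @param generations maximum generations (default 200).
#' @param patience early stop after this many stagnant generations
#'   (default 30).
#' @param beta,K model temperature and branching (K = 5: 3D cubic lattice).
#' @param seed RNG seed (passed to [set.seed()] inside [fit_de()]).
#' @return object of class `fit_spec`.
#' @export
fit_spec <- function(bounds = NULL,
                     constraint = c("none", "associative", "segregative"),
                     population = 32, F_weight = 0.7, CR = 0.9,
                     generations = 200, patience = 30, beta = 1, K = 5,
                     seed = NULL) {
  constraint <- match.arg(constraint)
  if (is.null(bounds)) {
    bounds <- rbind(J_pp = c(-5, 5), J_mm = c(-5, 5), J_pm = c(-5, 5),
                    s_plus = c(1e-3, 0.3), s_minus = c(1e-3, 0.3))
  }
  stopifnot(is.matrix(bounds), nrow(bounds) == 5,
            all(is.finite(bounds)), all(bounds[, 1] < bounds[, 2]))
  if (is.null(rownames(bounds)))
    rownames(bounds) <- c("J_pp", "J_mm", "J_pm", "s_plus", "s_minus")
  margin <- 0.05
  if (constraint == "associative") {
    bounds["J_pp", 2] <- -margin; bounds["J_mm", 2] <- -margin
    bounds["J_pm", 1] <- margin
  } else if (constraint == "segregative") {
    bounds["J_pp", 1] <- margin; bounds["J_mm", 1] <- margin
    bounds["J_pm", 2] <- -margin
  }
  structure(list(bounds = bounds, constraint = constraint,
                 population = as.integer(population), F_weight = F_weight,
                 CR = CR, generations = as.integer(generations),
                 patience = as.integer(patience), beta = beta,
                 K = as.integer(K), seed = seed),
            class = "fit_spec")
}

#' Fit a ternary model to a labeled phase diagram by differential evolution
#'
#' Minimizes [classification_loss()] over (J++, J--, J+-, s+, s-) with the
#' classic rand/1/bin differential-evolution scheme under box bounds
#' (mutants outside the box are reflected back in).  Region constraints
#' (associative/segregative) are enforced through the bounds, so no
#' returned parameter vector can violate them.  Runs are reproducible for
#' a fixed seed.
#'
#' @param dataset data frame with `c_plus`, `c_minus`, `label`.
#' @param spec a [fit_spec()].
#' @return object of class `fit_result`: list with `par` (named best
#'   parameters), `error_rate`, `trace` (best loss per generation),
#'   `predictions` (data frame with per-point BP labels at the optimum),
#'   `n_evaluations`, `seed`, `constraint`.
#' @export
fit_de <- function(dataset, spec = fit_spec()) {
  stopifnot(inherits(spec, "fit_spec"), nrow(dataset) > 0)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  lo <- spec$bounds[, 1]; hi <- spec$bounds[, 2]
  npar <- length(lo); NP <- spec$population
  nms <- rownames(spec$bounds)
  loss <- function(x) {
    names(x) <- nms
    classification_loss(x, dataset, beta = spec$beta, K = spec$K)
  }
  pop <- matrix(stats::runif(NP * npar, lo, hi), npar, NP)
  fit <- apply(pop, 2, loss)
  n_eval <- NP
  if (all(!is.finite(fit)))
    stop("all initial candidates are invalid (every mapping violates the ",
         "composition simplex); widen the scale bounds")
  trace <- numeric(0)
  best_prev <- min(fit); stagnant <- 0L
  for (gen in seq_len(spec$generations)) {
    for (i in seq_len(NP)) {
      idx <- sample(seq_len(NP)[-i], 3L)
      v <- pop[, idx[1]] + spec$F_weight * (pop[, idx[2]] - pop[, idx[3]])
      # reflect into the box
      v <- ifelse(v < lo, pmin(hi, 2 * lo - v), v)
      v <- ifelse(v > hi, pmax(lo, 2 * hi - v), v)
      cross <- stats::runif(npar) < spec$CR
      cross[sample.int(npar, 1L)] <- TRUE
      u <- ifelse(cross, v, pop[, i])
      fu <- loss(u); n_eval <- n_eval + 1L
      if (is.finite(fu) && (fu <= fit[i] || !is.finite(fit[i]))) {
        pop[, i] <- u; fit[i] <- fu
      }
    }
    best <- min(fit)
    trace <- c(trace, best)
    if (best < best_prev - 1e-12) { stagnant <- 0L; best_prev <- best }
    else stagnant <- stagnant + 1L
    if (best == 0 || stagnant >= spec$patience) break
  }
  ibest <- which.min(fit)
  par <- pop[, ibest]; names(par) <- nms
  model <- ternary_model(J_mm = par["J_mm"], J_pp = par["J_pp"],
                         J_pm = par["J_pm"], beta = spec$beta, K = spec$K)
  mp <- map_concentrations(dataset$c_plus, dataset$c_minus,
                           par["s_plus"], par["s_minus"])
  st <- ternary_stability(mp$phi_plus, mp$phi_minus, model)
  structure(list(par = par, error_rate = fit[ibest], trace = trace,
                 predictions = data.frame(
                   c_plus = dataset$c_plus, c_minus = dataset$c_minus,
                   phi_plus = mp$phi_plus, phi_minus = mp$phi_minus,
                   observed = dataset$label,
                   predicted = as.integer(st$label == "separated")),
                 n_evaluations = n_eval, seed = spec$seed,
                 constraint = spec$constraint),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> error rate", format(round(x$error_rate, 4)),
      "(constraint:", x$constraint, ")\n  J++ =",
      format(round(x$par["J_pp"], 3)), " J-- =",
      format(round(x$par["J_mm"], 3)), " J+- =",
      format(round(x$par["J_pm"], 3)), "\n  s+ =",
      format(signif(x$par["s_plus"], 4)), " s- =",
      format(signif(x$par["s_minus"], 4)), "\n")
  invisible(x)
}

#' Default concentration grid of the coacervation assay
#'
#' The screening geometry of the nucleotide/poly-lysine experiment: one
#' solute sampled from 0.2 to 2.2 mM in 11 steps, the other from 0.06 to
#' 7.14 mM in 112 steps (an 11 x 112 matrix, 1232 points).
#'
#' @param n_plus,n_minus grid sizes.
#' @return list with `c_plus` and `c_minus` vectors.
#' @export
assay_grid <- function(n_plus = 11, n_minus = 112) {
  list(c_plus = seq(0.2, 2.2, length.out = n_plus),
       c_minus = seq(0.06, 7.14, length.out = n_minus))
}

#' Synthesize a labeled phase dataset from a known model
#'
#' Generates the ground-truth analogue of an experimental phase diagram:
#' cavity-method mixed/separated labels on a concentration grid through a
#' known concentration-to-volume-fraction mapping, with optional
#' independent label flips emulating classification noise.  Used for
#' recovery tests of the inverse-modeling pipeline.
#'
#' @param model ternary [interaction_model()] (the ground truth).
#' @param grid list with `c_plus`, `c_minus` vectors (default
#'   [assay_grid()]).
#' @param s_plus,s_minus true mapping scales (defaults keep the default
#'   grid inside the simplex: 0.1 and 0.05).
#' @param label_noise probability of flipping each label (default 0).
#' @param seed RNG seed for the flips.
#' @return data frame with `c_plus`, `c_minus`, `label` plus attributes
#'   `truth` (named true parameter vector) and `clean_label`.
#' @export
synthesize_dataset <- function(model, grid = assay_grid(), s_plus = 0.1,
                               s_minus = 0.05, label_noise = 0,
                               seed = NULL) {
  stopifnot(inherits(model, "interaction_model"), model$q == 3L)
  if (!is.null(seed)) set.seed(seed)
  g <- expand.grid(c_plus = grid$c_plus, c_minus = grid$c_minus)
  mp <- map_concentrations(g$c_plus, g$c_minus, s_plus, s_minus)
  if (!all(mp$valid))
    stop("the mapping scales push ", sum(!mp$valid),
         " grid points outside the composition simplex")
  st <- ternary_stability(mp$phi_plus, mp$phi_minus, model)
  lab <- as.integer(st$label == "separated")
  clean <- lab
  if (label_noise > 0) {
    flip <- stats::runif(length(lab)) < label_noise
    lab[flip] <- 1L - lab[flip]
  }
  out <- data.frame(c_plus = g$c_plus, c_minus = g$c_minus, label = lab)
  attr(out, "truth") <- c(J_pp = model$J[3, 3], J_mm = model$J[2, 2],
                          J_pm = model$J[2, 3], s_plus = s_plus,
                          s_minus = s_minus)
  attr(out, "clean_label") <- clean
  out
}
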