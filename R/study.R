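# Study-level pipelines combining the simulator, the detector and the
# cavity method: detector calibration on binary annealing runs, and the
# theory-vs-simulation agreement study on ternary phase maps.

#' Calibrate the detector on annealing runs
#'
#' Runs Kawasaki annealing for a set of calibration systems (each a model
#' plus a composition, over several seeds), estimates each run's
#' transition temperature from the specific-heat peak, computes the
#' separation score along each path, and calibrates the score threshold so
#' the detector's firing temperature matches the specific-heat peak
#' ([calibrate_threshold()]).  The calibration set should resemble the
#' systems the detector will classify: mixing binary and ternary systems
#' anchors the threshold on both score scales.
#'
#' @param systems list of calibration systems; each element a list with
#'   `model` (an [interaction_model()]), `phi` (solute volume fractions,
#'   ordered as in [init_lattice()]), `L` (lattice size), and `beta_max`
#'   (annealing ramp end).
#' @param seeds integer seeds; each (system, seed) pair is one run.
#' @param n_iterations,sweeps_per_iteration annealing schedule.
#' @param n_snapshots snapshots classified per run.
#' @param sigma detector kernel width.
#' @param window specific-heat sliding window.
#' @return list with `threshold`, `calibration` (from
#'   [calibrate_threshold()]), `runs` (per-run list with beta/xi series and
#'   `beta_c_heat`), and `summary` (data frame: system, phi, seed,
#'   beta_c_heat, beta_c_xi at the calibrated threshold).
#' @export
calibrate_detector <- function(systems, seeds = 1:2, n_iterations = 500,
                               sweeps_per_iteration = 160,
                               n_snapshots = 250, sigma = 2, window = 50) {
  runs <- list()
  for (si in seq_along(systems)) {
    sys <- systems[[si]]
    for (s in seeds) {
      set.seed(s)
      st <- init_lattice(2, sys$L, sys$phi)
      sch <- anneal_schedule(0, sys$beta_max, n_iterations,
                             sweeps_per_iteration)
      run <- simulate_annealing(st, sys$model, sch,
                                n_snapshots = n_snapshots)
      pk <- specific_heat_peak(run, window = window)
      xi <- vapply(run$snapshots, function(x)
        classify_snapshot(x, sys$model, sigma = sigma)$xi, numeric(1))
      runs[[length(runs) + 1L]] <- list(system = si, phi = sys$phi[1],
                                        seed = s, beta = run$snapshot_betas,
                                        xi = xi, beta_c_heat = pk$beta_c)
    }
  }
  cal <- calibrate_threshold(runs)
  summ <- do.call(rbind, lapply(runs, function(r)
    data.frame(system = r$system, phi = r$phi, seed = r$seed,
               beta_c_heat = r$beta_c_heat,
               beta_c_xi = xi_crossing(r$beta, r$xi, cal$threshold))))
  list(threshold = cal$threshold, calibration = cal, runs = runs,
       summary = summ)
}

#' @rdname calibrate_detector
#' @param phis volume fractions of the binary calibration systems.
#' @param L linear lattice size (2D).
#' @param J solute-solute coupling (default 1).
#' @param beta_max end of the annealing ramp (from 0).
#' @param K branching of the matching theory (only recorded).
#' @param ... passed on to [calibrate_detector()].
#' @export
calibrate_binary_detector <- function(phis, seeds = 1:2, L = 32, J = 1,
                                      beta_max = 4, K = 3, ...) {
  model <- binary_model(J, 0, beta = 1, K = K)
  systems <- lapply(phis, function(p)
    list(model = model, phi = p, L = L, beta_max = beta_max))
  out <- calibrate_detector(systems, seeds = seeds, ...)
  out$summary$phi <- phis[out$summary$system]
  out
}

#' Theory-vs-simulation agreement on ternary phase maps
#'
#' For each interaction parameter set, simulates the ternary lattice model
#' over a grid of compositions (annealing to the model's beta, then
#' equilibrating), classifies each run with the free-energy-profile
#' detector, computes the cavity-method stability label at the same
#' compositions, and reports the pooled label agreement.
#'
#' @param models named list of ternary [interaction_model()] objects.
#' @param phi_grid composition grid (used for both solutes).
#' @param L linear lattice size (2D).
#' @param n_anneal_iterations,anneal_sweeps ramp from beta 0 to the model
#'   beta.
#' @param equil_sweeps equilibration sweeps at the final beta.
#' @param n_snapshots snapshots per run (classified independently,
#'   majority vote).
#' @param sigma detector kernel width.
#' @param threshold separation-score threshold (from
#'   [calibrate_binary_detector()]).
#' @param seed RNG seed.
#' @return list with `points` (data frame: model, phi_plus, phi_minus,
#'   bp_label, sim_label, xi, agree) and `agreement` (pooled fraction).
#' @export
bp_simulation_agreement <- function(models, phi_grid, L = 24,
                                    n_anneal_iterations = 200,
                                    anneal_sweeps = 10, equil_sweeps = 5e4,
                                    n_snapshots = 10, sigma = 2,
                                    threshold = 0.5, seed = 1) {
  rows <- list()
  set.seed(seed)
  for (nm in names(models)) {
    model <- models[[nm]]
    stopifnot(model$q == 3L)
    bp <- ternary_phase_map(phi_grid, phi_grid, model)
    for (i in seq_len(nrow(bp))) {
      pp <- bp$phi_plus[i]; pm <- bp$phi_minus[i]
      st <- init_lattice(2, L, c(pm, pp))
      sch <- anneal_schedule(0, model$beta, n_anneal_iterations,
                             anneal_sweeps, n_tail_sweeps = equil_sweeps)
      run <- simulate_annealing(st, model, sch, n_snapshots = n_snapshots,
                                keep_energies = FALSE)
      cl <- classify_snapshots(run$snapshots, model, sigma = sigma,
                               threshold = threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        model = nm, phi_plus = pp, phi_minus = pm,
        bp_label = as.character(bp$label[i]),
        sim_label = as.character(cl$label), xi = cl$xi_mean,
        agree = as.character(bp$label[i]) == as.character(cl$label))
    }
  }
  points <- do.call(rbind, rows)
  list(points = points, agreement = mean(points$agree))
}
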