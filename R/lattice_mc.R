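#' Initialize a lattice with fixed composition
#'
#' Creates a periodic d-dimensional lattice of side L whose sites are
#' populated uniformly at random with the requested composition; particle
#' counts are the rounded volume fractions, so composition is exact and is
#' conserved by the Kawasaki dynamics.
#'
#' @param d lattice dimension (2 or 3).
#' @param L linear size (L >= 3 for a valid periodic lattice).
#' @param phi volume fractions of the non-solvent components, ordered as
#'   the non-solvent entries of [state_labels()]: a single number for a
#'   binary model, `c(phi_minus, phi_plus)` for a ternary one.
#' @param q number of states (inferred as `length(phi) + 1` by default).
#' @param seed optional seed (calls [set.seed()]).
#' @return object of class `lattice_state`: list with `d`, `L`, `dims`,
#'   `sites` (integer array of internal 0-based states, dim = dims), `q`,
#'   `counts` (per-state site counts, solvent first).
#' @export
init_lattice <- function(d, L, phi, q = length(phi) + 1L, seed = NULL) {
  d <- as.integer(d); L <- as.integer(L)
  if (!d %in% c(2L, 3L)) stop("d must be 2 or 3")
  if (L < 3L) stop("periodic lattices need L >= 3")
  if (!is.null(seed)) set.seed(seed)
  n <- L^d
  counts <- round(phi * n)
  if (sum(counts) > n) stop("requested volume fractions exceed 1")
  fill <- c(n - sum(counts), counts)          # solvent first
  pool <- rep(seq_along(fill) - 1L, times = fill)
  sites <- array(sample(pool), dim = rep(L, d))
  structure(list(d = d, L = L, dims = rep(L, d),
                 sites = sites, q = as.integer(q),
                 counts = as.integer(fill)),
            class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  cat("<lattice_state> ", paste(x$dims, collapse = "x"),
      " periodic lattice, counts (solvent first): ",
      paste(x$counts, collapse = "/"), "\n", sep = "")
  invisible(x)
}

lattice_counts <- function(state) {
  tabulate(as.integer(state$sites) + 1L, nbins = state$q)
}

#' Lattice energy
#'
#' Energy of a lattice configuration under the model Hamiltonian, each
#' nearest-neighbor edge counted once, periodic boundaries.
#'
#' @param state a `lattice_state`.
#' @param model an [interaction_model()] with `q == state$q`.
#' @return scalar energy in kBT.
#' @export
lattice_energy <- function(state, model) {
  stopifnot(inherits(state, "lattice_state"), model$q == state$q)
  lattice_energy_cpp(as.integer(state$sites), state$dims, model$J, model$mu)
}

#' Kawasaki sweeps
#'
#' Runs `sweeps` Kawasaki sweeps at inverse temperature `beta`; one sweep
#' is N = L^d proposed nearest-neighbor pair swaps with Metropolis
#' acceptance min(1, e^{-beta dH}).  Composition is conserved exactly.
#' Proposals that swap equal states are accepted trivially (dH = 0).
#' Randomness comes from R's RNG (use [set.seed()] for reproducibility).
#'
#' @param state a `lattice_state`.
#' @param model matching [interaction_model()].
#' @param beta inverse temperature for the dynamics (overrides `model$beta`
#'   so annealing schedules can vary it); defaults to `model$beta`.
#' @param sweeps number of sweeps.
#' @param record_energy if TRUE, return the (incrementally updated) total
#'   energy after every sweep.
#' @return list with `state` (updated), `energy` (final), `energies`
#'   (per-sweep vector if requested), `acceptance` (accepted/proposed).
#' @export
kawasaki_sweep <- function(state, model, beta = model$beta, sweeps = 1,
                           record_energy = FALSE) {
  stopifnot(inherits(state, "lattice_state"), model$q == state$q)
  res <- kawasaki_run_cpp(as.integer(state$sites), state$dims, model$J,
                          model$mu, beta, as.integer(sweeps),
                          isTRUE(record_energy))
  state$sites <- array(res$state, dim = state$dims)
  list(state = state, energy = res$energy, energies = res$energies,
       acceptance = res$accepted / res$proposed)
}

#' Annealing schedule
#'
#' Describes a simulated-annealing protocol: `n_iterations` inverse
#' temperatures spaced linearly from `beta_start` to `beta_end`; at each
#' one the lattice is driven for `sweeps_per_iteration` sweeps (one sweep =
#' L^d proposed swaps), the first `discard_fraction` of which are treated
#' as equilibration and excluded from the energy statistics.
#'
#' Presets reproduce the two study protocols at full scale:
#' * `"binary-ramp"`: beta 0 -> 8 linearly over 1e4 iterations, 1e3 sweeps
#'   each;
#' * `"ternary-sampling"`: beta 0 -> 1 over 1e4 iterations of 1 sweep, then a
#'   long constant-beta tail (1e6 sweeps at beta_end, snapshots collected
#'   over a further 1e6) — realized here as `n_tail_sweeps`;
#' * `"quick"`: a scaled-down schedule for tests and desk studies.
#'
#' @param beta_start,beta_end inverse temperature ramp (beta nondecreasing).
#' @param n_iterations number of annealing steps.
#' @param sweeps_per_iteration sweeps at each temperature.
#' @param discard_fraction fraction of each iteration's sweeps treated as
#'   equilibration (default 0.5).
#' @param n_tail_sweeps extra constant-beta sweeps appended after the ramp.
#' @return object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(beta_start, beta_end, n_iterations,
                            sweeps_per_iteration, discard_fraction = 0.5,
                            n_tail_sweeps = 0) {
  stopifnot(beta_start >= 0, beta_end >= beta_start, n_iterations >= 1,
            sweeps_per_iteration >= 1)
  structure(list(beta_start = beta_start, beta_end = beta_end,
                 n_iterations = as.integer(n_iterations),
                 sweeps_per_iteration = as.integer(sweeps_per_iteration),
                 discard_fraction = discard_fraction,
                 n_tail_sweeps = as.integer(n_tail_sweeps)),
            class = "anneal_schedule")
}

#' @rdname anneal_schedule
#' @param preset one of "binary-ramp", "ternary-sampling", "quick".
#' @param scale divide iteration/sweep counts by this factor (>= 1) for
#'   scaled-down runs.
#' @export
preset_schedule <- function(preset = c("binary-ramp", "ternary-sampling", "quick"),
                            scale = 1) {
  preset <- match.arg(preset)
  sc <- function(x) max(1L, as.integer(round(x / scale)))
  switch(preset,
    "binary-ramp" = anneal_schedule(0, 8, sc(1e4), sc(1e3)),
    "ternary-sampling" = anneal_schedule(0, 1, sc(1e4), 1,
                                     n_tail_sweeps = sc(2e6)),
    "quick" = anneal_schedule(0, 2, sc(200), sc(20)))
}

#' Simulated annealing of the lattice model
#'
#' Drives a lattice through an annealing schedule, recording per-iteration
#' energy statistics and (optionally) snapshots.  The specific heat per
#' site is computed from the energy fluctuations within each iteration,
#' \eqn{C(\beta) = \beta^2 \mathrm{Var}(E) / N}.
#'
#' @param state initial `lattice_state`.
#' @param model matching model.
#' @param schedule an [anneal_schedule()].
#' @param n_snapshots number of snapshots to collect, uniformly spaced over
#'   the schedule (over the constant-beta tail if the schedule has one).
#' @param keep_energies retain the raw post-equilibration energy samples of
#'   every iteration (needed by the pooled sliding-window specific-heat
#'   estimator of [specific_heat_peak()]; default TRUE).
#' @return list of class `anneal_run` with `observables` (data frame:
#'   iteration, beta, energy_mean, energy_var, specific_heat, acceptance),
#'   `energy_samples` (matrix, kept sweeps x iterations, if requested),
#'   `snapshots` (list of `lattice_state`), `snapshot_betas`, `final_state`,
#'   and `energy_check` (|incremental - fresh| energy discrepancy at the
#'   end).
#' @export
simulate_annealing <- function(state, model, schedule, n_snapshots = 0,
                               keep_energies = TRUE) {
  stopifnot(inherits(schedule, "anneal_schedule"))
  n_it <- schedule$n_iterations
  betas <- if (n_it == 1L) schedule$beta_end else
    seq(schedule$beta_start, schedule$beta_end, length.out = n_it)
  N <- prod(state$dims)
  obs <- data.frame(iteration = seq_len(n_it), beta = betas,
                    energy_mean = NA_real_, energy_var = NA_real_,
                    specific_heat = NA_real_, acceptance = NA_real_)
  tail_snaps <- schedule$n_tail_sweeps > 0L
  snap_iters <- if (n_snapshots > 0 && !tail_snaps)
    unique(round(seq(1, n_it, length.out = n_snapshots))) else integer()
  snapshots <- list(); snapshot_betas <- numeric()
  keep_from <- max(1L, ceiling(schedule$sweeps_per_iteration *
                                 schedule$discard_fraction) + 1L)
  n_keep <- schedule$sweeps_per_iteration - keep_from + 1L
  esamp <- if (keep_energies) matrix(NA_real_, n_keep, n_it) else NULL
  for (it in seq_len(n_it)) {
    res <- kawasaki_sweep(state, model, beta = betas[it],
                          sweeps = schedule$sweeps_per_iteration,
                          record_energy = TRUE)
    state <- res$state
    e <- res$energies[keep_from:length(res$energies)]
    if (keep_energies) esamp[, it] <- e
    obs$energy_mean[it] <- mean(e)
    obs$energy_var[it] <- if (length(e) > 1) stats::var(e) else 0
    obs$specific_heat[it] <- betas[it]^2 * obs$energy_var[it] / N
    obs$acceptance[it] <- res$acceptance
    if (it %in% snap_iters) {
      snapshots[[length(snapshots) + 1L]] <- state
      snapshot_betas <- c(snapshot_betas, betas[it])
    }
  }
  if (tail_snaps) {
    # constant-beta tail: equilibrate half, sample snapshots from the rest
    half <- schedule$n_tail_sweeps %/% 2L
    res <- kawasaki_sweep(state, model, beta = schedule$beta_end,
                          sweeps = max(1L, half))
    state <- res$state
    n_snap <- max(n_snapshots, 1L)
    chunk <- max(1L, (schedule$n_tail_sweeps - half) %/% n_snap)
    for (s in seq_len(n_snap)) {
      res <- kawasaki_sweep(state, model, beta = schedule$beta_end,
                            sweeps = chunk)
      state <- res$state
      if (n_snapshots > 0) {
        snapshots[[length(snapshots) + 1L]] <- state
        snapshot_betas <- c(snapshot_betas, schedule$beta_end)
      }
    }
  }
  final_res <- kawasaki_sweep(state, model, beta = schedule$beta_end,
                              sweeps = 1, record_energy = TRUE)
  echeck <- abs(final_res$energy - lattice_energy(final_res$state, model))
  structure(list(observables = obs, energy_samples = esamp,
                 snapshots = snapshots, snapshot_betas = snapshot_betas,
                 final_state = final_res$state, energy_check = echeck,
                 n_sites = N),
            class = "anneal_run")
}

#' Critical point from the specific-heat peak
#'
#' Locates the peak of the specific heat \eqn{C(\beta) = \beta^2
#' \mathrm{Var}(E)/N} along an annealing path.  When the run retains its
#' raw energy samples, the variance at each temperature is estimated from a
#' sliding window of iterations (default 25 on each side of the center,
#' i.e. ~50 iterations) pooled together after removing a linear trend —
#' this captures the slow critical fluctuations that a single iteration is
#' too short to sample.  Without raw samples the per-iteration fluctuation
#' estimates are window-smoothed instead.  The peak width is the full width
#' at half prominence.  A series with no interior peak (flat energy, or
#' maximal C at the boundary) is flagged with `peak_found = FALSE`.
#'
#' @param series an `anneal_run` from [simulate_annealing()], or its
#'   `observables` data frame (columns `beta`, `specific_heat`).
#' @param window sliding-window length in iterations.
#' @return list with `beta_c`, `c_max`, `width`, `peak_found`, and the
#'   windowed series (`beta`, `smoothed`).
#' @export
specific_heat_peak <- function(series, window = 50) {
  esamp <- NULL; N <- NULL
  if (inherits(series, "anneal_run")) {
    esamp <- series$energy_samples; N <- series$n_sites
    series <- series$observables
  }
  stopifnot(all(c("beta", "specific_heat") %in% names(series)))
  n <- nrow(series)
  w <- max(1L, min(as.integer(window), n %/% 4L * 2L + 1L))
  if (w %% 2L == 0L) w <- w + 1L
  if (!is.null(esamp) && nrow(esamp) * w >= 8) {
    # pooled, linearly detrended variance over the window
    hw <- w %/% 2L
    cs <- rep(NA_real_, n)
    for (t in seq.int(hw + 1L, n - hw)) {
      e <- as.vector(esamp[, (t - hw):(t + hw)])
      x <- seq_along(e)
      r <- stats::lm.fit(cbind(1, x), e)$residuals
      cs[t] <- series$beta[t]^2 * sum(r^2) / (length(r) - 2) / N
    }
  } else {
    cs <- as.numeric(stats::filter(series$specific_heat, rep(1 / w, w),
                                   sides = 2))
  }
  ok <- which(!is.na(cs))
  if (!length(ok))
    return(list(beta_c = NA_real_, c_max = NA_real_, width = NA_real_,
                peak_found = FALSE, smoothed = cs))
  i_max <- ok[which.max(cs[ok])]
  c_max <- cs[i_max]
  spread <- c_max - min(cs[ok])
  interior <- i_max > min(ok) && i_max < max(ok)
  found <- interior && is.finite(spread) &&
    spread > 0.05 * max(abs(c_max), 1e-12)
  width <- NA_real_
  if (found) {
    half <- c_max - spread / 2
    lo <- i_max; while (lo > min(ok) && cs[lo] > half) lo <- lo - 1L
    hi <- i_max; while (hi < max(ok) && cs[hi] > half) hi <- hi + 1L
    width <- series$beta[hi] - series$beta[lo]
  }
  list(beta_c = if (found) series$beta[i_max] else NA_real_,
       c_max = c_max, width = width, peak_found = found,
       beta = series$beta, smoothed = cs)
}
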