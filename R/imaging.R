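# Automated phase-separation detection from lattice snapshots:
# periodic Gaussian density fields -> local-density histogram -> free-energy
# profile F(rho) = -log P(rho) -> minima counting -> separation score xi.

# 1D Gaussian kernel of total length L, truncated at `trunc` sigma, wrapped
# onto the periodic lattice and renormalized to sum 1.
gauss_kernel_1d <- function(L, sigma, trunc = 4) {
  r <- max(1L, min(floor(trunc * sigma), 10L * L))
  off <- seq.int(-r, r)
  k <- exp(-off^2 / (2 * sigma^2))
  kk <- numeric(L)
  pos <- (off %% L) + 1L
  for (i in seq_along(off)) kk[pos[i]] <- kk[pos[i]] + k[i]
  kk / sum(kk)
}

#' Smoothed local density of one component
#'
#' Convolves the indicator field of a component with an isotropic Gaussian
#' kernel under periodic boundary conditions (exact circular convolution
#' via the FFT; the kernel is truncated at 4 sigma and renormalized, so the
#' field mean equals the component's volume fraction to machine precision).
#'
#' @param state a `lattice_state`.
#' @param component user-facing state label of the component (1 for a
#'   binary model; -1 or +1 for a ternary one).
#' @param model the model (used only to map the label; optional if
#'   `component` is given as an internal 0-based state directly via
#'   `internal = TRUE`).
#' @param sigma kernel width in lattice units (default 3).
#' @param internal if TRUE, `component` is an internal 0-based state index.
#' @return object of class `density_field`: list with `field` (array in
#'   \[0,1\], same dim as lattice), `sigma`, `component`, `phi` (spatial
#'   mean).
#' @export
local_density <- function(state, component, model = NULL, sigma = 3,
                          internal = FALSE) {
  stopifnot(inherits(state, "lattice_state"))
  code <- if (internal) as.integer(component) else {
    labels <- if (!is.null(model)) model$labels else state_labels(state$q)
    m <- match(component, labels)
    if (is.na(m)) stop("unknown component label: ", component)
    m - 1L
  }
  ind <- array(as.numeric(state$sites == code), dim = state$dims)
  d <- length(state$dims); L <- state$dims[1]
  k1 <- gauss_kernel_1d(L, sigma)
  kern <- k1
  if (d >= 2) kern <- outer(kern, k1)
  if (d == 3) kern <- outer(kern, k1)
  f <- Re(stats::fft(stats::fft(ind) * stats::fft(kern), inverse = TRUE)) /
    length(ind)
  f <- pmin(pmax(f, 0), 1)
  structure(list(field = array(f, dim = state$dims), sigma = sigma,
                 component = component, phi = mean(f)),
            class = "density_field")
}

#' Free-energy profile of a density field
#'
#' Histograms the local-density field and converts the distribution to a
#' free-energy profile through the Gibbs relation
#' \eqn{F(\rho) = -\log P(\rho)} (in kBT), on the occupied bins.  The
#' profile is mildly smoothed (moving average) and its local minima are
#' located with a topographic prominence filter: the deepest minimum is
#' always reported; secondary minima are kept when their prominence (the
#' barrier height separating them from a deeper minimum) is at least
#' `min_prominence` kBT.
#'
#' @param field a `density_field` (or a bare numeric array of densities).
#' @param n_bins number of histogram bins on \[0, 1\] (default 64).
#' @param smooth moving-average width in bins (default 3; 1 disables).
#' @param min_prominence prominence threshold in kBT for secondary minima
#'   (default 0.25).
#' @return object of class `free_energy_profile`: list with `rho` (bin
#'   centers of occupied bins), `F` (profile values), `minima` (data frame:
#'   rho, value, prominence), `n_minima` (count passing the prominence
#'   filter), `delta` (largest secondary-minimum prominence, 0 if
#'   unimodal).
#' @export
free_energy_profile <- function(field, n_bins = 64, smooth = 3,
                                min_prominence = 0.25) {
  x <- if (inherits(field, "density_field")) field$field else field
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  cnt <- tabulate(pmin(pmax(findInterval(as.vector(x), breaks,
                                         rightmost.closed = TRUE), 1L),
                       n_bins), nbins = n_bins)
  occ <- which(cnt > 0)
  P <- cnt[occ] / sum(cnt)
  Fv <- -log(P)
  centers <- (breaks[-1] + breaks[-length(breaks)])[occ] / 2
  if (smooth > 1 && length(Fv) >= smooth) {
    w <- as.integer(smooth)
    sm <- stats::filter(Fv, rep(1 / w, w), sides = 2)
    # keep the ends unsmoothed rather than dropping them
    Fv <- ifelse(is.na(sm), Fv, as.numeric(sm))
  }
  mins <- profile_minima(centers, Fv)
  keep <- mins$prominence >= min_prominence |
    mins$value == min(mins$value)
  mins <- mins[keep, , drop = FALSE]
  delta <- if (nrow(mins) >= 2) {
    ord <- order(mins$value)
    max(mins$prominence[ord[-1]])
  } else 0
  structure(list(rho = centers, F = Fv, minima = mins,
                 n_minima = nrow(mins), delta = delta),
            class = "free_energy_profile")
}

# local minima (endpoints included) of a 1D profile with topographic
# prominence: for each minimum, the lowest barrier to any deeper minimum;
# the global minimum gets max(F) - value.
profile_minima <- function(x, y) {
  n <- length(y)
  if (n == 1L)
    return(data.frame(rho = x, value = y, prominence = 0))
  is_min <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) y[i] <= y[i - 1] else TRUE
    right <- if (i < n) y[i] <= y[i + 1] else TRUE
    strict <- (i > 1 && y[i] < y[i - 1]) || (i < n && y[i] < y[i + 1]) ||
      n == 1
    left && right && strict
  }, logical(1))
  # plateaus: keep the first index of each run of equal minimal values
  idx <- which(is_min)
  if (length(idx) > 1) {
    drop <- idx[-1][y[idx[-1]] == y[idx[-length(idx)]] &
                      diff(idx) == 1]
    idx <- setdiff(idx, drop)
  }
  if (!length(idx)) idx <- which.min(y)
  prom <- vapply(idx, function(i) {
    deeper <- idx[y[idx] < y[i]]
    if (!length(deeper)) return(max(y) - y[i])
    min(vapply(deeper, function(j) {
      rng <- if (j < i) j:i else i:j
      max(y[rng]) - y[i]
    }, numeric(1)))
  }, numeric(1))
  data.frame(rho = x[idx], value = y[idx], prominence = prom)
}

#' Separation score and phase call for a set of component profiles
#'
#' Combines the free-energy profiles of all solute components into a
#' continuous separation score
#' \deqn{\xi = 1 - e^{-\Delta/\Delta_0}, \qquad \Delta =
#'   \max_c \Delta_c,}
#' where \eqn{\Delta_c} is the largest secondary-minimum prominence (kBT)
#' of component c's profile (0 for a unimodal profile, so \eqn{\xi = 0}
#' when every component is well mixed; \eqn{\xi \to 1} for deeply bimodal
#' profiles).  The system is called separated when any component's profile
#' is bimodal strongly enough that \eqn{\xi} exceeds the threshold —
#' associative de-mixing condenses both solutes together while segregative
#' de-mixing condenses them singly, and both yield at least one bimodal
#' component.
#'
#' @param profiles a `free_energy_profile` or list of them (one per
#'   component).
#' @param threshold separation-score threshold for the binary call
#'   (default 0.5; calibrate with [calibrate_threshold()]).
#' @param delta0 prominence scale in kBT (default 1).
#' @return object of class `phase_call`: list with `xi`, `label` (factor
#'   mixed/separated), `delta`, `per_component` (data frame: n_minima,
#'   delta, xi), `threshold`.
#' @export
separation_score <- function(profiles, threshold = 0.5, delta0 = 1) {
  if (inherits(profiles, "free_energy_profile")) profiles <- list(profiles)
  deltas <- vapply(profiles, `[[`, numeric(1), "delta")
  nmin <- vapply(profiles, `[[`, numeric(1), "n_minima")
  delta <- max(deltas)
  xi <- 1 - exp(-delta / delta0)
  label <- factor(if (xi >= threshold) "separated" else "mixed",
                  levels = c("mixed", "separated"))
  structure(list(xi = xi, label = label, delta = delta,
                 per_component = data.frame(
                   n_minima = nmin, delta = deltas,
                   xi = 1 - exp(-deltas / delta0)),
                 threshold = threshold),
            class = "phase_call")
}

#' @export
print.phase_call <- function(x, ...) {
  cat("<phase_call> xi =", format(round(x$xi, 4)), "->",
      as.character(x$label), "(threshold", format(x$threshold), ")\n")
  invisible(x)
}

#' Classify a lattice snapshot
#'
#' Full detector pipeline for one snapshot: Gaussian local densities of
#' every solute component, free-energy profiles, separation score.  For
#' multi-solute systems the total solute occupancy (any non-solvent state)
#' is scanned as an additional channel by default: associative de-mixing
#' condenses all solutes into one dense phase, so the total density is its
#' natural order parameter and shows far deeper bimodality than either
#' component alone, while for a well-mixed system the total field is as
#' unimodal as the components.
#'
#' @param state a `lattice_state`.
#' @param model the matching model (its labels define the solute
#'   components).
#' @param sigma kernel width (lattice units).
#' @param threshold,delta0 passed to [separation_score()].
#' @param n_bins,smooth,min_prominence passed to [free_energy_profile()].
#' @param include_total add the total-occupancy channel (default for
#'   models with more than one solute).
#' @return a `phase_call` (the per-component table has one row per solute
#'   plus, when enabled, a final row for the total channel).
#' @export
classify_snapshot <- function(state, model, sigma = 3, threshold = 0.5,
                              delta0 = 1, n_bins = 64, smooth = 3,
                              min_prominence = 0.25,
                              include_total = model$q > 2L) {
  solutes <- model$labels[-1]
  prof1 <- function(ind) {
    f <- local_density(ind$state, ind$comp, ind$model, sigma = sigma,
                       internal = ind$internal)
    free_energy_profile(f, n_bins = n_bins, smooth = smooth,
                        min_prominence = min_prominence)
  }
  profs <- lapply(solutes, function(s)
    prof1(list(state = state, comp = s, model = model, internal = FALSE)))
  if (include_total) {
    tot <- state
    tot$sites <- array(as.integer(state$sites != 0L), dim = state$dims)
    tot$q <- 2L
    profs[[length(profs) + 1L]] <- prof1(
      list(state = tot, comp = 1L, model = NULL, internal = TRUE))
  }
  separation_score(profs, threshold = threshold, delta0 = delta0)
}

#' Classify a set of snapshots from one run
#'
#' Processes each snapshot independently and combines them: the run-level
#' score is the mean per-snapshot xi and the run-level label is the
#' majority vote of per-snapshot labels.
#'
#' @param snapshots list of `lattice_state` snapshots.
#' @inheritParams classify_snapshot
#' @return list with `xi_mean`, `label` (majority), `calls` (per-snapshot
#'   list), `xi` (per-snapshot vector).
#' @export
classify_snapshots <- function(snapshots, model, sigma = 3, threshold = 0.5,
                               delta0 = 1, ...) {
  calls <- lapply(snapshots, classify_snapshot, model = model, sigma = sigma,
                  threshold = threshold, delta0 = delta0, ...)
  xi <- vapply(calls, `[[`, numeric(1), "xi")
  sep <- mean(vapply(calls, function(cl)
    cl$label == "separated", logical(1)))
  list(xi_mean = mean(xi),
       label = factor(if (sep > 0.5) "separated" else "mixed",
                      levels = c("mixed", "separated")),
       vote_separated = sep, calls = calls, xi = xi)
}

#' First threshold crossing of the separation score along a run
#'
#' Returns the inverse temperature at which the (lightly smoothed)
#' separation score first reaches the threshold, linearly interpolated
#' between iterations; NA if the score never crosses.
#'
#' @param beta,xi equal-length vectors along the annealing path.
#' @param threshold score threshold.
#' @param smooth running-median window (odd; 1 disables).
#' @return scalar beta of the first crossing, or NA.
#' @export
xi_crossing <- function(beta, xi, threshold, smooth = 5) {
  stopifnot(length(beta) == length(xi))
  if (smooth > 1 && length(xi) >= smooth)
    xi <- stats::runmed(xi, k = smooth %/% 2L * 2L + 1L)
  above <- which(xi >= threshold)
  if (!length(above)) return(NA_real_)
  i <- above[1]
  if (i == 1L) return(beta[1])
  beta[i - 1] + (beta[i] - beta[i - 1]) *
    (threshold - xi[i - 1]) / (xi[i] - xi[i - 1])
}

#' Calibrate the separation-score threshold against the specific heat
#'
#' Chooses the xi threshold so that the temperature at which the detector
#' first fires on an annealing path agrees best with the specific-heat
#' peak temperature, across a set of calibration runs: minimizes the mean
#' |beta_xi(threshold) - beta_C| over the runs (runs where the score never
#' crosses are penalized with the end-of-path beta).
#'
#' @param runs list of calibration runs, each a list with `beta` (vector),
#'   `xi` (vector), `beta_c_heat` (scalar from [specific_heat_peak()]).
#' @param thresholds candidate grid (default 0.02..0.98).
#' @return list with `threshold` (best), `mean_abs_err`, and the full
#'   `table` (threshold, mean_abs_err).
#' @export
calibrate_threshold <- function(runs,
                                thresholds = seq(0.02, 0.98, by = 0.02)) {
  stopifnot(length(runs) >= 1)
  has_peak <- vapply(runs, function(r) is.finite(r$beta_c_heat), logical(1))
  if (!all(has_peak)) {
    warning(sum(!has_peak), " calibration run(s) without a specific-heat ",
            "peak dropped")
    runs <- runs[has_peak]
    if (!length(runs)) stop("no calibration run has a specific-heat peak")
  }
  err <- vapply(thresholds, function(t) {
    es <- vapply(runs, function(r) {
      bx <- xi_crossing(r$beta, r$xi, t)
      if (is.na(bx)) bx <- max(r$beta)
      abs(bx - r$beta_c_heat)
    }, numeric(1))
    mean(es)
  }, numeric(1))
  best <- which.min(err)
  list(threshold = thresholds[best], mean_abs_err = err[best],
       table = data.frame(threshold = thresholds, mean_abs_err = err))
}
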