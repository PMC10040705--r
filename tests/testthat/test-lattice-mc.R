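test_that("lattice initialization gives exact requested composition", {
  st <- init_lattice(2, 10, 0.5, seed = 1)
  expect_equal(st$counts, c(50L, 50L))
  expect_equal(lattice_counts(st), c(50L, 50L))
  st3 <- init_lattice(2, 10, c(0.2, 0.2), seed = 1)
  expect_equal(st3$counts, c(60L, 20L, 20L))
  # different seeds: same composition, different arrangement
  a <- init_lattice(2, 8, 0.3, seed = 1)
  b <- init_lattice(2, 8, 0.3, seed = 2)
  expect_equal(a$counts, b$counts)
  expect_false(identical(a$sites, b$sites))
  expect_error(init_lattice(2, 2, 0.5), "L >= 3")
  expect_error(init_lattice(2, 10, c(0.7, 0.7)), "exceed")
})

test_that("lattice energy matches the graph-based evaluator", {
  set.seed(3)
  m <- ternary_model(-1, 2, 0.5, 0.3, -0.2)
  st <- init_lattice(2, 5, c(0.3, 0.3))
  g <- lattice_graph(2, 5)
  labels <- state_labels(3)[as.integer(st$sites) + 1L]
  expect_equal(lattice_energy(st, m), energy(g, labels, m),
               tolerance = 1e-12)
  # 3D as well
  st3 <- init_lattice(3, 4, c(0.2, 0.2))
  g3 <- lattice_graph(3, 4)
  labels3 <- state_labels(3)[as.integer(st3$sites) + 1L]
  expect_equal(lattice_energy(st3, m), energy(g3, labels3, m),
               tolerance = 1e-12)
})

test_that("Kawasaki dynamics conserves composition and tracks energy", {
  set.seed(4)
  m <- binary_model(1, 0)
  st <- init_lattice(2, 12, 0.4)
  res <- kawasaki_sweep(st, m, beta = 1.5, sweeps = 500,
                        record_energy = TRUE)
  expect_equal(lattice_counts(res$state), st$counts)
  # incremental energy bookkeeping agrees with a fresh evaluation
  expect_lt(abs(res$energy - lattice_energy(res$state, m)), 1e-9)
  expect_equal(res$energies[500], res$energy)
  # infinite temperature accepts every proposal
  res0 <- kawasaki_sweep(st, m, beta = 0, sweeps = 5)
  expect_equal(res0$acceptance, 1)
  # ternary conservation
  mt <- demixing_presets()$associative
  st3 <- init_lattice(2, 10, c(0.25, 0.25))
  res3 <- kawasaki_sweep(st3, mt, beta = 1, sweeps = 300)
  expect_equal(lattice_counts(res3$state), st3$counts)
})

test_that("long-run swap dynamics samples the canonical ensemble (3x3)", {
  # 4 particles on 9 sites: 126 configurations, exact Boltzmann weights
  set.seed(9)
  m <- binary_model(1, 0)
  g <- lattice_graph(2, 3)
  conf <- utils::combn(9, 4)
  key <- apply(conf, 2, paste, collapse = ",")
  w <- apply(conf, 2, function(occ) {
    s <- integer(9); s[occ] <- 1L
    exp(-1 * energy(g, s, m))
  })
  p <- w / sum(w)
  st <- init_lattice(2, 3, 4 / 9)
  counts <- stats::setNames(numeric(length(key)), key)
  n_samp <- 6000
  for (i in seq_len(n_samp)) {
    r <- kawasaki_sweep(st, m, beta = 1, sweeps = 5)
    st <- r$state
    k <- paste(which(as.integer(st$sites) == 1L), collapse = ",")
    counts[k] <- counts[k] + 1
  }
  # group by energy level to keep expected counts large, compare within
  # 3 sigma multinomial bounds
  e_lev <- round(apply(conf, 2, function(occ) {
    s <- integer(9); s[occ] <- 1L
    energy(g, s, m)
  }), 9)
  for (lev in unique(e_lev)) {
    pe <- sum(p[e_lev == lev])
    oe <- sum(counts[e_lev == lev])
    expect_lt(abs(oe - n_samp * pe), 3 * sqrt(n_samp * pe * (1 - pe)) + 3)
  }
})

test_that("annealing runs equilibrate and keep honest bookkeeping", {
  set.seed(6)
  m <- binary_model(1, 0)
  st <- init_lattice(2, 16, 0.5)
  # constant-beta schedule is a plain equilibrium run with a plateau
  sch <- anneal_schedule(0.5, 0.5, 40, 40)
  run <- simulate_annealing(st, m, sch)
  expect_equal(nrow(run$observables), 40)
  expect_lt(run$energy_check, 1e-9)
  e <- run$observables$energy_mean
  q4 <- e[(length(e) - 9):length(e)]
  fit <- stats::lm(q4 ~ seq_along(q4))
  slope <- summary(fit)$coefficients[2, ]
  expect_lt(abs(slope["Estimate"]), slope["Std. Error"] * 3 + 0.05)
  # scaled-down preset completes and emits the requested snapshots
  sch2 <- preset_schedule("quick", scale = 4)
  run2 <- simulate_annealing(init_lattice(2, 12, 0.5), m, sch2,
                             n_snapshots = 5)
  expect_length(run2$snapshots, 5)
  expect_equal(lattice_counts(run2$final_state),
               c(72L, 72L))
  # ternary preset shape (heavily scaled)
  sch3 <- preset_schedule("ternary-sampling", scale = 2000)
  expect_gt(sch3$n_tail_sweeps, 0)
})

test_that("specific-heat peak is located or flagged", {
  # constant-energy series has no peak
  flat <- data.frame(beta = seq(0, 2, length.out = 100),
                     specific_heat = rep(0, 100))
  pk <- specific_heat_peak(flat, window = 10)
  expect_false(pk$peak_found)
  # a clear synthetic bump is found at the right place
  beta <- seq(0, 3, length.out = 200)
  bump <- data.frame(beta = beta,
                     specific_heat = exp(-(beta - 1.8)^2 / 0.05))
  pk2 <- specific_heat_peak(bump, window = 5)
  expect_true(pk2$peak_found)
  expect_equal(pk2$beta_c, 1.8, tolerance = 0.05)
  expect_true(is.finite(pk2$width))
  # a short real run produces a peak on the annealing path
  set.seed(8)
  m <- binary_model(1, 0)
  st <- init_lattice(2, 16, 0.5)
  run <- simulate_annealing(st, m, anneal_schedule(0, 3, 150, 60))
  pk3 <- specific_heat_peak(run, window = 30)
  expect_true(pk3$peak_found)
  expect_gt(pk3$beta_c, 1)
  expect_lt(pk3$beta_c, 2.8)
})
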