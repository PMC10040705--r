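test_that("local density is a mean-preserving periodic smoother", {
  set.seed(12)
  st <- init_lattice(2, 32, 0.37)
  f <- local_density(st, 1, sigma = 3)
  expect_equal(f$phi, mean(st$sites == 1L), tolerance = 1e-9)
  expect_true(all(f$field >= 0 & f$field <= 1))
  # single particle: maximal at its own site, symmetric under reflection
  st1 <- init_lattice(2, 16, 1 / 256)
  st1$sites <- array(0L, c(16, 16)); st1$sites[1, 1] <- 1L
  f1 <- local_density(st1, 1, sigma = 2)
  expect_equal(which.max(f1$field), 1L)
  expect_equal(f1$field[2, 1], f1$field[16, 1], tolerance = 1e-12)
  expect_equal(f1$field[1, 5], f1$field[1, 13], tolerance = 1e-12)
  # two-block configuration: saturated deep inside each block
  stb <- two_block_state(64)
  fb <- local_density(stb, 1, sigma = 2)
  expect_lt(abs(fb$field[16, 32] - 1), 1e-3)   # > 4 sigma from interface
  expect_lt(abs(fb$field[48, 32] - 0), 1e-3)
  # translation invariance of the downstream score
  sh <- stb
  sh$sites <- stb$sites[c(11:64, 1:10), ]
  xi_a <- separation_score(free_energy_profile(fb))$xi
  xi_b <- separation_score(free_energy_profile(
    local_density(sh, 1, sigma = 2)))$xi
  expect_equal(xi_a, xi_b, tolerance = 1e-12)
})

test_that("free-energy profiles count minima correctly", {
  set.seed(13)
  # uniform snapshot: unimodal near its density
  stu <- init_lattice(2, 64, 0.2)
  pu <- free_energy_profile(local_density(stu, 1, sigma = 3))
  expect_equal(pu$n_minima, 1)
  expect_equal(pu$minima$rho[which.min(pu$minima$value)], 0.2,
               tolerance = 0.05)
  # two-block snapshot: two minima near 0 and 1
  pb <- free_energy_profile(local_density(two_block_state(64), 1, sigma = 2))
  expect_equal(pb$n_minima, 2)
  expect_equal(sort(pb$minima$rho), c(0, 1), tolerance = 0.05)
  expect_gt(pb$delta, 1)
  # constant field: single occupied bin, no NaN/Inf anywhere
  pc <- free_energy_profile(array(0.5, c(8, 8)))
  expect_equal(pc$n_minima, 1)
  expect_true(all(is.finite(pc$F)))
  expect_equal(pc$delta, 0)
})

test_that("the separation score is monotone in block contrast", {
  set.seed(14)
  m <- binary_model(0, 0)
  # interdiffusion noise: swap the contents of random site pairs; many
  # swaps approach a uniform shuffle
  xi_at_mixing <- function(n_swaps) {
    st <- two_block_state(48)
    n <- length(st$sites)
    if (n_swaps > 0) for (k in seq_len(n_swaps)) {
      ij <- sample.int(n, 2)
      st$sites[ij] <- st$sites[rev(ij)]
    }
    separation_score(free_energy_profile(
      local_density(st, 1, sigma = 2)))$xi
  }
  xis <- vapply(c(0, 1500, 4000, 8000), xi_at_mixing, numeric(1))
  expect_gt(xis[1], 0.8)
  expect_true(all(diff(xis) <= 1e-9))
  expect_lt(xis[4], 0.2)
})

test_that("phase calls behave at the extremes and combine components", {
  # all-unimodal components: xi = 0, mixed
  flatprof <- free_energy_profile(array(0.3, c(6, 6)))
  call0 <- separation_score(list(flatprof, flatprof))
  expect_equal(call0$xi, 0)
  expect_equal(as.character(call0$label), "mixed")
  # a deeply bimodal component forces a separated call
  pb <- free_energy_profile(local_density(two_block_state(64), 1, sigma = 2))
  call1 <- separation_score(list(flatprof, pb))
  expect_gt(call1$xi, 0.8)
  expect_equal(as.character(call1$label), "separated")
  expect_equal(nrow(call1$per_component), 2)
})

test_that("snapshot sets combine by majority vote consistently with mean xi", {
  set.seed(15)
  m <- binary_model(1, 0, beta = 2.5, K = 3)
  st <- init_lattice(2, 24, 0.5)
  r <- kawasaki_sweep(st, m, beta = 2.5, sweeps = 3000)
  snaps <- list()
  for (i in 1:12) {
    r <- kawasaki_sweep(r$state, m, beta = 2.5, sweeps = 300)
    snaps[[i]] <- r$state
  }
  cl <- classify_snapshots(snaps, m, sigma = 2, threshold = 0.45)
  vote_label <- as.character(cl$label)
  mean_label <- if (cl$xi_mean >= 0.45) "separated" else "mixed"
  expect_equal(vote_label, mean_label)
  expect_equal(vote_label, "separated")   # deep quench has de-mixed
})

test_that("threshold calibration recovers a perfect synthetic detector", {
  # xi jumps 0 -> 1 exactly at the specific-heat peak: any interior
  # threshold gives zero error
  beta <- seq(0, 3, length.out = 100)
  runs <- lapply(c(1.0, 1.7, 2.2), function(bc)
    list(beta = beta, xi = as.numeric(beta >= bc), beta_c_heat = bc))
  cal <- calibrate_threshold(runs)
  expect_lt(cal$mean_abs_err, 0.04)
  expect_true(cal$threshold > 0 && cal$threshold < 1)
  # crossing helper: exact interpolation and NA when never crossed
  expect_equal(xi_crossing(beta, as.numeric(beta >= 1.7), 0.5, smooth = 1),
               1.7, tolerance = 0.04)
  expect_true(is.na(xi_crossing(beta, rep(0, 100), 0.5)))
})

test_that("mixed and separated exemplar runs get opposite labels", {
  # two representative ternary runs: one annealed into the two-phase
  # region (slow ramp, then equilibration, so domains coarsen), one held
  # at high temperature
  m <- demixing_presets(beta = 1, K = 3)$associative
  set.seed(16)
  st <- init_lattice(2, 24, c(0.25, 0.25))
  sch <- anneal_schedule(0, 1, 200, 10, n_tail_sweeps = 5e4)
  run <- simulate_annealing(st, m, sch, n_snapshots = 10,
                            keep_energies = FALSE)
  call_sep <- classify_snapshots(run$snapshots, m, sigma = 2,
                                 threshold = 0.45)
  mix_st <- init_lattice(2, 24, c(0.25, 0.25))
  mix_r <- kawasaki_sweep(mix_st, m, beta = 0.2, sweeps = 5000)
  call_mix <- classify_snapshot(mix_r$state, m, sigma = 2, threshold = 0.45)
  expect_equal(as.character(call_sep$label), "separated")
  expect_equal(as.character(call_mix$label), "mixed")
  expect_gt(call_sep$xi_mean - call_mix$xi, 0.5)
})
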