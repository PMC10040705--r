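test_that("ternary fixed points respect symmetry and limits", {
  # no couplings: both messages vanish
  fp <- ternary_fixed_point(ternary_model(0, 0, 0, 0.3, -0.2))
  expect_length(fp, 1)
  expect_equal(fp[[1]]$u_minus, 0, tolerance = 1e-12)
  expect_equal(fp[[1]]$u_plus, 0, tolerance = 1e-12)
  # exchange symmetry: in the single-solution regime the fixed point is
  # exactly symmetric
  ms <- ternary_model(J_mm = 0.5, J_pp = 0.5, J_pm = -0.3, mu_minus = 0.4,
                      mu_plus = 0.4)
  fps <- ternary_fixed_point(ms)
  for (s in fps) expect_equal(s$u_minus, s$u_plus, tolerance = 1e-10)
  # with strong symmetric couplings the solution set is exchange-symmetric
  # (spontaneously broken pairs come in mirror images)
  mstrong <- ternary_model(J_mm = 1.2, J_pp = 1.2, J_pm = -0.5,
                           mu_minus = 0.4, mu_plus = 0.4)
  fs <- ternary_fixed_point(mstrong)
  um <- vapply(fs, `[[`, numeric(1), "u_minus")
  up <- vapply(fs, `[[`, numeric(1), "u_plus")
  for (i in seq_along(um))
    expect_lt(min(abs(um - up[i]) + abs(up - um[i])), 1e-7)
  expect_true(any(abs(um - up) < 1e-9))         # the symmetric root is there
  # freezing out one solute reduces to the binary fixed point
  mt <- ternary_model(J_mm = 0.5, J_pp = 2, J_pm = 1, mu_minus = 50,
                      mu_plus = 1, K = 3)
  fpt <- ternary_fixed_point(mt)
  fpb <- binary_fixed_point(binary_model(2, 1, K = 3))
  up <- vapply(fpt, `[[`, numeric(1), "u_plus")
  ub <- vapply(fpb, `[[`, numeric(1), "u")
  expect_lt(min(abs(outer(up, ub, "-"))), 1e-8)
})

test_that("densities follow the three-state occupation formula", {
  m0 <- ternary_model(0, 0, 0)
  d <- ternary_densities(list(u_minus = 0, u_plus = 0), m0)
  expect_equal(unname(d), c(1, 1) / 3, tolerance = 1e-12)
  ms <- ternary_model(-0.8, -0.8, 2, 0.3, 0.3)
  fp <- ternary_fixed_point(ms)[[1]]
  ds <- ternary_densities(fp, ms)
  expect_equal(ds[["phi_plus"]], ds[["phi_minus"]], tolerance = 1e-10)
  # deep Cayley tree oracle (exact message passing, depth 7): the root
  # marginal of the free-boundary tree matches the homogeneous fixed point
  # (contracting parameter regime, so the leaf-to-root recursion converges)
  mt <- ternary_model(0.5, 0.8, 0.3, 0.6, 0.4, K = 3)
  fps <- ternary_fixed_point(mt)
  g <- cayley_tree(3, 7)
  bp <- tree_messages(g, mt)
  root <- c(bp$marginals[1, "1"], bp$marginals[1, "-1"])
  err <- vapply(fps, function(s) {
    d <- ternary_densities(s, mt)
    max(abs(d[["phi_plus"]] - root[1]), abs(d[["phi_minus"]] - root[2]))
  }, numeric(1))
  expect_lt(min(err), 1e-3)
})

test_that("density -> field inversion has the ideal closed form at J = 0", {
  m0 <- ternary_model(0, 0, 0, beta = 1.7)
  pp <- c(0.2, 0.05); pm <- c(0.3, 0.6)
  f <- ternary_fields_from_densities(pp, pm, m0)
  expect_equal(f$mu_plus, log((1 - pp - pm) / pp) / 1.7, tolerance = 1e-10)
  expect_equal(f$mu_minus, log((1 - pp - pm) / pm) / 1.7, tolerance = 1e-10)
  expect_true(all(abs(f$u_plus) < 1e-12 & abs(f$u_minus) < 1e-12))
  # symmetric couplings and equal densities give equal fields
  ms <- ternary_model(-1, -1, 3)
  fs <- ternary_fields_from_densities(0.15, 0.15, ms)
  expect_equal(fs$mu_plus, fs$mu_minus, tolerance = 1e-10)
  expect_error(ternary_fields_from_densities(0.7, 0.4, m0), "phi")
})

test_that("field inversion round-trips through the forward state equation", {
  m <- ternary_model(-1, -1, 3, beta = 1, K = 3)   # associative couplings
  grid <- expand.grid(pp = seq(0.1, 0.5, length.out = 5),
                      pm = seq(0.1, 0.45, length.out = 5))
  grid <- grid[grid$pp + grid$pm < 0.9, ]
  f <- ternary_fields_from_densities(grid$pp, grid$pm, m)
  for (i in seq_len(nrow(grid))) {
    mi <- ternary_model(-1, -1, 3, mu_minus = f$mu_minus[i],
                        mu_plus = f$mu_plus[i], beta = 1, K = 3)
    fps <- ternary_fixed_point(mi)
    ds <- vapply(fps, function(s) ternary_densities(s, mi), numeric(2))
    err <- apply(ds, 2, function(d)
      max(abs(d[1] - grid$pp[i]), abs(d[2] - grid$pm[i])))
    expect_lt(min(err), 1e-6)
  }
})

test_that("stability labels are thermodynamically sensible", {
  # ideal mixture is locally stable everywhere
  m0 <- ternary_model(0, 0, 0)
  g <- expand.grid(pp = seq(0.05, 0.85, by = 0.1),
                   pm = seq(0.05, 0.85, by = 0.1))
  g <- g[g$pp + g$pm < 0.95, ]
  st <- ternary_stability(g$pp, g$pm, m0)
  expect_true(all(st$label == "mixed"))
  # Maxwell symmetry of the numerical Hessian (mu is a gradient field)
  ma <- ternary_model(-1, -1, 3)
  sta <- ternary_stability(c(0.2, 0.1, 0.3), c(0.2, 0.25, 0.1), ma)
  expect_lt(max(abs(sta$asym)), 1e-4)
  # boundary handling
  expect_error(ternary_stability(1e-9, 0.2, m0), "simplex")
})

test_that("the associative diagram shows a bounded separated region and re-entrance", {
  m <- ternary_model(-1, -1, 3, beta = 1, K = 3)
  pm_scan <- c(0.005, 0.01, 0.02, 0.05, 0.1, 0.15, 0.25, 0.35, 0.5, 0.6)
  st <- ternary_stability(rep(0.05, length(pm_scan)), pm_scan, m)
  lab <- as.character(st$label)
  expect_equal(lab[1], "mixed")                   # near the phi- = 0 axis
  expect_equal(lab[length(lab)], "mixed")         # re-entrant at high phi-
  expect_true(any(lab == "separated"))
  r <- rle(lab)
  expect_identical(r$values, c("mixed", "separated", "mixed"))
  # region bounded away from the phi+ axis too (symmetric couplings)
  st2 <- ternary_stability(pm_scan, rep(0.05, length(pm_scan)), m)
  expect_identical(rle(as.character(st2$label))$values,
                   c("mixed", "separated", "mixed"))
})

test_that("phase maps reproduce the three de-mixing morphologies", {
  presets <- demixing_presets(beta = 1, K = 3)
  grid <- seq(0.05, 0.45, length.out = 7)
  maps <- lapply(presets, function(m) ternary_phase_map(grid, grid, m))
  # ideal grid is all mixed
  m0 <- ternary_phase_map(grid, grid, ternary_model(0, 0, 0))
  expect_true(all(m0$label == "mixed"))
  # all three interaction patterns phase separate somewhere
  for (mp in maps) expect_true(any(mp$label == "separated"))
  at <- function(mp, pp, pm) {
    i <- which.min((mp$phi_plus - pp)^2 + (mp$phi_minus - pm)^2)
    as.character(mp$label[i])
  }
  # associative: needs both solutes, so the dilute corner near one axis is
  # mixed while the central region separates
  expect_equal(at(maps$associative, 0.25, 0.25), "separated")
  expect_equal(at(maps$associative, 0.45, 0.05), "mixed")
  # segregative: mutual avoidance separates when both are abundant
  expect_equal(at(maps$segregative, 0.45, 0.45), "separated")
  expect_equal(at(maps$segregative, 0.05, 0.05), "mixed")
  # counter-ionic: the self-attracting (+) solute separates even with
  # almost no (-) partner
  expect_equal(at(maps$counterionic, 0.45, 0.05), "separated")
  expect_equal(at(maps$counterionic, 0.05, 0.45), "mixed")
})
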