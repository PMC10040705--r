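test_that("model constructors validate their invariants", {
  expect_error(interaction_model(2, matrix(c(0, 1, 1, 0), 2), c(0, 0)),
               "solvent")
  expect_error(interaction_model(3, matrix(c(0, 0, 0, 0, 1, 0.5, 0, 0.2, 1), 3),
                                 c(0, 0, 0)), "symmetric")
  expect_error(interaction_model(2, matrix(0, 2, 2), c(0.5, 0)), "solvent")
  expect_error(binary_model(1, 0, beta = -1), "beta")
  expect_error(binary_model(1, 0, K = 0), "K")
  m <- ternary_model(J_mm = -1, J_pp = -2, J_pm = 3, mu_minus = 0.4,
                     mu_plus = 0.7)
  # field convention: states (-1, 0, +1) map to internal indices (2, 1, 3)
  expect_identical(m$labels, c(0L, -1L, 1L))
  expect_equal(m$J[2, 2], -1)
  expect_equal(m$J[3, 3], -2)
  expect_equal(m$J[2, 3], 3)
  expect_equal(m$mu[2], 0.4)
  expect_equal(m$mu[3], 0.7)
})

test_that("graphs reject self-loops, duplicates and degenerate lattices", {
  expect_error(interaction_graph(3, rbind(c(1, 1))), "self-loop")
  expect_error(interaction_graph(3, rbind(c(1, 2), c(2, 1))), "duplicate")
  expect_error(interaction_graph(3, rbind(c(1, 4))), "out of range")
  expect_error(lattice_graph(2, 2), "L >= 3")
  g <- lattice_graph(2, 4)
  expect_equal(nrow(g$edges), 2 * 16)         # 2 d L^d periodic edges
  expect_false(g$is_tree)
  g3 <- lattice_graph(3, 3)
  expect_equal(nrow(g3$edges), 3 * 27)
  expect_true(path_graph(5)$is_tree)
  expect_true(random_tree(9)$is_tree)
  expect_false(cycle_graph(4)$is_tree)
  ct <- cayley_tree(3, 2)
  expect_true(ct$is_tree)
  expect_equal(ct$n, 1 + 4 + 12)
})

test_that("energy matches hand enumeration and the brute-force oracle", {
  # all-solvent: couplings and solvent potential vanish
  m <- random_model(3)
  g <- lattice_graph(2, 3)
  expect_equal(energy(g, rep(0, g$n), m), 0)
  # 3-node path, ternary (+1, +1, -1): -(J++ + J+-) + 2 mu+ + mu-
  m3 <- ternary_model(J_mm = 0, J_pp = 2, J_pm = 0.5, mu_minus = 0.2,
                      mu_plus = 0.1)
  expect_equal(energy(path_graph(3), c(1, 1, -1), m3), -2.1)
  # isolated occupied node: just mu
  m2 <- binary_model(1.3, 0.7)
  expect_equal(energy(interaction_graph(1), 1, m2), 0.7)
  # state out of range
  expect_error(energy(path_graph(2), c(0, 7), m2), "out of range")
  # oracle equivalence and node-relabeling invariance on random graphs
  set.seed(5)
  for (rep in 1:10) {
    q <- sample(2:3, 1)
    m <- random_model(q)
    g <- if (rep %% 2) random_tree(7) else cycle_graph(6)
    s <- sample(m$labels, g$n, replace = TRUE)
    expect_equal(energy(g, s, m), energy_oracle(g, s, m))
    perm <- sample(g$n)
    gp <- interaction_graph(g$n, cbind(perm[g$edges[, 1]],
                                       perm[g$edges[, 2]]))
    sp <- integer(g$n); sp[perm] <- s
    expect_equal(energy(gp, sp, m), energy(g, s, m))
  }
})

test_that("exact enumeration reproduces closed-form partition functions", {
  # single binary node: Z = 1 + e^{-mu}
  m <- binary_model(1, 0.8)
  z1 <- exact_partition(interaction_graph(1), m)
  expect_equal(z1$Z, 1 + exp(-0.8), tolerance = 1e-12)
  # two nodes, one edge, J = 1, mu = 0: Z = 3 + e
  m2 <- binary_model(1, 0)
  z2 <- exact_partition(path_graph(2), m2)
  expect_equal(z2$Z, 3 + exp(1), tolerance = 1e-12)
  # high-temperature limit: Z -> q^N
  mq <- random_model(3, beta = 1e-9)
  zq <- exact_partition(cycle_graph(4), mq)
  expect_equal(zq$Z, 3^4, tolerance = 1e-6)
  # marginals normalized per node
  set.seed(11)
  m <- random_model(3)
  z <- exact_partition(random_tree(6), m)
  expect_lt(max(abs(rowSums(z$marginals) - 1)), 1e-12)
  # capacity error names the cap
  expect_error(exact_partition(path_graph(11), binary_model(1, 0),
                               cap = 1000), "cap")
})

test_that("particle-hole mapping relates occupancies on regular graphs", {
  # on a C-regular graph, holes see J' = J and mu' = C J - mu
  set.seed(21)
  J <- 0.8; mu <- 0.3; C <- 2                 # cycle: degree 2
  g <- cycle_graph(5)
  z1 <- exact_partition(g, binary_model(J, mu))
  z2 <- exact_partition(g, binary_model(J, C * J - mu))
  expect_equal(z1$marginals[, "1"], 1 - z2$marginals[, "1"],
               tolerance = 1e-10)
})

test_that("model config files round-trip through YAML", {
  tmp <- tempfile(fileext = ".yaml")
  m <- ternary_model(J_mm = -1, J_pp = -1, J_pm = 3, mu_minus = 0.2,
                     beta = 1.5, K = 5)
  write_model_config(m, tmp)
  m2 <- read_model_config(tmp)
  expect_equal(m2$J, m$J)
  expect_equal(m2$mu, m$mu)
  expect_equal(m2$beta, m$beta)
  expect_equal(m2$K, m$K)
  mb <- binary_model(2, 1, beta = 2, K = 4)
  write_model_config(mb, tmp)
  expect_equal(read_model_config(tmp)$J, mb$J)
})
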