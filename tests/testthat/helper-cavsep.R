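# shared fixtures: random models and graphs built in code

random_model <- function(q, beta = 1, K = 3) {
  J <- matrix(0, q, q)
  for (a in 2:q) for (b in a:q) J[a, b] <- J[b, a] <- stats::runif(1, -2, 2)
  mu <- c(0, stats::runif(q - 1, -2, 2))
  interaction_model(q, J, mu, beta = beta, K = K)
}

# brute-force energy oracle: explicit loop over edges and nodes
energy_oracle <- function(graph, states, model) {
  idx <- match(states, model$labels)
  e <- 0
  if (nrow(graph$edges)) {
    for (k in seq_len(nrow(graph$edges))) {
      i <- graph$edges[k, 1]; j <- graph$edges[k, 2]
      e <- e - model$J[idx[i], idx[j]]
    }
  }
  e + sum(model$mu[idx])
}

# two-block half/half binary configuration on an L x L lattice
two_block_state <- function(L) {
  st <- init_lattice(2, L, 0.5)
  sites <- array(0L, c(L, L))
  sites[seq_len(L %/% 2), ] <- 1L
  st$sites <- sites
  st$counts <- c(L^2 - L %/% 2 * L, L %/% 2 * L)
  st
}
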