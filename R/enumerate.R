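#' Energy of a configuration
#'
#' Evaluates the Hamiltonian
#' \eqn{H(\sigma) = -\sum_{\langle i,j\rangle} J(\sigma_i,\sigma_j) + \sum_i \mu(\sigma_i)}
#' on an arbitrary graph, each undirected edge counted exactly once.
#'
#' @param graph an [interaction_graph()].
#' @param states per-node state vector in user-facing labels (see
#'   [state_labels()]): 0/1 for binary, -1/0/+1 for ternary.
#' @param model an [interaction_model()].
#' @return scalar energy in kBT.
#' @export
energy <- function(graph, states, model) {
  stopifnot(inherits(graph, "interaction_graph"),
            inherits(model, "interaction_model"))
  if (length(states) != graph$n)
    stop("states must have one entry per node (", graph$n, ")")
  idx <- states_to_index(states, model)
  e_pair <- if (nrow(graph$edges))
    sum(model$J[cbind(idx[graph$edges[, 1]], idx[graph$edges[, 2]])]) else 0
  -e_pair + sum(model$mu[idx])
}

#' Exact partition function by enumeration
#'
#' Computes \eqn{Z = \sum_\sigma e^{-\beta H(\sigma)}} by full enumeration of
#' the q^N configurations, together with the exact single-site marginal
#' distributions.  Serves as the ground-truth oracle for the cavity method
#' on small systems.
#'
#' @inheritParams energy
#' @param cap enumeration cap on the number of configurations
#'   (default 3^12 = 531441).
#' @return list with `Z`, `logZ`, and `marginals` (n x q matrix, columns
#'   named by state label, rows summing to 1).
#' @export
exact_partition <- function(graph, model, cap = 3^12) {
  stopifnot(inherits(graph, "interaction_graph"),
            inherits(model, "interaction_model"))
  n <- graph$n; q <- model$q
  n_conf <- q^n
  if (n_conf > cap)
    stop("enumeration too large: q^N = ", format(n_conf),
         " exceeds the cap of ", format(cap), " configurations")
  conf <- as.matrix(expand.grid(rep(list(seq_len(q)), n),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(conf) <- NULL
  eng <- rep(0, n_conf)
  for (e in seq_len(nrow(graph$edges))) {
    eng <- eng - model$J[cbind(conf[, graph$edges[e, 1]],
                               conf[, graph$edges[e, 2]])]
  }
  for (i in seq_len(n)) eng <- eng + model$mu[conf[, i]]
  lw <- -model$beta * eng
  m <- max(lw)
  w <- exp(lw - m)
  Zs <- sum(w)
  logZ <- m + log(Zs)
  marg <- matrix(0, n, q, dimnames = list(NULL, model$labels))
  for (i in seq_len(n)) {
    for (s in seq_len(q)) marg[i, s] <- sum(w[conf[, i] == s])
  }
  marg <- marg / Zs
  list(Z = exp(logZ), logZ = logZ, marginals = marg)
}
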