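#' Lattice solution model (generalized Potts model with solvent)
#'
#' Defines the microscopic model
#' \deqn{H(\sigma) = -\sum_{\langle i,j\rangle} J(\sigma_i,\sigma_j) + \sum_i \mu(\sigma_i)}
#' on a graph or regular lattice.  State 0 is the solvent; couplings to the
#' solvent and its chemical potential are identically zero.  All energies are
#' in units of kBT, so `beta` is dimensionless (default 1).
#'
#' Note the sign convention: the chemical potential enters the Hamiltonian
#' with a plus sign, so *larger* `mu` suppresses occupancy (the fugacity of a
#' solute is `exp(-beta*mu)`).  Users expecting the opposite convention must
#' negate `mu`.
#'
#' @param q number of states including the solvent (q >= 2).
#' @param J symmetric q x q coupling matrix in kBT; row/column 1 (solvent)
#'   must be zero.  Rows/columns are ordered as `state_labels(q)`.
#' @param mu length-q chemical potential vector in kBT; `mu[1]` (solvent)
#'   must be zero.
#' @param beta inverse temperature (dimensionless; energies are in kBT).
#' @param K Cayley-tree branching number (connectivity C = K + 1) used by the
#'   homogeneous cavity equations.
#' @return An object of class `interaction_model`.
#' @seealso [binary_model()], [ternary_model()] for the common special cases.
#' @export
interaction_model <- function(q, J, mu, beta = 1, K = 3) {
  q <- as.integer(q)
  if (q < 2L) stop("q must be >= 2 (solvent plus at least one solute)")
  J <- as.matrix(J)
  if (!all(dim(J) == c(q, q))) stop("J must be a ", q, "x", q, " matrix")
  if (max(abs(J - t(J))) > 1e-12) stop("J must be symmetric")
  if (any(J[1, ] != 0) || any(J[, 1] != 0))
    stop("couplings to the solvent (state 0) must be zero")
  mu <- as.numeric(mu)
  if (length(mu) != q) stop("mu must have length q = ", q)
  if (mu[1] != 0) stop("the solvent chemical potential mu[1] must be zero")
  if (!is.finite(beta) || beta <= 0) stop("beta must be positive")
  K <- as.integer(K)
  if (K < 1L) stop("K must be a positive integer")
  structure(
    list(q = q, J = J, mu = mu, beta = beta, K = K,
         labels = state_labels(q)),
    class = "interaction_model")
}

#' State labels used in user-facing I/O
#'
#' Internal state indices are 1..q with index 1 the solvent.  User-facing
#' labels follow the field convention: `0, 1` for a binary solution and
#' `0, -1, +1` for a ternary one (solute "minus" maps to internal index 2,
#' solute "plus" to index 3).  For q > 3 the labels are `0, 1, ..., q-1`.
#'
#' @param q number of states.
#' @return integer vector of length q, `labels[i]` being the label of
#'   internal index i.
#' @export
state_labels <- function(q) {
  if (q == 3L) c(0L, -1L, 1L) else c(0L, seq_len(q - 1L))
}

#' @rdname interaction_model
#' @param J_scalar solute-solute coupling J(1,1) for the binary model.
#' @param mu_scalar solute chemical potential for the binary model.
#' @export
binary_model <- function(J_scalar, mu_scalar = 0, beta = 1, K = 3) {
  J <- matrix(0, 2, 2); J[2, 2] <- J_scalar
  interaction_model(2L, J, c(0, mu_scalar), beta = beta, K = K)
}

#' @rdname interaction_model
#' @param J_mm,J_pp,J_pm ternary couplings J(-1,-1), J(+1,+1), J(+1,-1).
#' @param mu_minus,mu_plus ternary chemical potentials of the two solutes.
#' @export
ternary_model <- function(J_mm, J_pp, J_pm, mu_minus = 0, mu_plus = 0,
                          beta = 1, K = 3) {
  # internal index 2 = state -1, index 3 = state +1
  J <- matrix(0, 3, 3)
  J[2, 2] <- J_mm; J[3, 3] <- J_pp; J[2, 3] <- J[3, 2] <- J_pm
  interaction_model(3L, J, c(0, mu_minus, mu_plus), beta = beta, K = K)
}

#' @export
print.interaction_model <- function(x, ...) {
  kind <- switch(as.character(x$q), "2" = "binary", "3" = "ternary",
                 paste0("q = ", x$q))
  cat("<interaction_model> ", kind, ", beta = ", format(x$beta),
      ", K = ", x$K, " (connectivity ", x$K + 1L, ")\n", sep = "")
  if (x$q == 2L) {
    cat("  J = ", format(x$J[2, 2]), ", mu = ", format(x$mu[2]), "\n", sep = "")
  } else if (x$q == 3L) {
    cat("  J-- = ", format(x$J[2, 2]), ", J++ = ", format(x$J[3, 3]),
        ", J+- = ", format(x$J[2, 3]), "\n  mu- = ", format(x$mu[2]),
        ", mu+ = ", format(x$mu[3]), "\n", sep = "")
  } else {
    cat("  J:\n"); print(x$J); cat("  mu:", format(x$mu), "\n")
  }
  invisible(x)
}

#' The three ternary de-mixing parameter presets
#'
#' Interaction parameter sets for the three canonical modes of ternary phase
#' separation: associative (cross-attraction condenses both solutes into one
#' dense phase, J-- = J++ = -1, J+- = 3), segregative (each solute condenses
#' on its own, J-- = J++ = 1, J+- = -3), and counter-ionic (one
#' self-attracting solute drags a cross-attracting partner, J++ = 2,
#' J-- = 0, J+- = 0.5).
#'
#' @param beta inverse temperature (default 1).
#' @param K branching number (default 3, matching a 2D square lattice).
#' @return named list of three `interaction_model` objects.
#' @export
demixing_presets <- function(beta = 1, K = 3) {
  list(
    associative  = ternary_model(J_mm = -1, J_pp = -1, J_pm = 3,
                                 beta = beta, K = K),
    segregative  = ternary_model(J_mm = 1, J_pp = 1, J_pm = -3,
                                 beta = beta, K = K),
    counterionic = ternary_model(J_mm = 0, J_pp = 2, J_pm = 0.5,
                                 beta = beta, K = K))
}

# map user-facing state labels to internal indices 1..q (errors on bad labels)
states_to_index <- function(states, model) {
  idx <- match(states, model$labels)
  if (anyNA(idx))
    stop("state out of range: ", paste(unique(states[is.na(idx)]), collapse = ", "),
         " (valid labels: ", paste(model$labels, collapse = ", "), ")")
  idx
}

index_to_states <- function(idx, model) model$labels[idx]

#' Interaction graph
#'
#' A plain undirected graph on which the model's energy and partition
#' function can be evaluated exactly (each unordered edge stored once).
#'
#' @param n number of nodes.
#' @param edges two-column integer matrix of undirected edges (each pair
#'   once), or NULL for an edgeless graph.
#' @return object of class `interaction_graph` with fields `n`, `edges`,
#'   `is_tree`.
#' @export
interaction_graph <- function(n, edges = NULL) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(integer(), 0L, 2L)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2L)
  }
  if (nrow(edges)) {
    if (any(edges < 1L | edges > n)) stop("edge endpoint out of range")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (anyDuplicated(key)) stop("duplicate edges are not allowed")
  }
  structure(list(n = n, edges = edges, is_tree = graph_is_tree(n, edges)),
            class = "interaction_graph")
}

# tree <=> connected with n-1 edges
graph_is_tree <- function(n, edges) {
  if (nrow(edges) != n - 1L) return(FALSE)
  if (n == 1L) return(TRUE)
  adj <- graph_adjacency(n, edges)
  seen <- logical(n); seen[1L] <- TRUE; queue <- 1L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]]; new <- nb[!seen[nb]]
    seen[new] <- TRUE; queue <- c(queue, new)
  }
  all(seen)
}

graph_adjacency <- function(n, edges) {
  adj <- rep(list(integer()), n)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat("<interaction_graph> n =", x$n, "nodes,", nrow(x$edges), "edges,",
      if (x$is_tree) "tree" else "not a tree", "\n")
  invisible(x)
}

#' Standard small graphs
#'
#' Convenience constructors: path, star, cycle, random labeled tree, a
#' regular Cayley tree of given branching and depth, and the periodic
#' square/cubic lattice graph.
#'
#' @param n number of nodes.
#' @name graph-builders
NULL

#' @rdname graph-builders
#' @export
path_graph <- function(n) {
  interaction_graph(n, cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L))
}

#' @rdname graph-builders
#' @export
star_graph <- function(n) {
  interaction_graph(n, cbind(1L, seq.int(2L, n)))
}

#' @rdname graph-builders
#' @export
cycle_graph <- function(n) {
  if (n < 3L) stop("a cycle needs n >= 3")
  interaction_graph(n, rbind(cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L),
                             c(n, 1L)))
}

#' @rdname graph-builders
#' @export
random_tree <- function(n) {
  if (n == 1L) return(interaction_graph(1L))
  parents <- vapply(seq.int(2L, n), function(i) {
    if (i == 2L) 1L else sample.int(i - 1L, 1L)
  }, integer(1))
  interaction_graph(n, cbind(parents, seq.int(2L, n)))
}

#' @rdname graph-builders
#' @param K branching number of the Cayley tree: the root has K + 1
#'   neighbors, every other internal node has K children.
#' @param depth number of generations below the root (depth 0 = root only).
#' @export
cayley_tree <- function(K, depth) {
  edges <- list(); parent_gen <- 1L; next_id <- 2L
  for (g in seq_len(depth)) {
    n_children <- if (g == 1L) K + 1L else K
    children <- integer()
    for (p in parent_gen) {
      ch <- seq.int(next_id, next_id + n_children - 1L)
      edges[[length(edges) + 1L]] <- cbind(p, ch)
      children <- c(children, ch)
      next_id <- next_id + n_children
    }
    parent_gen <- children
  }
  em <- if (length(edges)) do.call(rbind, edges) else NULL
  interaction_graph(next_id - 1L, em)
}

#' @rdname graph-builders
#' @param d lattice dimension (2 or 3).
#' @param L linear size; periodic lattices require L >= 3 so that the wrap
#'   produces no duplicate edges.
#' @param periodic wrap boundaries (default TRUE).
#' @export
lattice_graph <- function(d, L, periodic = TRUE) {
  d <- as.integer(d); L <- as.integer(L)
  if (!d %in% c(2L, 3L)) stop("d must be 2 or 3")
  if (periodic && L < 3L)
    stop("periodic lattices need L >= 3 (L < 3 would duplicate edges)")
  if (L < 2L) stop("L must be >= 2")
  dims <- rep(L, d)
  n <- L^d
  coord <- arrayInd(seq_len(n), dims)
  edges <- list()
  for (axis in seq_len(d)) {
    nb <- coord
    nb[, axis] <- nb[, axis] + 1L
    if (periodic) {
      nb[, axis] <- ((nb[, axis] - 1L) %% L) + 1L
      keep <- rep(TRUE, n)
    } else {
      keep <- nb[, axis] <= L
    }
    to <- as.integer((nb - 1L) %*% cumprod(c(1L, dims[-d])) + 1L)
    edges[[axis]] <- cbind(seq_len(n)[keep], to[keep])
  }
  interaction_graph(n, do.call(rbind, edges))
}
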