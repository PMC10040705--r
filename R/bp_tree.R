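#' Exact cavity message passing on a tree
#'
#' Computes the directed cavity messages
#' \deqn{Z_{i\to j}(\sigma_i) = \sum_{\sigma_j} e^{\beta[J(\sigma_i,\sigma_j)-\mu(\sigma_j)]}
#'   \prod_{k \in \partial j \setminus i} Z_{j\to k}(\sigma_j)}
#' for every directed edge of a tree, together with the partition function
#' and all single-site marginals.  On a tree the decomposition is exact (no
#' iteration): messages are evaluated leaf-to-root and back.  All
#' computations are done in log space so deep trees do not overflow.
#'
#' @param graph an [interaction_graph()] with `is_tree = TRUE`.
#' @param model an [interaction_model()].
#' @return list with `logZ`, `Z`, `marginals` (n x q matrix, columns named
#'   by state label), and `log_messages` (named list, entry `"i->j"` holding
#'   the length-q vector \eqn{\log Z_{i\to j}(\sigma_i)} indexed by the
#'   state of node i).
#' @export
tree_messages <- function(graph, model) {
  stopifnot(inherits(graph, "interaction_graph"),
            inherits(model, "interaction_model"))
  if (!graph$is_tree) stop("tree_messages requires an acyclic connected graph")
  n <- graph$n; q <- model$q; beta <- model$beta
  # transfer weight W[a, b] = beta * (J[a, b] - mu[b]); message recursion is
  # a log-sum-exp over the second index
  W <- beta * (model$J - matrix(model$mu, q, q, byrow = TRUE))

  adj <- graph_adjacency(n, graph$edges)
  # BFS rooting at node 1
  parent <- integer(n); parent[1L] <- 0L
  order <- integer(n); order[1L] <- 1L
  seen <- logical(n); seen[1L] <- TRUE
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- order[head]; head <- head + 1L
    for (w in adj[[v]]) if (!seen[w]) {
      seen[w] <- TRUE; tail <- tail + 1L; order[tail] <- w; parent[w] <- v
    }
  }
  children <- rep(list(integer()), n)
  for (v in order[-1L]) children[[parent[v]]] <- c(children[[parent[v]]], v)

  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  # up[[v]] = log Z_{parent(v) -> v}(sigma_parent): subtree hanging at v
  # down[[v]] = log Z_{v -> parent(v)}(sigma_v): rest of the tree seen from v
  up <- rep(list(numeric(q)), n)
  down <- rep(list(numeric(q)), n)

  for (v in rev(order)) {
    if (v == 1L) next
    S <- numeric(q)                        # sum of children messages at v
    for (c in children[[v]]) S <- S + up[[c]]
    up[[v]] <- vapply(seq_len(q), function(a) lse(W[a, ] + S), numeric(1))
  }
  for (v in order[-1L]) {
    p <- parent[v]
    Tp <- if (p == 1L) numeric(q) else down[[p]]
    for (c in children[[p]]) if (c != v) Tp <- Tp + up[[c]]
    down[[v]] <- vapply(seq_len(q), function(a) lse(W[a, ] + Tp), numeric(1))
  }

  marg <- matrix(0, n, q, dimnames = list(NULL, model$labels))
  logZ <- NA_real_
  for (v in seq_len(n)) {
    lm <- -beta * model$mu
    for (c in children[[v]]) lm <- lm + up[[c]]
    if (v != 1L) lm <- lm + down[[v]]
    z <- lse(lm)
    if (v == 1L) logZ <- z
    marg[v, ] <- exp(lm - z)
  }

  msgs <- list()
  for (v in order[-1L]) {
    p <- parent[v]
    msgs[[paste0(p, "->", v)]] <- up[[v]]
    msgs[[paste0(v, "->", p)]] <- down[[v]]
  }
  list(logZ = logZ, Z = exp(logZ), marginals = marg, log_messages = msgs)
}
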