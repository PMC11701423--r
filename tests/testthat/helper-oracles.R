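# Independent oracles used to cross-check the package's algorithms.
# These deliberately use different algorithms from the implementation:
# d-separation via classic per-path blocking rules (chain/fork/collider)
# instead of moralization, closures via matrix powers, mixtures via
# moment algebra.

# all simple paths between a and b in the skeleton, as node sequences
skeleton_paths <- function(g, a, b) {
  ed <- graph_edges(g)
  nbr <- lapply(graph_nodes(g), function(v)
    unique(c(ed$to[ed$from == v], ed$from[ed$to == v])))
  names(nbr) <- graph_nodes(g)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    for (w in nbr[[v]]) {
      if (w == b) out[[length(out) + 1L]] <<- c(path, w)
      else if (!(w %in% path)) walk(c(path, w))
    }
  }
  walk(a)
  out
}

# classic path-blocking d-separation: every path must be blocked
oracle_d_separated <- function(g, A, B, C) {
  if (!length(A) || !length(B)) return(TRUE)
  ed <- graph_edges(g)
  has_edge <- function(x, y) any(ed$from == x & ed$to == y)
  path_open <- function(p) {
    if (length(p) == 2L) return(TRUE)
    for (i in 2:(length(p) - 1L)) {
      v <- p[i]
      collider <- has_edge(p[i - 1L], v) && has_edge(p[i + 1L], v)
      if (collider) {
        if (!any(descendants(g, v) %in% C)) return(FALSE)
      } else {
        if (v %in% C) return(FALSE)
      }
    }
    TRUE
  }
  for (a in A) for (b in B) {
    for (p in skeleton_paths(g, a, b)) if (path_open(p)) return(FALSE)
  }
  TRUE
}

# reachability (transitive closure) as a logical matrix, via matrix powers
closure_matrix <- function(g) {
  A <- adjacency_matrix(g) > 0
  m <- nrow(A)
  R <- A
  for (i in seq_len(m)) R <- R | (R %*% A > 0)
  R
}

# moments of an equal-weight mixture of Gaussians
mixture_moments <- function(moms) {
  k <- length(moms)
  mu <- Reduce(`+`, lapply(moms, `[[`, "mean")) / k
  S <- Reduce(`+`, lapply(moms, `[[`, "cov")) / k
  for (mm in moms) {
    d <- mm$mean - mu
    S <- S + outer(d, d) / k
  }
  list(mean = mu, cov = S)
}

# random DAG for property tests (independent of random_sem's generator)
random_test_dag <- function(m, p = 0.4) {
  nodes <- paste0("n", seq_len(m))
  ed <- list()
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    if (runif(1) < p)
      ed[[length(ed) + 1L]] <- data.frame(from = nodes[i], to = nodes[j])
  }
  digraph(nodes, if (length(ed)) do.call(rbind, ed) else NULL)
}

# every acyclic configuration on 3 labelled nodes (each unordered pair
# absent, forward or backward)
all_3node_dags <- function() {
  nodes <- c("a", "b", "c")
  pairs <- list(c("a", "b"), c("a", "c"), c("b", "c"))
  out <- list()
  for (s1 in 0:2) for (s2 in 0:2) for (s3 in 0:2) {
    ed <- list()
    for (k in 1:3) {
      st <- c(s1, s2, s3)[k]
      pr <- pairs[[k]]
      if (st == 1) ed[[length(ed) + 1L]] <- data.frame(from = pr[1],
                                                       to = pr[2])
      if (st == 2) ed[[length(ed) + 1L]] <- data.frame(from = pr[2],
                                                       to = pr[1])
    }
    g <- digraph(nodes, if (length(ed)) do.call(rbind, ed) else NULL)
    if (is_acyclic(g)) out[[length(out) + 1L]] <- g
  }
  out
}

# partial correlation of i, j given K from a covariance matrix
pcor_from_cov <- function(S, i, j, K) {
  sel <- c(i, j, K)
  P <- solve(S[sel, sel, drop = FALSE])
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# random supported (backdoor-free) standardized model and a node pair:
# source with no parents, target reachable from it
random_supported_pair <- function(seed) {
  for (k in 0:50) {
    model <- random_sem(5, edge_prob = 0.5, seed = seed + 1000L * k)
    g <- model$graph
    roots <- Filter(function(v) !length(parent_sets(g)[[v]]),
                    graph_nodes(g))
    for (s in roots) {
      down <- setdiff(descendants(g, s), s)
      if (length(down))
        return(list(model = standardize(model), s = s,
                    t = down[length(down)]))
    }
  }
  stop("no supported pair found")
}
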