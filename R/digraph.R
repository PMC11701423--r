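#' Directed graph
#'
#' A minimal directed-graph container for causal models: an ordered set of
#' string node identifiers and a set of directed edges. At most one edge per
#' ordered pair, no self-loops. Node order is fixed by declaration order so
#' that every downstream iteration is deterministic.
#'
#' @param nodes Character vector of unique node identifiers.
#' @param edges Edge set: a two-column matrix or data frame (from, to), a
#'   character vector of \code{"a->b"} strings, or \code{NULL} for an
#'   edgeless graph.
#' @return An object of class \code{digraph} with components \code{nodes}
#'   (character) and \code{edges} (data frame with columns \code{from},
#'   \code{to}).
#' @examples
#' g <- digraph(c("s", "u", "t"), c("s->u", "u->t"))
#' parent_sets(g)
#' ancestors(g, "t")
#' @export
digraph <- function(nodes, edges = NULL) {
  if (!is.character(nodes) || length(nodes) < 1L || anyNA(nodes))
    stop("'nodes' must be a non-empty character vector")
  dup <- unique(nodes[duplicated(nodes)])
  if (length(dup))
    stop("duplicate node identifiers: ", paste(dup, collapse = ", "))
  ed <- as_edge_df(edges)
  unknown <- setdiff(unique(c(ed$from, ed$to)), nodes)
  if (length(unknown))
    stop("edge endpoints not among declared nodes: ",
         paste(unknown, collapse = ", "))
  if (any(ed$from == ed$to))
    stop("self-loops are not allowed: ",
         paste(ed$from[ed$from == ed$to], collapse = ", "))
  key <- paste(ed$from, ed$to, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate edges: ",
         paste(unique(paste0(ed$from, "->", ed$to)[duplicated(key)]),
               collapse = ", "))
  structure(list(nodes = nodes, edges = ed), class = "digraph")
}

# normalise the accepted edge inputs to a data.frame(from, to)
as_edge_df <- function(edges) {
  if (is.null(edges) || NROW(edges) == 0L)
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  if (is.character(edges)) {
    parts <- strsplit(edges, "->", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) stop("malformed edge string(s): ",
                       paste(edges[bad], collapse = ", "))
    return(data.frame(from = trimws(vapply(parts, `[`, "", 1L)),
                      to   = trimws(vapply(parts, `[`, "", 2L)),
                      stringsAsFactors = FALSE))
  }
  ed <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(ed) < 2L) stop("'edges' needs two columns (from, to)")
  data.frame(from = as.character(ed[[1L]]), to = as.character(ed[[2L]]),
             stringsAsFactors = FALSE)
}

#' @export
print.digraph <- function(x, ...) {
  cat("digraph with", length(x$nodes), "nodes and", nrow(x$edges), "edges\n")
  cat("nodes:", paste(x$nodes, collapse = ", "), "\n")
  if (nrow(x$edges))
    cat("edges:", paste(paste0(x$edges$from, " -> ", x$edges$to),
                        collapse = ", "), "\n")
  invisible(x)
}

#' @rdname digraph
#' @param g A \code{digraph}.
#' @export
graph_nodes <- function(g) {
  stopifnot(inherits(g, "digraph"))
  g$nodes
}

#' @rdname digraph
#' @export
graph_edges <- function(g) {
  stopifnot(inherits(g, "digraph"))
  g$edges
}

#' @rdname digraph
#' @export
n_nodes <- function(g) length(graph_nodes(g))

check_nodes <- function(g, v, what = "node") {
  unknown <- setdiff(v, g$nodes)
  if (length(unknown))
    stop("unknown ", what, "(s): ", paste(unknown, collapse = ", "))
  invisible(v)
}

#' Adjacency matrix
#'
#' @param g A \code{digraph}.
#' @return A 0/1 matrix \code{A} with \code{A[from, to] = 1} for every edge.
#' @export
adjacency_matrix <- function(g) {
  stopifnot(inherits(g, "digraph"))
  m <- length(g$nodes)
  A <- matrix(0L, m, m, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges)) A[cbind(g$edges$from, g$edges$to)] <- 1L
  A
}

children_list <- function(g) {
  out <- lapply(g$nodes, function(v) g$edges$to[g$edges$from == v])
  names(out) <- g$nodes
  out
}

#' Parent sets of every node
#'
#' \code{PA(t)} contains every node \code{s} with an edge \code{s -> t}
#' (the direct causes of \code{t} when the graph is causal).
#'
#' @param g A \code{digraph}.
#' @return Named list, one character vector of parents per node, in node
#'   order.
#' @export
parent_sets <- function(g) {
  stopifnot(inherits(g, "digraph"))
  out <- lapply(g$nodes, function(v) g$edges$from[g$edges$to == v])
  names(out) <- g$nodes
  out
}

#' Ancestors of a node
#'
#' All nodes with a directed path into \code{t}, plus \code{t} itself
#' (the self-inclusive convention used throughout the moralization
#' machinery).
#'
#' @param g A \code{digraph}.
#' @param t A node identifier.
#' @return Character vector of ancestors in node order.
#' @export
ancestors <- function(g, t) {
  stopifnot(inherits(g, "digraph"), length(t) == 1L)
  check_nodes(g, t)
  pa <- parent_sets(g)
  seen <- t
  frontier <- t
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(pa[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  g$nodes[g$nodes %in% seen]
}

#' Descendants of a node
#'
#' All nodes reachable from \code{s} by a directed path, plus \code{s}
#' itself.
#'
#' @param g A \code{digraph}.
#' @param s A node identifier.
#' @return Character vector of descendants in node order.
#' @export
descendants <- function(g, s) {
  stopifnot(inherits(g, "digraph"), length(s) == 1L)
  check_nodes(g, s)
  ch <- children_list(g)
  seen <- s
  frontier <- s
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(ch[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  g$nodes[g$nodes %in% seen]
}

#' Is the graph acyclic?
#'
#' Kahn's topological sort; \code{TRUE} when a full ordering exists.
#'
#' @param g A \code{digraph}.
#' @export
is_acyclic <- function(g) {
  !is.null(topological_order(g))
}

# topological order, or NULL when the graph has a cycle
topological_order <- function(g) {
  indeg <- vapply(parent_sets(g), length, 1L)
  ch <- children_list(g)
  order <- character(0)
  avail <- names(indeg)[indeg == 0L]
  while (length(avail)) {
    v <- avail[1L]
    avail <- avail[-1L]
    order <- c(order, v)
    for (w in ch[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) avail <- c(avail, w)
    }
  }
  if (length(order) < length(g$nodes)) NULL else order
}

#' Undirected graph
#'
#' Symmetric, self-loop-free undirected graph; edges stored with endpoints
#' in node order so each unordered pair appears once.
#'
#' @param nodes Character vector of node identifiers.
#' @param edges Two-column edge input as in \code{\link{digraph}}; orientation
#'   is ignored.
#' @export
ugraph <- function(nodes, edges = NULL) {
  ed <- as_edge_df(edges)
  if (any(ed$from == ed$to)) stop("self-loops are not allowed")
  unknown <- setdiff(unique(c(ed$from, ed$to)), nodes)
  if (length(unknown))
    stop("edge endpoints not among declared nodes: ",
         paste(unknown, collapse = ", "))
  idx <- match(ed$from, nodes) > match(ed$to, nodes)
  tmp <- ed$from[idx]; ed$from[idx] <- ed$to[idx]; ed$to[idx] <- tmp
  ed <- unique(ed)
  structure(list(nodes = nodes, edges = ed), class = "ugraph")
}

#' @export
print.ugraph <- function(x, ...) {
  cat("undirected graph with", length(x$nodes), "nodes and",
      nrow(x$edges), "edges\n")
  if (nrow(x$edges))
    cat("edges:", paste(paste0(x$edges$from, " - ", x$edges$to),
                        collapse = ", "), "\n")
  invisible(x)
}

has_uedge <- function(ug, a, b) {
  any((ug$edges$from == a & ug$edges$to == b) |
      (ug$edges$from == b & ug$edges$to == a))
}

#' Ancestral moral graph
#'
#' The three-step construction behind d-separation: (1) restrict the graph
#' to the ancestral closure of \code{A}; (2) marry every pair of parents
#' sharing a child ("moralization"); (3) drop edge directions.
#'
#' @param g A \code{digraph}.
#' @param A Character vector of nodes whose ancestral closure is taken.
#' @return A \code{\link{ugraph}} on the ancestral closure of \code{A}.
#' @export
moralize_ancestral <- function(g, A) {
  stopifnot(inherits(g, "digraph"))
  check_nodes(g, A)
  keep <- unique(unlist(lapply(A, ancestors, g = g), use.names = FALSE))
  keep <- g$nodes[g$nodes %in% keep]
  ed <- g$edges[g$edges$from %in% keep & g$edges$to %in% keep, ,
                drop = FALSE]
  sub <- digraph(keep, ed)
  extra <- list()
  for (pa in parent_sets(sub)) {
    if (length(pa) >= 2L) {
      prs <- utils::combn(pa, 2L)
      extra[[length(extra) + 1L]] <-
        data.frame(from = prs[1L, ], to = prs[2L, ],
                   stringsAsFactors = FALSE)
    }
  }
  all_ed <- rbind(ed[, c("from", "to")], do.call(rbind, extra))
  ugraph(keep, all_ed)
}

#' d-separation
#'
#' Are the nodes in \code{A} d-separated from the nodes in \code{B} by
#' \code{C}? Computed on the moralized ancestral graph of the union: after
#' deleting \code{C}, \code{A} and \code{B} must lie in different connected
#' components (equivalently, every path between them passes through
#' \code{C}).
#'
#' @param g A \code{digraph}.
#' @param A,B,C Pairwise-disjoint node sets (\code{C} may be empty).
#' @return \code{TRUE} when \code{A} and \code{B} are d-separated by
#'   \code{C}. Empty \code{A} or \code{B} is vacuously separated (with a
#'   warning).
#' @export
d_separated <- function(g, A, B, C = character()) {
  stopifnot(inherits(g, "digraph"))
  check_nodes(g, c(A, B, C))
  if (length(intersect(A, B)) || length(intersect(A, C)) ||
      length(intersect(B, C)))
    stop("A, B and C must be pairwise disjoint")
  if (!length(A) || !length(B)) {
    warning("empty A or B: d-separation holds vacuously")
    return(TRUE)
  }
  mg <- moralize_ancestral(g, unique(c(A, B, C)))
  keep <- setdiff(mg$nodes, C)
  ed <- mg$edges[mg$edges$from %in% keep & mg$edges$to %in% keep, ,
                 drop = FALSE]
  # BFS from A over the pruned moral graph
  adj <- lapply(keep, function(v)
    c(ed$to[ed$from == v], ed$from[ed$to == v]))
  names(adj) <- keep
  seen <- intersect(A, keep)
  frontier <- seen
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  !any(B %in% seen)
}

#' Graph-theoretic transitive reduction
#'
#' The unique minimal edge subset of an acyclic graph with the same
#' reachability relation (Aho-Garey-Ullman). For a DAG an edge
#' \code{u -> v} is redundant exactly when \code{v} stays reachable from
#' \code{u} after removing that edge. Distinct from the data-driven
#' correlation criterion in \code{\link{transitive_reduce_weighted}}.
#'
#' @param g An acyclic \code{digraph}.
#' @return A \code{digraph} with the redundant edges removed.
#' @export
transitive_reduction_graph <- function(g) {
  stopifnot(inherits(g, "digraph"))
  if (!is_acyclic(g))
    stop("transitive reduction requires an acyclic graph ",
         "(uniqueness fails on cyclic input)")
  keep <- rep(TRUE, nrow(g$edges))
  for (i in seq_len(nrow(g$edges))) {
    u <- g$edges$from[i]; v <- g$edges$to[i]
    gg <- digraph(g$nodes, g$edges[-i, , drop = FALSE])
    if (v %in% descendants(gg, u)) keep[i] <- FALSE
  }
  digraph(g$nodes, g$edges[keep, , drop = FALSE])
}

#' Sufficient number of single-node experiments
#'
#' Upper bound on the number of single-node interventions sufficient to
#' orient a causal graph over \code{m} variables, implemented as
#' \code{ceiling(log2(m))}. This convention reproduces the standard worked
#' examples (m = 3 needs 2 experiments, m = 10 needs 4); note that the
#' frequently quoted "log(m) + 1" form disagrees numerically with those
#' examples unless the ceiling convention is used. For \code{m = 1} there is
#' nothing to orient and the bound is 0.
#'
#' @param m Positive integer number of variables.
#' @return Non-negative integer.
#' @examples
#' sufficient_intervention_bound(3)  # 2
#' sufficient_intervention_bound(10) # 4
#' @export
sufficient_intervention_bound <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1 ||
      m != round(m))
    stop("'m' must be a single integer >= 1")
  as.integer(ceiling(log2(m)))
}

# all directed simple paths from s to t with at most max_len edges;
# returns list of character vectors (node sequences). attr "truncated" is
# TRUE when the length cap cut off the search somewhere.
directed_paths <- function(g, s, t, max_len = Inf) {
  ch <- children_list(g)
  paths <- list()
  truncated <- FALSE
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t && length(path) > 1L) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    if (length(path) - 1L >= max_len) {
      if (length(ch[[v]])) truncated <<- TRUE
      return(invisible())
    }
    for (w in ch[[v]]) {
      if (w == t) {
        paths[[length(paths) + 1L]] <<- c(path, w)
      } else if (!(w %in% path)) {
        walk(c(path, w))
      }
    }
    invisible()
  }
  if (s == t) stop("path endpoints must differ")
  walk(s)
  attr(paths, "truncated") <- truncated
  paths
}
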