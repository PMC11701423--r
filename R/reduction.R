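#' Data-driven transitive-reduction criterion for one edge
#'
#' The minimum-coefficient pruning heuristic: edge \code{s -> t} is marked
#' for removal when some alternative directed path \code{s -> ... -> t}
#' (length at least 2) has all of its edge weights larger in absolute
#' value than the weight of the direct edge, i.e. when
#' \code{min |w(path)| > |w(s,t)|} (strict inequality; exact ties keep the
#' edge). The heuristic is not consistent: a true direct edge whose
#' coefficient partially cancels the indirect paths can be removed even at
#' population weights.
#'
#' @param pg A \code{\link{perturbation_graph}} with weights on all edges.
#' @param s,t Endpoints of an existing edge \code{s -> t}.
#' @param max_path_length Cap on the number of edges per enumerated path
#'   (default 6); a warning is emitted when the cap truncates the search.
#' @return List with \code{keep} (logical), \code{weight}, and
#'   \code{report}: a data frame of alternative paths with their minimum
#'   absolute weight and whether each triggers removal.
#' @export
tr_criterion_keep <- function(pg, s, t, max_path_length = 6L) {
  stopifnot(inherits(pg, "perturbation_graph"))
  g <- pg$graph
  check_nodes(g, c(s, t))
  if (!any(g$edges$from == s & g$edges$to == t))
    stop("no edge ", s, "->", t, " in the perturbation graph")
  w_direct <- pg_weight(pg, s, t)
  paths <- directed_paths(g, s, t, max_len = max_path_length)
  if (isTRUE(attr(paths, "truncated")))
    warning("path enumeration truncated at length ", max_path_length,
            "; increase max_path_length for a complete search")
  paths <- Filter(function(p) length(p) > 2L, paths)
  if (!length(paths)) {
    return(list(keep = TRUE, weight = w_direct,
                report = data.frame(path = character(),
                                    min_abs_weight = numeric(),
                                    triggers = logical())))
  }
  mins <- vapply(paths, function(p) {
    min(abs(vapply(seq_len(length(p) - 1L), function(i)
      pg_weight(pg, p[i], p[i + 1L]), 0)))
  }, 0)
  trig <- mins > abs(w_direct)
  report <- data.frame(
    path = vapply(paths, paste, "", collapse = "->"),
    min_abs_weight = mins, triggers = trig,
    stringsAsFactors = FALSE)
  list(keep = !any(trig), weight = w_direct, report = report)
}

#' Weighted transitive reduction of a perturbation graph
#'
#' Applies \code{\link{tr_criterion_keep}} to every edge. By default the
#' criterion is evaluated in a single pass against the original edge set,
#' so the output does not depend on edge order; \code{iterate = TRUE}
#' re-evaluates against the shrinking graph until a fixed point (an
#' order-dependent variant offered for comparison with cascading
#' implementations).
#'
#' @inheritParams tr_criterion_keep
#' @param iterate Re-prune against the current graph until stable.
#' @return The pruned \code{\link{digraph}}, with a per-edge decision log
#'   in \code{attr(., "log")} (columns \code{source, target, weight, kept,
#'   triggering_path}).
#' @export
transitive_reduce_weighted <- function(pg, max_path_length = 6L,
                                       iterate = FALSE) {
  stopifnot(inherits(pg, "perturbation_graph"))
  prune_once <- function(pg) {
    ed <- pg$graph$edges
    log <- vector("list", nrow(ed))
    keep <- rep(TRUE, nrow(ed))
    for (i in seq_len(nrow(ed))) {
      res <- tr_criterion_keep(pg, ed$from[i], ed$to[i], max_path_length)
      keep[i] <- res$keep
      trigger <- if (res$keep) NA_character_ else
        res$report$path[which(res$report$triggers)[1L]]
      log[[i]] <- data.frame(source = ed$from[i], target = ed$to[i],
                             weight = res$weight, kept = res$keep,
                             triggering_path = trigger,
                             stringsAsFactors = FALSE)
    }
    list(graph = digraph(pg$graph$nodes, ed[keep, , drop = FALSE]),
         log = do.call(rbind, log))
  }
  res <- prune_once(pg)
  log <- res$log
  if (iterate) {
    repeat {
      cur <- perturbation_graph(res$graph, pg$weights,
                                alpha = pg$alpha, method = pg$method)
      nxt <- prune_once(cur)
      if (nrow(nxt$graph$edges) == nrow(res$graph$edges)) break
      res <- nxt
      log <- rbind(log, nxt$log)
    }
  }
  out <- res$graph
  attr(out, "log") <- log
  out
}

#' Compare an estimated graph with the truth
#'
#' Edge precision and recall over directed edges plus the structural
#' Hamming distance (SHD), counting each differing unordered node pair as
#' one edit so an edge reversal costs 1.
#'
#' @param estimate,truth \code{\link{digraph}}s on the same node set.
#' @return List with \code{edge_precision}, \code{edge_recall},
#'   \code{structural_hamming_distance}. An empty estimate has precision 1
#'   by convention (no false positives).
#' @export
compare_graphs <- function(estimate, truth) {
  stopifnot(inherits(estimate, "digraph"), inherits(truth, "digraph"))
  if (!setequal(estimate$nodes, truth$nodes))
    stop("graphs must share the same node set")
  key <- function(g) paste(g$edges$from, g$edges$to, sep = "\r")
  ke <- key(estimate); kt <- key(truth)
  tp <- length(intersect(ke, kt))
  precision <- if (length(ke)) tp / length(ke) else 1
  recall <- if (length(kt)) tp / length(kt) else 1
  # SHD over unordered pairs: any difference in the pair's edge
  # configuration (absent / -> / <- / both) counts once
  pair_state <- function(g, a, b) {
    paste(as.integer(any(g$edges$from == a & g$edges$to == b)),
          as.integer(any(g$edges$from == b & g$edges$to == a)))
  }
  nodes <- truth$nodes
  shd <- 0L
  if (length(nodes) >= 2L) {
    prs <- utils::combn(nodes, 2L)
    for (i in seq_len(ncol(prs))) {
      a <- prs[1L, i]; b <- prs[2L, i]
      if (pair_state(estimate, a, b) != pair_state(truth, a, b))
        shd <- shd + 1L
    }
  }
  list(edge_precision = precision, edge_recall = recall,
       structural_hamming_distance = shd)
}
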