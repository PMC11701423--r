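#' Per-context Pearson correlation
#'
#' Correlation between two variables over the rows of a single context.
#'
#' @param data A \code{\link{multi_context_data}}.
#' @param s,t Variable names.
#' @param label Context label.
#' @return List with \code{r} and \code{n}.
#' @export
context_correlation <- function(data, s, t, label) {
  data <- as_multi_context_data(data)
  check_vars(data, c(s, t))
  check_labels(data, label)
  rows <- mcd_context(data) == label
  n <- sum(rows)
  if (n < 4L) stop("need at least 4 rows in context '", label, "'")
  x <- data[[s]][rows]; y <- data[[t]][rows]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in context '", label, "'")
  list(r = stats::cor(x, y), n = n)
}

#' Pooled (conditional) correlation
#'
#' The conditional correlation of the perturbation-graph literature: a
#' plain Pearson correlation computed over the pooled rows of the
#' observational context and the intervention-on-\code{s} context, with the
#' means taken over the pool. Because the pool is a mixture of two context
#' distributions, a non-zero pooled correlation does not by itself witness
#' a directed path; see \code{\link{marginal_invariance_test}}.
#'
#' @inheritParams context_correlation
#' @param obs_label Label of the observational context.
#' @param int_label Label of the intervention context being pooled with it.
#' @return Pearson correlation over the pooled rows.
#' @export
conditional_correlation <- function(data, s, t, int_label,
                                    obs_label = "obs") {
  data <- as_multi_context_data(data)
  check_vars(data, c(s, t))
  check_labels(data, c(obs_label, int_label))
  rows <- mcd_context(data) %in% c(obs_label, int_label)
  n1 <- sum(mcd_context(data) == obs_label)
  n2 <- sum(mcd_context(data) == int_label)
  if (n1 != n2)
    warning("pooled correlation with unequal context sizes (",
            n1, " vs ", n2, "); the mixture interpretation assumes ",
            "contexts of equal probability")
  x <- data[[s]][rows]; y <- data[[t]][rows]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero pooled variance")
  stats::cor(x, y)
}

#' Test equality of correlations across contexts
#'
#' Fisher-z two-sample test of the hypothesis that the correlation between
#' \code{s} and \code{t} is the same in the observational context and in
#' the intervention-on-\code{s} context (marginal invariance). Marginal
#' invariance is what licenses pooling the two contexts into a single
#' conditional correlation.
#'
#' @inheritParams conditional_correlation
#' @param alpha Significance level for the reported decision.
#' @return List with \code{p}, \code{decision} ("marginally invariant" when
#'   \code{p > alpha}), \code{r_obs}, \code{r_int}, \code{n_obs},
#'   \code{n_int}.
#' @export
marginal_invariance_test <- function(data, s, t, int_label,
                                     obs_label = "obs", alpha = 0.05) {
  data <- as_multi_context_data(data)
  c1 <- context_correlation(data, s, t, obs_label)
  c2 <- context_correlation(data, s, t, int_label)
  if (c1$n < 5L || c2$n < 5L)
    stop("need at least 5 rows per context for the Fisher-z test")
  if (abs(c1$r) >= 1 - 1e-12 || abs(c2$r) >= 1 - 1e-12)
    stop("|r| = 1: Fisher z is undefined; jitter the data or handle ",
         "the exact linear dependence explicitly")
  z <- (atanh(c1$r) - atanh(c2$r)) /
    sqrt(1 / (c1$n - 3) + 1 / (c2$n - 3))
  p <- 2 * stats::pnorm(-abs(z))
  list(p = p,
       decision = if (p > alpha) "marginally invariant" else
         "not marginally invariant",
       r_obs = c1$r, r_int = c2$r, n_obs = c1$n, n_int = c2$n)
}

#' Test for a change in distribution
#'
#' Two-sample test comparing the marginal distribution of \code{t} between
#' the observational context and a named intervention context: the
#' Kolmogorov-Smirnov test (largest absolute discrepancy of the two
#' empirical CDFs; the default) or Welch's t test on the means.
#'
#' @inheritParams conditional_correlation
#' @param t Variable whose distribution is compared.
#' @param label Intervention context label.
#' @param method \code{"ks"} or \code{"welch"}.
#' @param exact Passed to \code{\link[stats]{ks.test}} (default lets
#'   \code{ks.test} decide by sample size).
#' @return p-value.
#' @export
distribution_change_test <- function(data, t, label, obs_label = "obs",
                                     method = c("ks", "welch"),
                                     exact = NULL) {
  method <- match.arg(method)
  data <- as_multi_context_data(data)
  check_vars(data, t)
  check_labels(data, c(obs_label, label))
  x <- data[[t]][mcd_context(data) == obs_label]
  y <- data[[t]][mcd_context(data) == label]
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 rows in each context")
  if (method == "ks") {
    suppressWarnings(stats::ks.test(x, y, exact = exact))$p.value
  } else {
    stats::t.test(x, y)$p.value
  }
}

#' Perturbation graph constructor (low level)
#'
#' Builds a perturbation-graph object from an existing \code{digraph} and
#' per-edge weights, without any testing. Used for population-level
#' analyses and for re-loading graphs from disk;
#' \code{\link{build_perturbation_graph}} is the data-driven entry point.
#'
#' @param graph A \code{\link{digraph}}.
#' @param weights Data frame with columns \code{source}, \code{target},
#'   \code{weight} covering every edge of \code{graph} (extra rows allowed),
#'   or a numeric vector aligned with \code{graph_edges(graph)}.
#' @param evidence Optional per-pair evidence data frame (see
#'   \code{\link{build_perturbation_graph}}).
#' @param alpha,method Bookkeeping fields.
#' @export
perturbation_graph <- function(graph, weights, evidence = NULL,
                               alpha = NA_real_, method = NA_character_) {
  stopifnot(inherits(graph, "digraph"))
  ed <- graph$edges
  if (is.numeric(weights) && is.null(dim(weights))) {
    if (length(weights) != nrow(ed))
      stop("'weights' must have one entry per edge")
    weights <- data.frame(source = ed$from, target = ed$to,
                          weight = as.numeric(weights),
                          stringsAsFactors = FALSE)
  }
  weights <- as.data.frame(weights)
  if (!all(c("source", "target", "weight") %in% names(weights)))
    stop("'weights' needs columns source, target, weight")
  key_w <- paste(weights$source, weights$target, sep = "\r")
  key_e <- paste(ed$from, ed$to, sep = "\r")
  if (!all(key_e %in% key_w))
    stop("missing weight for edge(s): ",
         paste(paste0(ed$from, "->", ed$to)[!(key_e %in% key_w)],
               collapse = ", "))
  structure(list(graph = graph, weights = weights, evidence = evidence,
                 alpha = alpha, method = method),
            class = "perturbation_graph")
}

#' @export
print.perturbation_graph <- function(x, ...) {
  cat("perturbation graph (alpha =", x$alpha, ", method =", x$method,
      ")\n")
  print(x$graph)
  invisible(x)
}

# weight of edge s->t in a perturbation graph
pg_weight <- function(pg, s, t) {
  w <- pg$weights
  hit <- w$source == s & w$target == t
  if (!any(hit)) stop("no weight recorded for edge ", s, "->", t)
  w$weight[which(hit)[1L]]
}

#' Estimate a perturbation graph from multi-context data
#'
#' For every single-target intervention context (on node \code{s}) and
#' every other node \code{t}, tests whether the distribution of \code{t}
#' changed relative to the observational context and draws the edge
#' \code{s -> t} when the (multiplicity-corrected) p-value is at most
#' \code{alpha}. An edge therefore witnesses a directed path
#' \code{s -> ... -> t} (an ancestor relation), not a direct cause. Full
#' per-pair evidence (per-context and pooled correlations, change and
#' invariance p-values) is attached.
#'
#' @param data A \code{\link{multi_context_data}}.
#' @param design Optional \code{\link{context_design}} declaring which
#'   context intervenes on which node. Without it, every non-\code{obs}
#'   label whose name is a variable is taken as a single-target
#'   intervention on that variable (the package's labelling convention).
#' @param alpha Edge-decision level (default .05).
#' @param method Change test, \code{"ks"} or \code{"welch"}.
#' @param multiplicity Per-source correction across the m-1 targets:
#'   \code{"holm"} (default), \code{"bonferroni"} or \code{"none"}.
#' @param obs_label Label of the observational context.
#' @return A \code{\link{perturbation_graph}}: \code{graph} holds the
#'   decided edges, \code{weights} the pooled correlations, and
#'   \code{evidence} one row per tested (source, target) pair with columns
#'   \code{source, target, r_obs, r_int, r_pooled, p_change, p_change_adj,
#'   p_invariance, n_obs, n_int, edge}.
#' @export
build_perturbation_graph <- function(data, design = NULL, alpha = 0.05,
                                     method = c("ks", "welch"),
                                     multiplicity = c("holm", "bonferroni",
                                                      "none"),
                                     obs_label = "obs") {
  method <- match.arg(method)
  multiplicity <- match.arg(multiplicity)
  data <- as_multi_context_data(data)
  vars <- mcd_vars(data)
  check_labels(data, obs_label)
  if (!is.null(design)) {
    stopifnot(inherits(design, "context_design"))
    ivs <- lapply(design$contexts, `[[`, "intervention")
    labs <- design$labels
    keep <- vapply(ivs, function(x) x$kind != "none", TRUE)
    src <- lapply(ivs[keep], `[[`, "targets")
    labs <- labs[keep]
  } else {
    labs <- setdiff(unique(mcd_context(data)), obs_label)
    src <- as.list(labs)
  }
  multi <- lengths(src) != 1L | !vapply(src, function(s)
    all(s %in% vars), TRUE)
  if (any(multi)) {
    warning("skipping context(s) without a single known target: ",
            paste(labs[multi], collapse = ", "))
    labs <- labs[!multi]
    src <- src[!multi]
  }
  if (!length(labs))
    stop("at least one single-target intervention context is required")
  ev <- list()
  for (i in seq_along(labs)) {
    s <- src[[i]][1L]
    lab <- labs[i]
    targets <- setdiff(vars, s)
    p_change <- vapply(targets, function(t)
      distribution_change_test(data, t, lab, obs_label, method), 0)
    p_adj <- switch(multiplicity,
                    none = p_change,
                    holm = stats::p.adjust(p_change, "holm"),
                    bonferroni = stats::p.adjust(p_change, "bonferroni"))
    for (j in seq_along(targets)) {
      t <- targets[j]
      inv <- tryCatch(
        suppressWarnings(
          marginal_invariance_test(data, s, t, lab, obs_label, alpha)),
        error = function(e) NULL)
      r_pool <- tryCatch(
        suppressWarnings(
          conditional_correlation(data, s, t, lab, obs_label)),
        error = function(e) NA_real_)
      ev[[length(ev) + 1L]] <- data.frame(
        source = s, target = t,
        r_obs = if (is.null(inv)) NA_real_ else inv$r_obs,
        r_int = if (is.null(inv)) NA_real_ else inv$r_int,
        r_pooled = r_pool,
        p_change = p_change[j], p_change_adj = p_adj[j],
        p_invariance = if (is.null(inv)) NA_real_ else inv$p,
        n_obs = sum(mcd_context(data) == obs_label),
        n_int = sum(mcd_context(data) == lab),
        edge = p_adj[j] <= alpha,
        stringsAsFactors = FALSE)
    }
  }
  ev <- do.call(rbind, ev)
  ev <- ev[order(ev$source, ev$target), , drop = FALSE]
  rownames(ev) <- NULL
  edges <- ev[ev$edge, c("source", "target"), drop = FALSE]
  names(edges) <- c("from", "to")
  g <- digraph(vars, edges)
  w <- data.frame(source = ev$source, target = ev$target,
                  weight = ev$r_pooled, stringsAsFactors = FALSE)
  perturbation_graph(g, w, evidence = ev, alpha = alpha, method = method)
}

#' Population-level perturbation graph of a model
#'
#' The perturbation graph that infinite data would produce: an edge
#' \code{s -> t} for every strict descendant \code{t} of \code{s} in the
#' model's graph, weighted by the model's implied observational
#' correlation between the pair (under marginal invariance the pooled
#' conditional correlation coincides with it). Serves as the oracle
#' against which the data-driven estimate and the pruning criterion are
#' evaluated.
#'
#' @param model A \code{\link{sem_model}}.
#' @return A \code{\link{perturbation_graph}}.
#' @export
population_perturbation_graph <- function(model) {
  stopifnot(inherits(model, "sem_model"))
  g <- model$graph
  mom <- implied_moments(model)
  R <- stats::cov2cor(mom$cov)
  ed <- list()
  for (s in g$nodes) {
    for (t in setdiff(descendants(g, s), s)) {
      ed[[length(ed) + 1L]] <- data.frame(
        source = s, target = t, weight = R[s, t],
        stringsAsFactors = FALSE)
    }
  }
  w <- if (length(ed)) do.call(rbind, ed) else
    data.frame(source = character(), target = character(),
               weight = numeric())
  pg_graph <- digraph(g$nodes, w[, c("source", "target")])
  perturbation_graph(pg_graph, w, alpha = NA_real_,
                     method = "population")
}
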