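#' Linear Gaussian structural equation model
#'
#' Each variable is a linear function of its graph parents plus independent
#' Gaussian noise: \code{X[t] = sum_s B[t,s] X[s] + eps[t]} with
#' \code{eps[t] ~ N(noise_mean[t], noise_var[t])}. \code{B[t, s]} is the
#' coefficient of the edge \code{s -> t}, so \code{B} is non-zero exactly on
#' the transposed adjacency pattern. Cyclic graphs are allowed provided the
#' spectral radius of \code{B} is below 1, in which case the model is read
#' at its equilibrium \code{X = (I - B)^{-1} eps}.
#'
#' @param graph A \code{\link{digraph}}.
#' @param beta Edge coefficients: either a numeric vector aligned with
#'   \code{graph_edges(graph)} rows, or a full m-by-m matrix with
#'   \code{beta[t, s]} the weight of edge \code{s -> t}.
#' @param noise_mean Per-node noise means (scalar recycled).
#' @param noise_var Per-node noise variances, strictly positive (scalar
#'   recycled).
#' @return An object of class \code{sem_model}: list with \code{graph},
#'   \code{B}, \code{noise_mean}, \code{noise_var}.
#' @examples
#' g <- digraph(c("s", "u", "t"), c("s->u", "u->t"))
#' m <- sem_model(g, beta = c(1, 1))
#' implied_moments(m)$cov
#' @export
sem_model <- function(graph, beta, noise_mean = 0, noise_var = 1) {
  stopifnot(inherits(graph, "digraph"))
  nd <- graph$nodes
  m <- length(nd)
  ed <- graph$edges
  if (is.matrix(beta)) {
    if (!all(dim(beta) == m)) stop("'beta' matrix must be m x m")
    B <- beta
    dimnames(B) <- list(nd, nd)
  } else {
    if (length(beta) != nrow(ed))
      stop("'beta' must have one coefficient per edge (",
           nrow(ed), " edges)")
    B <- matrix(0, m, m, dimnames = list(nd, nd))
    if (nrow(ed)) B[cbind(ed$to, ed$from)] <- beta
  }
  # coefficient pattern must match the edge set exactly
  A <- adjacency_matrix(graph)
  if (any((B != 0) != (t(A) == 1L)))
    stop("non-zero pattern of 'beta' must match the edge set ",
         "(B[t,s] != 0 iff s->t is an edge)")
  noise_mean <- rep_len(as.numeric(noise_mean), m)
  noise_var <- rep_len(as.numeric(noise_var), m)
  names(noise_mean) <- names(noise_var) <- nd
  if (any(noise_var <= 0)) stop("noise variances must be > 0")
  if (!is_acyclic(graph)) {
    rho <- max(abs(eigen(B, only.values = TRUE)$values))
    if (rho >= 1)
      stop("cyclic model requires spectral radius of B < 1 (got ",
           signif(rho, 4), ")")
  }
  structure(list(graph = graph, B = B, noise_mean = noise_mean,
                 noise_var = noise_var),
            class = "sem_model")
}

#' @export
print.sem_model <- function(x, ...) {
  cat("linear Gaussian SEM on", length(x$graph$nodes), "nodes,",
      nrow(x$graph$edges), "edges",
      if (!is_acyclic(x$graph)) "(cyclic)" else "", "\n")
  ed <- x$graph$edges
  if (nrow(ed)) {
    w <- x$B[cbind(ed$to, ed$from)]
    cat(paste0("  ", ed$from, " -> ", ed$to, "  (", signif(w, 4), ")",
               collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Intervention specification
#'
#' \describe{
#'   \item{none}{observation, the context \code{C = obs}.}
#'   \item{hard}{intervention by replacement: each target's structural
#'     equation is deleted and the variable is replaced by an external
#'     \code{W ~ N(replacement_mean, replacement_var)}; graphically, all
#'     edges into the target are cut.}
#'   \item{soft}{a shift intervention: \code{shift_mean} is added to the
#'     target's noise mean and \code{extra_var} to its noise variance while
#'     incoming edges stay intact.}
#' }
#'
#' @param kind One of \code{"none"}, \code{"hard"}, \code{"soft"}.
#' @param targets Character vector of intervened nodes (empty for
#'   \code{"none"}).
#' @param replacement_mean,replacement_var Law of the replacement variable
#'   \code{W} for hard interventions (\code{replacement_var >= 0}; zero
#'   gives a deterministic clamp).
#' @param shift_mean,extra_var Mean shift and added noise variance for soft
#'   interventions (\code{extra_var >= 0}).
#' @export
intervention <- function(kind = c("none", "hard", "soft"),
                         targets = character(),
                         replacement_mean = 2, replacement_var = 1,
                         shift_mean = 2, extra_var = 0) {
  kind <- match.arg(kind)
  targets <- as.character(targets)
  if (kind == "none" && length(targets))
    stop("'none' intervention cannot have targets")
  if (kind != "none" && !length(targets))
    stop("'", kind, "' intervention needs at least one target")
  if (kind == "hard" && replacement_var < 0)
    stop("replacement_var must be >= 0")
  if (kind == "soft" && extra_var < 0)
    stop("extra_var must be >= 0")
  structure(list(kind = kind, targets = targets,
                 replacement_mean = replacement_mean,
                 replacement_var = replacement_var,
                 shift_mean = shift_mean, extra_var = extra_var),
            class = "intervention")
}

#' Multi-context experimental design
#'
#' An ordered list of contexts, each a label, an
#' \code{\link{intervention}} and a sample size. Exactly one label (by
#' convention \code{"obs"}) must carry the no-intervention context.
#'
#' @param contexts List of \code{list(label=, intervention=, n=)} entries.
#' @export
context_design <- function(contexts) {
  stopifnot(is.list(contexts), length(contexts) >= 1L)
  labs <- vapply(contexts, function(x) as.character(x$label), "")
  if (anyDuplicated(labs))
    stop("context labels must be unique")
  kinds <- vapply(contexts, function(x) x$intervention$kind, "")
  ns <- vapply(contexts, function(x) as.numeric(x$n), 0)
  if (any(ns < 0) || any(ns != round(ns)))
    stop("sample sizes must be non-negative integers")
  if (sum(kinds == "none") != 1L)
    stop("exactly one context must be observational (kind 'none')")
  structure(list(contexts = contexts, labels = labs), class = "context_design")
}

#' @rdname context_design
#' @param nodes Nodes to intervene on, one context each (label = node name).
#' @param n Sample size per context.
#' @param kind,obs_label,... Intervention kind and parameters passed to
#'   \code{\link{intervention}}; \code{obs_label} names the observational
#'   context.
#' @details \code{single_target_design} is the workhorse layout of
#'   perturbation experiments: one observational context plus one
#'   single-node intervention context per requested node, labelled by the
#'   node's name.
#' @export
single_target_design <- function(nodes, n, kind = "hard",
                                 obs_label = "obs", ...) {
  ctx <- c(list(list(label = obs_label, intervention = intervention("none"),
                     n = n)),
           lapply(nodes, function(v)
             list(label = v, intervention = intervention(kind, v, ...),
                  n = n)))
  context_design(ctx)
}

# fold an intervention into (B, noise_mean, noise_var)
apply_intervention <- function(model, iv) {
  stopifnot(inherits(model, "sem_model"), inherits(iv, "intervention"))
  B <- model$B
  mu <- model$noise_mean
  v <- model$noise_var
  if (iv$kind != "none") {
    check_nodes(model$graph, iv$targets, "intervention target")
    if (iv$kind == "hard") {
      B[iv$targets, ] <- 0
      mu[iv$targets] <- iv$replacement_mean
      v[iv$targets] <- iv$replacement_var
    } else {
      mu[iv$targets] <- mu[iv$targets] + iv$shift_mean
      v[iv$targets] <- v[iv$targets] + iv$extra_var
    }
  }
  list(B = B, noise_mean = mu, noise_var = v)
}

#' Implied Gaussian moments
#'
#' Population mean vector and covariance matrix of the model under an
#' intervention: with intervention-modified \code{B'}, noise means
#' \code{m'} and variances \code{Psi'},
#' \code{mu = (I - B')^{-1} m'} and
#' \code{Sigma = (I - B')^{-1} Psi' (I - B')^{-T}}.
#'
#' @param model A \code{\link{sem_model}}.
#' @param iv An \code{\link{intervention}} (default: none).
#' @return List with \code{mean} (named vector) and \code{cov} (symmetric
#'   PSD matrix).
#' @export
implied_moments <- function(model, iv = intervention("none")) {
  eff <- apply_intervention(model, iv)
  m <- length(model$graph$nodes)
  IB <- diag(m) - eff$B
  rho <- max(abs(eigen(eff$B, only.values = TRUE)$values))
  if (rho >= 1)
    stop("effective coefficient matrix has spectral radius >= 1")
  inv <- tryCatch(solve(IB), error = function(e)
    stop("(I - B) is singular under this intervention"))
  mu <- drop(inv %*% eff$noise_mean)
  S <- inv %*% diag(eff$noise_var, m) %*% t(inv)
  S <- (S + t(S)) / 2
  dimnames(S) <- list(model$graph$nodes, model$graph$nodes)
  names(mu) <- model$graph$nodes
  list(mean = mu, cov = S)
}

#' Standardize a structural model
#'
#' Rescales coefficients and noise moments so that every implied marginal
#' variance equals 1 while the implied correlation matrix is unchanged:
#' with \code{D = diag(1/sd)}, the new coefficient matrix is
#' \code{D B D^{-1}} (edge weights become path coefficients in Wright's
#' sense).
#'
#' @param model An acyclic \code{\link{sem_model}}.
#' @return A \code{sem_model} whose implied marginal variances are all 1.
#' @export
standardize <- function(model) {
  stopifnot(inherits(model, "sem_model"))
  if (!is_acyclic(model$graph))
    stop("standardize() requires an acyclic model")
  mom <- implied_moments(model)
  sd <- sqrt(diag(mom$cov))
  if (any(sd <= 0)) stop("implied variance of 0; cannot standardize")
  m <- length(sd)
  B <- model$B * outer(1 / sd, sd)      # B[t,s] * sd_s / sd_t
  sem_model(model$graph, B,
            noise_mean = model$noise_mean / sd,
            noise_var = model$noise_var / sd^2)
}

#' Path-rule correlation between two nodes
#'
#' For a standardized acyclic model where every source of association
#' between \code{s} and \code{t} is a directed path \code{s -> ... -> t}
#' (no common-cause backdoor), the correlation decomposes as the sum over
#' directed paths of the product of the path coefficients along each path
#' (Wright's path rule). Models with a backdoor between the two nodes are
#' rejected with an error pointing to \code{\link{implied_moments}}, which
#' is valid for any topology.
#'
#' @param model_std A standardized acyclic \code{\link{sem_model}} (see
#'   \code{\link{standardize}}); marginal variances are checked.
#' @param s,t Source and target node.
#' @return List with \code{correlation} (sum of contributions),
#'   \code{paths} (list of node-sequence character vectors) and
#'   \code{contributions} (numeric, one product per path).
#' @export
wright_path_correlation <- function(model_std, s, t) {
  stopifnot(inherits(model_std, "sem_model"))
  g <- model_std$graph
  check_nodes(g, c(s, t))
  if (s == t) stop("'s' and 't' must differ")
  if (!is_acyclic(g)) stop("path-rule correlation requires an acyclic model")
  mom <- implied_moments(model_std)
  if (max(abs(diag(mom$cov) - 1)) > 1e-6)
    stop("model is not standardized; call standardize() first")
  # a common ancestor of s and t with a directed path to t avoiding s
  # creates a backdoor trek not covered by the directed decomposition
  g_no_s <- induced_subgraph(g, setdiff(g$nodes, s))
  for (u in setdiff(ancestors(g, s), s)) {
    if (t %in% descendants(g_no_s, u))
      stop("common-cause backdoor between '", s, "' and '", t,
           "' via '", u, "'; use implied_moments() instead")
  }
  paths <- directed_paths(g, s, t)
  contrib <- vapply(paths, function(p) {
    prod(model_std$B[cbind(p[-1L], p[-length(p)])])
  }, 0)
  list(correlation = sum(contrib), paths = paths, contributions = contrib)
}

induced_subgraph <- function(g, keep) {
  ed <- g$edges[g$edges$from %in% keep & g$edges$to %in% keep, ,
                drop = FALSE]
  digraph(g$nodes[g$nodes %in% keep], ed)
}

#' Sample a multi-context data set
#'
#' Draws i.i.d. rows from each context's implied Gaussian, in design
#' order, with a local RNG seeded by \code{seed} (the caller's RNG state is
#' left untouched; identical seeds give identical output).
#'
#' @param model A \code{\link{sem_model}}.
#' @param design A \code{\link{context_design}}.
#' @param seed Integer seed.
#' @return A \code{\link{multi_context_data}}.
#' @export
sample_contexts <- function(model, design, seed) {
  stopifnot(inherits(model, "sem_model"), inherits(design, "context_design"))
  if (missing(seed) || !is.numeric(seed))
    stop("an integer 'seed' is required for reproducibility")
  ns <- vapply(design$contexts, function(x) as.numeric(x$n), 0)
  if (all(ns == 0)) stop("all context sample sizes are 0")
  nd <- model$graph$nodes
  with_local_seed(seed, {
    blocks <- lapply(design$contexts, function(ctx) {
      if (ctx$n == 0)
        return(matrix(numeric(), 0L, length(nd),
                      dimnames = list(NULL, nd)))
      mom <- implied_moments(model, ctx$intervention)
      x <- MASS::mvrnorm(ctx$n, mu = mom$mean, Sigma = mom$cov)
      if (ctx$n == 1L) x <- matrix(x, 1L, dimnames = list(NULL, nd))
      x
    })
    labels <- rep(design$labels, times = ns)
    multi_context_data(do.call(rbind, blocks), labels)
  })
}

# evaluate expr under a locally seeded RNG, restoring the caller's state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
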