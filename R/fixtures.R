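#' Catalogue of worked-example models
#'
#' Small structural models used throughout the package's examples and
#' tests:
#' \describe{
#'   \item{fig2_chain}{\code{s -> u -> t}, unit coefficients and noise;
#'     the mediation chain whose perturbation graph gains the extra edge
#'     \code{s -> t}.}
#'   \item{fig2_fork}{\code{s <- u -> t}, unit coefficients; the common
#'     cause whose pooled correlation is non-zero even though intervening
#'     on \code{s} leaves \code{t} untouched.}
#'   \item{fig3a}{\code{s -> v -> t}, \code{s -> w -> t}, all standardized
#'     path coefficients -0.2; noise variances chosen so every marginal
#'     variance is 1, making the edge weights path coefficients. The
#'     implied corr(s, t) is exactly .08 and the minimum-coefficient
#'     pruning rule correctly removes the (absent) direct edge.}
#'   \item{fig3b}{fig3a plus the direct edge \code{s -> t} with path
#'     coefficient -0.1; corr(s, t) = -.02, and the same pruning rule now
#'     removes a true direct edge: the counterexample showing the
#'     heuristic is inconsistent.}
#'   \item{fig4a}{\code{v -> s -> u -> t}: conditioning on \code{u} makes
#'     the effect of an intervention on \code{s} vanish at \code{t}.}
#'   \item{fig4b}{fig4a plus \code{s -> t}: the intervention on \code{s}
#'     moves \code{t} no matter what is conditioned on.}
#'   \item{peters_nonnecessity}{\code{t <- u -> s -> t -> v}: the design
#'     in which interventions on only one variable already constrain the
#'     parent set of \code{t}.}
#' }
#'
#' @param name One of the names above.
#' @return A validated \code{\link{sem_model}}.
#' @examples
#' m <- fixture("fig3a")
#' wright_path_correlation(m, "s", "t")$correlation # 0.08
#' @export
fixture <- function(name) {
  catalog <- list(
    fig2_chain = function() {
      g <- digraph(c("s", "u", "t"), c("s->u", "u->t"))
      sem_model(g, beta = c(1, 1))
    },
    fig2_fork = function() {
      g <- digraph(c("s", "u", "t"), c("u->s", "u->t"))
      sem_model(g, beta = c(1, 1))
    },
    fig3a = function() {
      g <- digraph(c("s", "v", "w", "t"),
                   c("s->v", "v->t", "s->w", "w->t"))
      unit_variance_model(g, beta = c(-0.2, -0.2, -0.2, -0.2))
    },
    fig3b = function() {
      g <- digraph(c("s", "v", "w", "t"),
                   c("s->v", "v->t", "s->w", "w->t", "s->t"))
      unit_variance_model(g, beta = c(-0.2, -0.2, -0.2, -0.2, -0.1))
    },
    fig4a = function() {
      g <- digraph(c("v", "s", "u", "t"), c("v->s", "s->u", "u->t"))
      sem_model(g, beta = c(1, 1, 1))
    },
    fig4b = function() {
      g <- digraph(c("v", "s", "u", "t"),
                   c("v->s", "s->u", "u->t", "s->t"))
      sem_model(g, beta = c(1, 1, 1, 1))
    },
    peters_nonnecessity = function() {
      g <- digraph(c("u", "s", "t", "v"),
                   c("u->t", "u->s", "s->t", "t->v"))
      sem_model(g, beta = c(1, 1, 1, 1))
    })
  if (!name %in% names(catalog))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(catalog), collapse = ", "))
  catalog[[name]]()
}

# choose noise variances so every implied marginal variance is exactly 1,
# turning the edge weights into standardized path coefficients
unit_variance_model <- function(graph, beta) {
  nd <- graph$nodes
  m <- length(nd)
  B <- matrix(0, m, m, dimnames = list(nd, nd))
  B[cbind(graph$edges$to, graph$edges$from)] <- beta
  ord <- topological_order(graph)
  S <- matrix(0, m, m, dimnames = list(nd, nd))
  nv <- stats::setNames(rep(NA_real_, m), nd)
  for (t in ord) {
    b <- B[t, , drop = TRUE]
    explained <- drop(b %*% S %*% b)
    if (explained >= 1)
      stop("coefficients imply variance > 1 for node ", t)
    nv[t] <- 1 - explained
    S[t, ] <- S[, t] <- drop(S %*% b)
    S[t, t] <- 1
  }
  sem_model(graph, B, noise_mean = 0, noise_var = nv)
}

#' Random acyclic structural model
#'
#' A DAG drawn by a random topological order and independent edge
#' coin-flips, with coefficient magnitudes uniform on \code{coeff_range}
#' and random signs; unit noise. The magnitude range (default
#' \code{[0.3, 0.9]}) keeps the model away from near-cancellation, where
#' faithfulness would fail numerically.
#'
#' @param m Number of nodes (named \code{V1..Vm}).
#' @param edge_prob Probability of each forward edge.
#' @param coeff_range Length-2 positive range of coefficient magnitudes,
#'   inside (0, 1).
#' @param seed Integer seed.
#' @return A \code{\link{sem_model}}.
#' @export
random_sem <- function(m, edge_prob = 0.3, coeff_range = c(0.3, 0.9),
                       seed) {
  if (m < 1) stop("'m' must be >= 1")
  if (edge_prob < 0 || edge_prob > 1) stop("'edge_prob' must be in [0,1]")
  if (length(coeff_range) != 2L || any(coeff_range <= 0) ||
      any(coeff_range >= 1) || coeff_range[1] > coeff_range[2])
    stop("'coeff_range' must be an increasing range inside (0, 1)")
  with_local_seed(seed, {
    nodes <- paste0("V", seq_len(m))
    ord <- sample(nodes)
    ed <- list()
    if (m >= 2L) {
      for (i in seq_len(m - 1L)) {
        for (j in (i + 1L):m) {
          if (stats::runif(1) < edge_prob)
            ed[[length(ed) + 1L]] <- data.frame(from = ord[i],
                                               to = ord[j],
                                               stringsAsFactors = FALSE)
        }
      }
    }
    g <- digraph(nodes, if (length(ed)) do.call(rbind, ed) else NULL)
    k <- nrow(g$edges)
    beta <- stats::runif(k, coeff_range[1], coeff_range[2]) *
      sample(c(-1, 1), k, replace = TRUE)
    sem_model(g, beta)
  })
}

#' Synthetic Likert attitude survey
#'
#' Emulates a perturbation-design attitude survey: a latent linear
#' Gaussian model over \code{m} attitude variables is measured once
#' without intervention and once per variable under a soft mean-shift
#' intervention on that variable (m + 1 contexts in total), and every
#' column is discretized to a 1..7 Likert response by equal-probability
#' thresholds of the observational latent marginal, which keeps the
#' observational margins symmetric. This is synthetic data: it mimics the
#' design of the real survey (11 attitudes, 12 contexts), not its items.
#'
#' @param m Number of attitude variables; for \code{m = 11} the columns
#'   carry the attitude names of the motivating survey.
#' @param n_per_context Rows per context.
#' @param shift Soft-intervention mean shift in units of the target's
#'   observational SD (default 3).
#' @param edge_prob,coeff_range Latent-model topology parameters passed to
#'   \code{\link{random_sem}}.
#' @param seed Integer seed.
#' @return A \code{\link{multi_context_data}} with values in 1..7 and
#'   context labels \code{"obs"} plus one label per variable. The latent
#'   model and design are attached as attributes \code{"model"} and
#'   \code{"design"}.
#' @export
likert_survey_generator <- function(m = 11, n_per_context = 200,
                                    shift = 3, edge_prob = 0.3,
                                    coeff_range = c(0.3, 0.7), seed) {
  if (n_per_context < 1) stop("'n_per_context' must be >= 1")
  model <- random_sem(m, edge_prob, coeff_range, seed = seed)
  if (m == 11L) {
    names11 <- c("mora", "nutr", "envir", "infer", "suff", "tax",
                 "taste", "death", "sad", "guilty", "disg")
    model$graph$nodes <- names11
    model$graph$edges$from <- names11[match(model$graph$edges$from,
                                            paste0("V", 1:11))]
    model$graph$edges$to <- names11[match(model$graph$edges$to,
                                          paste0("V", 1:11))]
    dimnames(model$B) <- list(names11, names11)
    names(model$noise_mean) <- names(model$noise_var) <- names11
  }
  nodes <- model$graph$nodes
  mom <- implied_moments(model)
  sds <- sqrt(diag(mom$cov))
  ctx <- c(list(list(label = "obs", intervention = intervention("none"),
                     n = n_per_context)),
           lapply(nodes, function(v)
             list(label = v,
                  intervention = intervention("soft", v,
                                              shift_mean = shift * sds[[v]]),
                  n = n_per_context)))
  design <- context_design(ctx)
  latent <- sample_contexts(model, design, seed = seed + 1L)
  X <- mcd_matrix(latent)
  for (v in nodes) {
    thr <- stats::qnorm(seq_len(6) / 7, mean = mom$mean[[v]],
                        sd = sds[[v]])
    X[, v] <- findInterval(X[, v], thr) + 1
  }
  out <- multi_context_data(X, mcd_context(latent))
  attr(out, "model") <- model
  attr(out, "design") <- design
  out
}

#' Synthetic regime-change time series
#'
#' A stable VAR(1) with a chain transition structure
#' (\code{V1 -> V2 -> ... -> Vm} at lag 1, plus autoregression) and a mean
#' shift added to one variable's innovations from \code{break_at} onward,
#' emulating an intensive longitudinal series with an unannounced regime
#' change (the motivating application records 1478 momentary assessments
#' of four sum scores, hence the defaults). Synthetic stand-in: the real
#' series is neither downloaded nor imitated item by item.
#'
#' @param m Number of variables (\code{V1..Vm}).
#' @param n Number of time points.
#' @param break_at First time index of the new regime
#'   (\code{0 < break_at <= n}); \code{NULL} for no break.
#' @param shift_target Variable receiving the shift (name or index).
#' @param shift Innovation mean shift (the stationary mean of the target
#'   moves by \code{shift / (1 - a)} with autoregression \code{a}).
#' @param a Autoregressive and cross-lag coefficient (default .4; the
#'   transition matrix has \code{a} on the diagonal and first
#'   subdiagonal, spectral radius \code{a < 1}).
#' @param seed Integer seed.
#' @return List with \code{series} (n-by-m matrix), \code{blocks} (list of
#'   pre/post index ranges; halves when there is no break),
#'   \code{break_at} and \code{transition}.
#' @export
regime_timeseries_generator <- function(m = 4, n = 1478,
                                        break_at = floor(n / 2) + 1,
                                        shift_target = 1, shift = 2,
                                        a = 0.4, seed) {
  if (abs(a) >= 1) stop("transition coefficient must satisfy |a| < 1")
  A <- diag(a, m)
  if (m >= 2L) for (i in 2:m) A[i, i - 1L] <- a
  if (max(abs(eigen(A, only.values = TRUE)$values)) >= 1)
    stop("unstable transition matrix")
  nodes <- paste0("V", seq_len(m))
  dimnames(A) <- list(nodes, nodes)
  if (is.character(shift_target)) shift_target <- match(shift_target, nodes)
  if (!is.null(break_at) && (break_at <= 0 || break_at > n))
    stop("'break_at' must be in (0, n]")
  with_local_seed(seed, {
    X <- matrix(0, n, m, dimnames = list(NULL, nodes))
    x <- rep(0, m)
    for (i in seq_len(n)) {
      eps <- stats::rnorm(m)
      if (!is.null(break_at) && i >= break_at)
        eps[shift_target] <- eps[shift_target] + shift
      x <- drop(A %*% x) + eps
      X[i, ] <- x
    }
    blocks <- if (is.null(break_at)) {
      list(seq_len(floor(n / 2)), (floor(n / 2) + 1L):n)
    } else {
      list(seq_len(break_at - 1L), break_at:n)
    }
    list(series = X, blocks = blocks, break_at = break_at,
         transition = A)
  })
}
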