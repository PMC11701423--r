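#' Ordinary least squares on a predictor set
#'
#' Fits \code{t ~ intercept + S} over the given rows by QR least squares
#' and returns coefficients, intercept, residuals (in row order) and the
#' coefficient covariance pieces needed for confidence intervals.
#'
#' @param data A \code{\link{multi_context_data}} (or anything coercible).
#' @param t Target variable name.
#' @param S Character vector of predictor names (may be empty: the fit is
#'   then the intercept-only model and residuals are the centred target).
#' @param rows Optional logical/integer row subset.
#' @return List with \code{coefficients} (named, no intercept),
#'   \code{intercept}, \code{residuals}, \code{sigma2}, \code{se},
#'   \code{df}.
#' @export
ols_fit <- function(data, t, S = character(), rows = NULL) {
  data <- as_multi_context_data(data)
  check_vars(data, c(t, S))
  if (t %in% S) stop("'S' must not contain the target")
  X <- mcd_matrix(data)
  if (!is.null(rows)) X <- X[rows, , drop = FALSE]
  n <- nrow(X)
  p <- length(S)
  if (n < p + 2L) stop("need at least |S| + 2 rows (", p + 2L, ")")
  M <- cbind(`(Intercept)` = 1, X[, S, drop = FALSE])
  qr_ <- qr(M)
  if (qr_$rank < ncol(M))
    stop("rank-deficient design for S = {",
         paste(S, collapse = ", "), "}")
  fit <- qr.coef(qr_, X[, t])
  res <- X[, t] - drop(M %*% fit)
  df <- n - ncol(M)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qr_))
  se <- sqrt(sigma2 * diag(XtXinv))
  names(se) <- colnames(M)
  list(coefficients = fit[-1L], intercept = fit[[1L]], residuals = res,
       sigma2 = sigma2, se = se[-1L], df = df)
}

#' Invariance p-value of a predictor set
#'
#' Tests whether the conditional law of the target given the set \code{S}
#' is the same in every context: the operational core of invariant causal
#' prediction. Two tests are offered. \code{"ks_residual"} fits one pooled
#' OLS of the target on \code{S} and compares each context's residuals
#' with the residuals of the remaining rows by a two-sample
#' Kolmogorov-Smirnov test. \code{"chow"} compares, for each context
#' against the remaining rows, the regression coefficients (Chow F
#' statistic) and the residual variances (variance-ratio F). Component
#' p-values are combined by Bonferroni; with exactly two contexts the
#' single distinct comparison is used without a context correction, so the
#' combined test stays calibrated.
#'
#' @param data A \code{\link{multi_context_data}} with at least 2 contexts.
#' @param t Target variable.
#' @param S Predictor set (possibly empty).
#' @param method \code{"ks_residual"} (default) or \code{"chow"}.
#' @param exact Passed to \code{\link[stats]{ks.test}}.
#' @return Combined p-value; \code{p > alpha} is read as "S invariant".
#' @export
invariance_pvalue <- function(data, t, S = character(),
                              method = c("ks_residual", "chow"),
                              exact = NULL) {
  method <- match.arg(method)
  data <- as_multi_context_data(data)
  labs <- unique(mcd_context(data))
  if (length(labs) < 2L)
    stop("invariance testing requires >= 2 contexts")
  ctx <- mcd_context(data)
  p <- length(S)
  small <- labs[tabulate(factor(ctx, labs)) < p + 2L]
  if (length(small))
    stop("context(s) too small for the fit: ",
         paste(small, collapse = ", "))
  # with two contexts the context-vs-rest comparisons coincide; use one
  comps <- if (length(labs) == 2L) labs[1L] else labs
  if (method == "ks_residual") {
    res <- ols_fit(data, t, S)$residuals
    if (stats::sd(res) == 0) stop("constant residuals")
    pvals <- vapply(comps, function(l) {
      suppressWarnings(
        stats::ks.test(res[ctx == l], res[ctx != l],
                       exact = exact))$p.value
    }, 0)
    min(1, length(comps) * min(pvals))
  } else {
    pvals <- unlist(lapply(comps, function(l)
      chow_pair(data, t, S, ctx == l)))
    min(1, length(pvals) * min(pvals))
  }
}

# Chow-type comparison of rows 'in' against the rest: coefficient-equality
# F test and residual-variance-ratio F test; returns both p-values.
chow_pair <- function(data, t, S, inrows) {
  f1 <- ols_fit(data, t, S, rows = inrows)
  f2 <- ols_fit(data, t, S, rows = !inrows)
  fp <- ols_fit(data, t, S)
  k <- length(S) + 1L
  n <- length(fp$residuals)
  rss1 <- sum(f1$residuals^2)
  rss2 <- sum(f2$residuals^2)
  rssp <- sum(fp$residuals^2)
  Fc <- ((rssp - rss1 - rss2) / k) / ((rss1 + rss2) / (n - 2L * k))
  p_coef <- stats::pf(Fc, k, n - 2L * k, lower.tail = FALSE)
  Fv <- f1$sigma2 / f2$sigma2
  p_var <- 2 * min(stats::pf(Fv, f1$df, f2$df),
                   stats::pf(Fv, f1$df, f2$df, lower.tail = FALSE))
  c(coef = p_coef, var = min(1, p_var))
}

# all subsets of 'vars' with size <= k, empty set first, deterministic order
subsets_upto <- function(vars, k) {
  out <- list(character(0))
  for (size in seq_len(min(k, length(vars)))) {
    cmb <- utils::combn(vars, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Invariant causal prediction for one target
#'
#' Enumerates every predictor set \code{S} up to \code{max_set_size}
#' (including the empty set), keeps the sets whose invariance p-value
#' exceeds \code{alpha}, and estimates the direct causes of the target as
#' the intersection of all accepted sets. The intersection is contained in
#' the true parent set with probability at least \code{1 - alpha}; when no
#' set is accepted the model is flagged as rejected and the estimate is
#' empty. Contexts in which members of \code{S} were intervened on are
#' deliberately part of the test: interventions on parents do not disturb
#' the conditional law of the target given its parents, and that is
#' precisely the invariance being exploited.
#'
#' @param data A \code{\link{multi_context_data}} with >= 2 contexts.
#' @param t Target variable.
#' @param alpha Level of each invariance test (default .05).
#' @param max_set_size Largest predictor-set size enumerated (default
#'   \code{min(m - 1, 6)}).
#' @param method Invariance test, see \code{\link{invariance_pvalue}}.
#' @param exclude_labels Context labels dropped before the analysis
#'   (at least 2 contexts must remain). A context that intervenes
#'   directly on the target breaks the target's own mechanism, so no set
#'   can be invariant across it; excluding such contexts is what
#'   \code{\link{icp_graph}} does per target. Keeping them is also
#'   meaningful: a rejected model then signals a directly perturbed
#'   target.
#' @return An \code{icp_result}: \code{target}, \code{accepted} (list of
#'   set records with p-values, coefficients and per-member confidence
#'   intervals), \code{tests} (data frame of all sets tried),
#'   \code{parent_estimate}, \code{ci} (see
#'   \code{\link{icp_confidence_intervals}}), \code{model_rejected},
#'   \code{alpha}, \code{method}.
#' @export
icp_fit <- function(data, t, alpha = 0.05, max_set_size = NULL,
                    method = c("ks_residual", "chow"),
                    exclude_labels = character()) {
  method <- match.arg(method)
  data <- as_multi_context_data(data)
  check_vars(data, t)
  if (length(exclude_labels)) {
    check_labels(data, exclude_labels)
    keep <- !(mcd_context(data) %in% exclude_labels)
    data <- multi_context_data(mcd_matrix(data)[keep, , drop = FALSE],
                               mcd_context(data)[keep])
    if (length(unique(mcd_context(data))) < 2L)
      stop("fewer than 2 contexts remain after exclusion")
  }
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  cands <- setdiff(mcd_vars(data), t)
  if (is.null(max_set_size)) max_set_size <- min(length(cands), 6L)
  if (max_set_size < 0) stop("'max_set_size' must be >= 0")
  sets <- subsets_upto(cands, max_set_size)
  accepted <- list()
  tests <- data.frame(set = vapply(sets, function(s)
    if (length(s)) paste(s, collapse = ",") else "{}", ""),
    p = NA_real_, accepted = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(sets)) {
    S <- sets[[i]]
    p <- invariance_pvalue(data, t, S, method = method)
    tests$p[i] <- p
    if (p > alpha) {
      tests$accepted[i] <- TRUE
      fit <- ols_fit(data, t, S)
      q <- stats::qt(1 - alpha / 2, fit$df)
      accepted[[length(accepted) + 1L]] <- list(
        S = S, p = p, coeffs = fit$coefficients,
        ci_low = fit$coefficients - q * fit$se,
        ci_high = fit$coefficients + q * fit$se)
    }
  }
  model_rejected <- length(accepted) == 0L
  parent_estimate <- if (model_rejected) character(0) else
    Reduce(intersect, lapply(accepted, `[[`, "S"))
  ci <- if (model_rejected) NULL else
    ci_union(cands, accepted)
  structure(list(target = t, accepted = accepted, tests = tests,
                 parent_estimate = parent_estimate, ci = ci,
                 model_rejected = model_rejected, alpha = alpha,
                 method = method),
            class = "icp_result")
}

# union-of-intervals hull per candidate variable
ci_union <- function(cands, accepted) {
  rows <- lapply(cands, function(v) {
    lo <- 0; hi <- 0; zero <- FALSE
    for (a in accepted) {
      if (v %in% a$S) {
        lo <- min(lo, a$ci_low[[v]])
        hi <- max(hi, a$ci_high[[v]])
        if (a$ci_low[[v]] <= 0 && a$ci_high[[v]] >= 0) zero <- TRUE
      } else {
        zero <- TRUE
      }
    }
    in_all <- all(vapply(accepted, function(a) v %in% a$S, TRUE))
    if (in_all) {
      # start the hull from the sets' own intervals, not from {0}
      lo <- min(vapply(accepted, function(a) a$ci_low[[v]], 0))
      hi <- max(vapply(accepted, function(a) a$ci_high[[v]], 0))
      zero <- lo <= 0 && hi >= 0
    }
    data.frame(variable = v, lower = lo, upper = hi,
               includes_zero = zero, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Confidence intervals from the accepted sets
#'
#' For each candidate variable, the union over accepted sets of that set's
#' (1 - alpha) OLS interval for the variable, reported as the union's
#' convex hull; an accepted set that excludes the variable contributes the
#' degenerate interval {0}, so only variables appearing in every accepted
#' set can have an interval bounded away from zero.
#'
#' @param data A \code{\link{multi_context_data}}.
#' @param t Target variable.
#' @param accepted Non-empty list of accepted-set records (as in
#'   \code{icp_fit}'s result).
#' @param alpha Level (the interval level is 1 - alpha).
#' @return Data frame with \code{variable}, \code{lower}, \code{upper},
#'   \code{includes_zero}.
#' @export
icp_confidence_intervals <- function(data, t, accepted, alpha = 0.05) {
  if (!length(accepted))
    stop("no accepted sets: the model was rejected ",
         "(see 'model_rejected')")
  data <- as_multi_context_data(data)
  cands <- setdiff(mcd_vars(data), t)
  # recompute the per-set intervals at the requested level
  acc <- lapply(accepted, function(a) {
    fit <- ols_fit(data, t, a$S)
    q <- stats::qt(1 - alpha / 2, fit$df)
    list(S = a$S, p = a$p, coeffs = fit$coefficients,
         ci_low = fit$coefficients - q * fit$se,
         ci_high = fit$coefficients + q * fit$se)
  })
  ci_union(cands, acc)
}

#' @export
print.icp_result <- function(x, ...) {
  cat("invariant causal prediction for target '", x$target, "' (alpha = ",
      x$alpha, ", method = ", x$method, ")\n", sep = "")
  if (x$model_rejected) {
    cat("no invariant set found: model rejected, estimate empty\n")
    cat("(a rejected model can indicate a directly perturbed target or ",
        "an unobserved confounder; predictors may still be ancestors)\n",
        sep = "")
  } else {
    acc <- vapply(x$accepted, function(a)
      if (length(a$S)) paste(a$S, collapse = ",") else "{}", "")
    cat("accepted sets:", paste0("{", acc, "}", collapse = " "), "\n")
    cat("parent estimate (intersection):",
        if (length(x$parent_estimate))
          paste(x$parent_estimate, collapse = ", ") else "(empty)", "\n")
    if (!is.null(x$ci)) {
      cat("confidence intervals:\n")
      print(x$ci, row.names = FALSE)
    }
  }
  invisible(x)
}

#' Nodewise ICP graph
#'
#' Runs \code{\link{icp_fit}} with every variable as the target and draws
#' the edge \code{v -> t} whenever \code{v} is in the parent estimate for
#' \code{t}. For each target the contexts that intervene on the target
#' itself are excluded (its own mechanism is not invariant across them);
#' contexts intervening on other variables, including members of the
#' candidate sets, are all kept. The output may contain 2-cycles (mutual
#' parenthood across targets); they are reported via a message, not
#' forbidden, matching the cyclic-equilibrium reading of the model.
#'
#' @inheritParams icp_fit
#' @param design Optional \code{\link{context_design}} declaring which
#'   context intervenes on which node; without it, a context labelled
#'   with a variable's name is taken to intervene on that variable (the
#'   package's labelling convention).
#' @return List with \code{graph} (a \code{\link{digraph}}),
#'   \code{results} (per-target \code{icp_result}s) and \code{cycles}
#'   (data frame of mutual edges, possibly empty).
#' @export
icp_graph <- function(data, alpha = 0.05, max_set_size = NULL,
                      method = c("ks_residual", "chow"),
                      design = NULL) {
  method <- match.arg(method)
  data <- as_multi_context_data(data)
  if (length(unique(mcd_context(data))) < 2L)
    stop(">= 2 contexts required")
  vars <- mcd_vars(data)
  labels_on <- function(t) {
    if (is.null(design)) {
      intersect(unique(mcd_context(data)), t)
    } else {
      hit <- vapply(design$contexts, function(c)
        t %in% c$intervention$targets, TRUE)
      design$labels[hit]
    }
  }
  results <- lapply(vars, function(t)
    icp_fit(data, t, alpha = alpha, max_set_size = max_set_size,
            method = method, exclude_labels = labels_on(t)))
  names(results) <- vars
  ed <- list()
  for (t in vars) {
    for (v in results[[t]]$parent_estimate) {
      ed[[length(ed) + 1L]] <- data.frame(from = v, to = t,
                                          stringsAsFactors = FALSE)
    }
  }
  g <- digraph(vars, if (length(ed)) do.call(rbind, ed) else NULL)
  key <- paste(g$edges$from, g$edges$to, sep = "\r")
  rev_key <- paste(g$edges$to, g$edges$from, sep = "\r")
  mutual <- key %in% rev_key
  cycles <- g$edges[mutual & g$edges$from < g$edges$to, , drop = FALSE]
  if (nrow(cycles))
    message("2-cycle(s) in the nodewise graph: ",
            paste(paste0(cycles$from, " <-> ", cycles$to),
                  collapse = ", "))
  list(graph = g, results = results, cycles = cycles)
}
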