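#' Sequential invariant causal prediction for time series
#'
#' Splits a multivariate time series into consecutive blocks, treats the
#' blocks as contexts (a block boundary standing in for an unknown regime
#' change or intervention), and runs the ICP subset search on a lagged
#' design: the regression of the target at time i uses the concurrent
#' values of the candidate variables, their lags 1..\code{lags}, and the
#' target's own lags 1..\code{lags} as an always-included autoregressive
#' baseline. Invariance across blocks is judged with the Chow-type test of
#' \code{\link{invariance_pvalue}} (coefficient equality plus normalized
#' residual variance). The parent estimate is reported at the variable
#' level: a variable is retained when any of its columns (concurrent or
#' lagged) is needed for invariance.
#'
#' @param ts Numeric matrix, rows = time points, named columns =
#'   variables.
#' @param t Target variable name.
#' @param lags Non-negative number of lags (default 1).
#' @param blocks Either an integer k >= 2 (k consecutive equal blocks) or
#'   a list of strictly increasing, non-overlapping integer ranges of row
#'   indices.
#' @param alpha Level of each invariance test.
#' @param max_set_size Largest candidate-variable set size enumerated.
#' @return An \code{icp_result} whose \code{parent_estimate} contains
#'   variable names.
#' @export
seq_icp_fit <- function(ts, t, lags = 1L, blocks = 2L, alpha = 0.05,
                        max_set_size = NULL) {
  ts <- as.matrix(ts)
  if (!is.numeric(ts) || is.null(colnames(ts)))
    stop("'ts' must be a numeric matrix with column names")
  vars <- colnames(ts)
  if (!(t %in% vars)) stop("unknown target '", t, "'")
  n <- nrow(ts)
  if (lags < 0 || lags != round(lags)) stop("'lags' must be >= 0")
  ranges <- block_ranges(blocks, n)
  if (length(ranges) < 2L) stop("at least 2 blocks are required")
  blen <- vapply(ranges, length, 1L)
  if (lags >= min(blen)) stop("'lags' must be smaller than every block")
  cands <- setdiff(vars, t)
  if (is.null(max_set_size)) max_set_size <- min(length(cands), 6L)

  rows <- (lags + 1L):n
  block_of <- rep(NA_integer_, n)
  for (b in seq_along(ranges)) block_of[ranges[[b]]] <- b
  keep <- rows[!is.na(block_of[rows])]
  # engineered design: concurrent candidates, lags of everything
  cols <- list()
  for (v in vars) {
    if (v != t) cols[[v]] <- ts[keep, v]
    if (lags > 0) for (l in seq_len(lags))
      cols[[paste0(v, "_lag", l)]] <- ts[keep - l, v]
  }
  design <- do.call(cbind, c(list(ts[keep, t, drop = FALSE]), cols))
  colnames(design)[1L] <- t
  ctx <- paste0("block", block_of[keep])
  mdat <- multi_context_data(design, ctx)
  own_lags <- if (lags > 0) paste0(t, "_lag", seq_len(lags)) else
    character(0)
  col_group <- function(v) c(if (v != t) v,
                             if (lags > 0) paste0(v, "_lag",
                                                  seq_len(lags)))
  min_rows <- min(table(ctx))
  needed <- length(own_lags) + (max_set_size) * (lags + 1L) + 2L
  if (min_rows < needed)
    stop("blocks too short for the lagged design (need >= ", needed,
         " usable rows per block)")

  sets <- subsets_upto(cands, max_set_size)
  accepted <- list()
  tests <- data.frame(set = vapply(sets, function(s)
    if (length(s)) paste(s, collapse = ",") else "{}", ""),
    p = NA_real_, accepted = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(sets)) {
    S_cols <- c(own_lags, unlist(lapply(sets[[i]], col_group),
                                 use.names = FALSE))
    p <- invariance_pvalue(mdat, t, S_cols, method = "chow")
    tests$p[i] <- p
    if (p > alpha) {
      tests$accepted[i] <- TRUE
      fit <- ols_fit(mdat, t, S_cols)
      q <- stats::qt(1 - alpha / 2, fit$df)
      accepted[[length(accepted) + 1L]] <- list(
        S = sets[[i]], S_cols = S_cols, p = p,
        coeffs = fit$coefficients,
        ci_low = fit$coefficients - q * fit$se,
        ci_high = fit$coefficients + q * fit$se)
    }
  }
  model_rejected <- length(accepted) == 0L
  parent_estimate <- if (model_rejected) character(0) else
    Reduce(intersect, lapply(accepted, `[[`, "S"))
  structure(list(target = t, accepted = accepted, tests = tests,
                 parent_estimate = parent_estimate, ci = NULL,
                 model_rejected = model_rejected, alpha = alpha,
                 method = "chow", lags = lags,
                 blocks = ranges),
            class = "icp_result")
}

# normalise the blocks argument to a list of index vectors
block_ranges <- function(blocks, n) {
  if (is.numeric(blocks) && length(blocks) == 1L) {
    k <- as.integer(blocks)
    if (k < 2L) stop("at least 2 blocks are required")
    cut <- floor(seq(0L, n, length.out = k + 1L))
    return(lapply(seq_len(k), function(i) (cut[i] + 1L):cut[i + 1L]))
  }
  if (!is.list(blocks)) stop("'blocks' must be an integer or a list")
  ranges <- lapply(blocks, function(r) as.integer(r))
  idx <- unlist(ranges)
  if (anyDuplicated(idx)) stop("blocks must not overlap")
  if (any(idx < 1L | idx > n)) stop("block indices out of range")
  bad <- vapply(ranges, function(r)
    length(r) < 2L || any(diff(r) != 1L), TRUE)
  if (any(bad)) stop("each block must be a consecutive run of indices")
  ranges
}
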