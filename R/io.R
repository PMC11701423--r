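#' Read a multi-context CSV table
#'
#' Expects a header row, one column named \code{context} and numeric
#' remaining columns; variable order follows the header.
#'
#' @param path CSV file path.
#' @return A \code{\link{multi_context_data}}.
#' @export
read_context_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop("empty file: ", path)
  if (!"context" %in% names(df))
    stop("missing 'context' column in ", path)
  vars <- setdiff(names(df), "context")
  vals <- matrix(NA_real_, nrow(df), length(vars),
                 dimnames = list(NULL, vars))
  for (v in vars) {
    x <- suppressWarnings(as.numeric(df[[v]]))
    bad <- which(is.na(x))
    if (length(bad))
      stop("non-numeric cell at row ", bad[1L], ", column '", v, "'")
    vals[, v] <- x
  }
  multi_context_data(vals, df$context)
}

#' Write a multi-context table as CSV
#'
#' Numeric values are written at 10 significant digits so that re-running
#' a logged command reproduces the file byte for byte.
#'
#' @param data A \code{\link{multi_context_data}}.
#' @param path Output path.
#' @export
write_context_table <- function(data, path) {
  data <- as_multi_context_data(data)
  X <- mcd_matrix(data)
  out <- data.frame(context = mcd_context(data),
                    apply(X, 2L, function(col) sprintf("%.10g", col)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a graph to disk
#'
#' @param g A \code{\link{digraph}} (a \code{\link{perturbation_graph}} is
#'   accepted for \code{edge_csv}, adding its weight column).
#' @param path Output path.
#' @param format \code{"edge_csv"} (columns source,target[,weight]),
#'   \code{"dot"} (Graphviz), or \code{"adjacency_json"}. Edges are
#'   written sorted by (source, target) for stable files; \code{edge_csv}
#'   and \code{adjacency_json} round-trip through
#'   \code{\link{read_graph}}.
#' @export
write_graph <- function(g, path,
                        format = c("edge_csv", "dot", "adjacency_json")) {
  format <- match.arg(format)
  weights <- NULL
  if (inherits(g, "perturbation_graph")) {
    weights <- g$weights
    g <- g$graph
  }
  stopifnot(inherits(g, "digraph"))
  ed <- g$edges[order(g$edges$from, g$edges$to), , drop = FALSE]
  if (format == "edge_csv") {
    out <- data.frame(source = ed$from, target = ed$to,
                      stringsAsFactors = FALSE)
    if (!is.null(weights)) {
      key <- paste(weights$source, weights$target, sep = "\r")
      out$weight <- sprintf("%.10g",
        weights$weight[match(paste(out$source, out$target, sep = "\r"),
                             key)])
    }
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else if (format == "dot") {
    lines <- c("digraph {",
               paste0("  \"", g$nodes, "\";"),
               if (nrow(ed)) paste0("  \"", ed$from, "\" -> \"",
                                    ed$to, "\";"),
               "}")
    writeLines(lines, path)
  } else {
    adj <- lapply(g$nodes, function(v) ed$to[ed$from == v])
    names(adj) <- g$nodes
    jsonlite::write_json(list(nodes = g$nodes, adjacency = adj), path,
                         auto_unbox = FALSE, pretty = TRUE)
  }
  invisible(path)
}

#' Read a graph from disk
#'
#' @param path File written by \code{\link{write_graph}}.
#' @param format \code{"edge_csv"} or \code{"adjacency_json"}.
#' @param nodes Optional full node set for \code{edge_csv} (isolated nodes
#'   are not recoverable from an edge list alone).
#' @return A \code{\link{digraph}}; for a weighted edge CSV a
#'   \code{\link{perturbation_graph}}.
#' @export
read_graph <- function(path, format = c("edge_csv", "adjacency_json"),
                       nodes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edge_csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("source", "target") %in% names(df)))
      stop("edge CSV needs 'source' and 'target' columns")
    nd <- if (is.null(nodes)) unique(c(df$source, df$target)) else nodes
    g <- digraph(nd, data.frame(from = df$source, to = df$target,
                                stringsAsFactors = FALSE))
    if ("weight" %in% names(df)) {
      perturbation_graph(g, data.frame(source = df$source,
                                       target = df$target,
                                       weight = as.numeric(df$weight),
                                       stringsAsFactors = FALSE))
    } else g
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    nd <- as.character(obj$nodes)
    ed <- list()
    for (v in names(obj$adjacency)) {
      for (w in obj$adjacency[[v]])
        ed[[length(ed) + 1L]] <- data.frame(from = v, to = w,
                                            stringsAsFactors = FALSE)
    }
    digraph(nd, if (length(ed)) do.call(rbind, ed) else NULL)
  }
}

#' Model and design JSON
#'
#' Model spec format:
#' \code{{"nodes": [...], "edges": [{"from","to","beta"}, ...],
#' "noise": {node: {"mean", "var"}}}}; design format:
#' \code{{"contexts": [{"label","kind","targets",...,"n"}, ...]}}.
#'
#' @param path JSON file path.
#' @return \code{read_model_json} a \code{\link{sem_model}};
#'   \code{read_design_json} a \code{\link{context_design}}.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.character(obj$nodes)
  ed <- as.data.frame(obj$edges)
  g <- digraph(nodes, if (nrow(ed)) ed[, c("from", "to")] else NULL)
  nm <- vapply(nodes, function(v)
    if (!is.null(obj$noise[[v]]$mean)) obj$noise[[v]]$mean else 0, 0)
  nv <- vapply(nodes, function(v)
    if (!is.null(obj$noise[[v]]$var)) obj$noise[[v]]$var else 1, 0)
  sem_model(g, beta = if (nrow(ed)) as.numeric(ed$beta) else numeric(),
            noise_mean = nm, noise_var = nv)
}

#' @rdname read_model_json
#' @param model A \code{\link{sem_model}}.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "sem_model"))
  ed <- model$graph$edges
  noise <- lapply(model$graph$nodes, function(v)
    list(mean = model$noise_mean[[v]], var = model$noise_var[[v]]))
  names(noise) <- model$graph$nodes
  jsonlite::write_json(
    list(nodes = model$graph$nodes,
         edges = if (nrow(ed))
           data.frame(from = ed$from, to = ed$to,
                      beta = model$B[cbind(ed$to, ed$from)]) else
             list(),
         noise = noise),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_model_json
#' @export
read_design_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  ctx <- lapply(obj$contexts, function(c) {
    kind <- if (is.null(c$kind)) "none" else c$kind
    iv <- if (kind == "none") intervention("none") else
      intervention(kind, unlist(c$targets),
                   replacement_mean = c$replacement_mean %||% 2,
                   replacement_var = c$replacement_var %||% 1,
                   shift_mean = c$shift_mean %||% 2,
                   extra_var = c$extra_var %||% 0)
    list(label = c$label, intervention = iv, n = c$n)
  })
  context_design(ctx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
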