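#' Multi-context data
#'
#' A numeric data matrix with one context label per row: the common input
#' to every estimator in the package. Stored as a data frame whose first
#' column is \code{context} (character) and whose remaining columns are the
#' variables, so it prints, subsets and round-trips through CSV like any
#' data frame.
#'
#' @param values Numeric matrix or data frame (columns = variables, with
#'   names).
#' @param context Character vector of per-row context labels; the
#'   observational context is conventionally labelled \code{"obs"}.
#' @return Object of class \code{c("multi_context_data", "data.frame")}.
#' @export
multi_context_data <- function(values, context) {
  v <- as.matrix(values)
  if (!is.numeric(v)) stop("'values' must be numeric")
  if (anyNA(v)) stop("missing values are not allowed")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    stop("'values' needs unique column names")
  if ("context" %in% colnames(v))
    stop("'context' is reserved for the label column")
  context <- as.character(context)
  if (length(context) != nrow(v))
    stop("one context label per row is required")
  if (anyNA(context) || any(!nzchar(context)))
    stop("context labels must be non-empty strings")
  out <- data.frame(context = context, v, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("multi_context_data", "data.frame")
  out
}

#' @rdname multi_context_data
#' @param x An object to convert: a data frame with a \code{context}
#'   column.
#' @export
as_multi_context_data <- function(x) {
  if (inherits(x, "multi_context_data")) return(x)
  x <- as.data.frame(x)
  if (!"context" %in% names(x))
    stop("a 'context' column is required")
  multi_context_data(x[setdiff(names(x), "context")], x$context)
}

#' @rdname multi_context_data
#' @export
mcd_matrix <- function(x) {
  stopifnot(inherits(x, "multi_context_data"))
  as.matrix(x[setdiff(names(x), "context")])
}

#' @rdname multi_context_data
#' @export
mcd_context <- function(x) {
  stopifnot(inherits(x, "multi_context_data"))
  x[["context"]]
}

#' @rdname multi_context_data
#' @export
mcd_vars <- function(x) {
  stopifnot(inherits(x, "multi_context_data"))
  setdiff(names(x), "context")
}

#' @export
print.multi_context_data <- function(x, ...) {
  tab <- table(mcd_context(x))
  cat("multi-context data:", nrow(x), "rows,", length(mcd_vars(x)),
      "variables,", length(tab), "contexts\n")
  cat("contexts:",
      paste0(names(tab), " (n=", as.integer(tab), ")", collapse = ", "),
      "\n")
  NextMethod()
}

check_vars <- function(data, v) {
  unknown <- setdiff(v, mcd_vars(data))
  if (length(unknown))
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  invisible(v)
}

check_labels <- function(data, l) {
  unknown <- setdiff(l, unique(mcd_context(data)))
  if (length(unknown))
    stop("context label(s) not present in data: ",
         paste(unknown, collapse = ", "))
  invisible(l)
}
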