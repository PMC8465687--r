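#' Validate an adjacency matrix
#'
#' Checks that `adjacency` is a square, symmetric, zero-diagonal numeric
#' matrix, the representation used throughout the package for an undirected
#' graph. Simple (unweighted) graphs must have entries in \{0, 1\};
#' weighted graphs (e.g. correlation networks) may hold arbitrary reals.
#'
#' @param adjacency numeric matrix.
#' @param weighted logical; if `FALSE` entries must be 0/1.
#' @param tol numeric tolerance for the symmetry check.
#' @return the validated matrix, invisibly.
#' @export
validate_adjacency <- function(adjacency, weighted = FALSE, tol = 1e-10) {
  if (!is.matrix(adjacency) || !is.numeric(adjacency))
    stop("adjacency must be a numeric matrix", call. = FALSE)
  n <- nrow(adjacency)
  if (n < 1L || ncol(adjacency) != n)
    stop("adjacency must be square with at least one vertex", call. = FALSE)
  if (anyNA(adjacency))
    stop("adjacency contains missing values", call. = FALSE)
  if (max(abs(adjacency - t(adjacency))) > tol)
    stop("adjacency is not symmetric", call. = FALSE)
  if (any(diag(adjacency) != 0))
    stop("adjacency has nonzero diagonal (self-loops are not supported)",
         call. = FALSE)
  if (!weighted && !all(adjacency %in% c(0, 1)))
    stop("simple graph adjacency must be binary (0/1)", call. = FALSE)
  invisible(adjacency)
}

#' Construct a graph series
#'
#' A graph series is an ordered sequence of T undirected graphs on a common
#' vertex set, stored as a list of adjacency matrices. It is the basic
#' "network time series" object fed to [extract_features()] and
#' [graph_granger()].
#'
#' @param graphs list of adjacency matrices sharing a vertex count.
#' @param label identifier for the series.
#' @param weighted logical; whether edges carry real weights.
#' @param validate logical; run [validate_adjacency()] on every element.
#' @return an object of class `graph_series`.
#' @export
graph_series <- function(graphs, label = "series", weighted = FALSE,
                         validate = TRUE) {
  if (!is.list(graphs) || length(graphs) < 2L)
    stop("a graph series needs a list of at least two graphs", call. = FALSE)
  n <- nrow(graphs[[1L]])
  if (validate) {
    for (t in seq_along(graphs)) {
      validate_adjacency(graphs[[t]], weighted = weighted)
      if (nrow(graphs[[t]]) != n)
        stop("all graphs in a series must share the vertex count; graph ", t,
             " has ", nrow(graphs[[t]]), " vertices, expected ", n,
             call. = FALSE)
    }
  }
  structure(list(graphs = graphs, n_vertices = n,
                 label = as.character(label), weighted = isTRUE(weighted)),
            class = "graph_series")
}

#' @export
length.graph_series <- function(x) length(x$graphs)

#' @export
print.graph_series <- function(x, ...) {
  cat("<graph_series> '", x$label, "': T = ", length(x$graphs),
      " graphs, n = ", x$n_vertices, " vertices",
      if (x$weighted) ", weighted" else "", "\n", sep = "")
  invisible(x)
}

# number of edges (nonzero upper-triangle entries)
edge_count <- function(adjacency) {
  sum(adjacency[upper.tri(adjacency)] != 0)
}
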