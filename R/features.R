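#' Spectral radius of a graph
#'
#' The largest eigenvalue of the adjacency matrix. For an undirected graph
#' the adjacency is symmetric, so all eigenvalues are real and the spectral
#' radius is computed by symmetric eigen-decomposition. For weighted graphs
#' with possibly negative weights (correlation networks) this is the largest
#' eigenvalue, not the largest absolute eigenvalue.
#'
#' @param adjacency symmetric adjacency matrix (binary or weighted).
#' @param weighted logical; passed to [validate_adjacency()].
#' @param validate logical; skip validation on trusted internal input.
#' @return the largest eigenvalue, a single numeric.
#' @examples
#' K2 <- matrix(c(0, 1, 1, 0), 2)
#' spectral_radius(K2)  # 1
#' @export
spectral_radius <- function(adjacency, weighted = TRUE, validate = TRUE) {
  if (validate) validate_adjacency(adjacency, weighted = weighted)
  if (nrow(adjacency) == 1L) return(0)
  eigen(adjacency, symmetric = TRUE, only.values = TRUE)$values[1L]
}

#' Graph-level centrality feature
#'
#' Reduces a graph to one number: the mean over vertices of a centrality
#' measure. Available measures are shortest-path betweenness
#' (unnormalised), harmonic closeness (finite on disconnected graphs),
#' eigenvector centrality (absolute entries of the unit-norm leading
#' eigenvector of the adjacency), and degree. The degree mean equals
#' `2 * m / n` for a graph with m edges.
#'
#' @param adjacency symmetric binary adjacency matrix.
#' @param feature one of `"betweenness"`, `"closeness"`, `"eigenvector"`,
#'   `"degree"`, or `"spectral_radius"` (dispatches to
#'   [spectral_radius()]).
#' @return a single numeric.
#' @export
centrality_feature <- function(adjacency,
                               feature = c("spectral_radius", "betweenness",
                                           "closeness", "eigenvector",
                                           "degree")) {
  feature <- match.arg(feature)
  if (feature == "spectral_radius") return(spectral_radius(adjacency))
  validate_adjacency(adjacency, weighted = FALSE)
  n <- nrow(adjacency)
  switch(feature,
    degree = mean(colSums(adjacency)),
    eigenvector = {
      if (n == 1L) return(1)
      v <- eigen(adjacency, symmetric = TRUE)$vectors[, 1L]
      mean(abs(v))  # unit-norm convention: regular graph gives 1/sqrt(n)
    },
    betweenness = {
      g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected")
      mean(igraph::betweenness(g, directed = FALSE, normalized = FALSE))
    },
    closeness = {
      g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected")
      mean(igraph::harmonic_centrality(g, normalized = FALSE))
    })
}

#' Extract a feature time series from graph series
#'
#' Applies one scalar graph feature to every graph of every series and
#' stacks the results into the T x k matrix modelled by [var_fit()]:
#' column i holds the feature of series i over time.
#'
#' @param series a [graph_series()] or a list of them, all of equal length.
#' @param feature feature name, see [centrality_feature()].
#' @param allow_empty if `FALSE` (default), a graph with no edges is an
#'   error (the framework assumes non-empty edge sets); if `TRUE` its
#'   feature is computed anyway (spectral radius 0) with a warning.
#' @return a numeric T x k matrix of class `feature_series` with attributes
#'   `feature` and column names taken from series labels.
#' @export
extract_features <- function(series, feature = "spectral_radius",
                             allow_empty = FALSE) {
  if (inherits(series, "graph_series")) series <- list(series)
  if (!length(series)) stop("no graph series given", call. = FALSE)
  stopifnot(all(vapply(series, inherits, logical(1), "graph_series")))
  Ts <- vapply(series, length, integer(1))
  if (length(unique(Ts)) != 1L)
    stop("all graph series must have equal length; got lengths ",
         paste(Ts, collapse = ", "), call. = FALSE)
  T_len <- Ts[1L]
  k <- length(series)
  values <- matrix(NA_real_, T_len, k)
  for (i in seq_len(k)) {
    s <- series[[i]]
    for (t in seq_len(T_len)) {
      A <- s$graphs[[t]]
      if (edge_count(A) == 0L) {
        if (!allow_empty)
          stop("graph ", t, " of series '", s$label, "' has no edges; ",
               "set allow_empty = TRUE to use feature value 0",
               call. = FALSE)
        warning("graph ", t, " of series '", s$label,
                "' has no edges; feature computed anyway", call. = FALSE)
      }
      values[t, i] <- if (feature == "spectral_radius")
        spectral_radius(A, weighted = s$weighted, validate = FALSE)
      else centrality_feature(A, feature)
    }
  }
  colnames(values) <- vapply(series, `[[`, character(1), "label")
  feature_series(values, feature = feature)
}

#' Construct a feature series object
#'
#' @param values numeric T x k matrix, no missing values, T >= 2.
#' @param feature name of the feature the columns hold.
#' @return `values` with class `feature_series` and a `feature` attribute.
#' @export
feature_series <- function(values, feature = "spectral_radius") {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values))
    stop("feature series must be numeric with no missing values",
         call. = FALSE)
  if (nrow(values) < 2L)
    stop("feature series needs at least two time points", call. = FALSE)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("y", seq_len(ncol(values)))
  structure(values, feature = feature,
            class = c("feature_series", "matrix", "array"))
}
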