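# Time-varying correlation graphs from multivariate signals.
#
# One weighted graph per time point: the edge (a, b) at time t carries an
# estimate of the instantaneous Pearson correlation between channels a and
# b, obtained by smoothing-spline estimates of time-varying means,
# variances and covariances.

#' Time-varying Pearson correlation graph series
#'
#' For each channel a cubic smoothing-spline mean is removed; the
#' instantaneous cross-products of the centred signals are spline-smoothed
#' into time-varying covariance and variance estimates, and the correlation
#' `r_ab(t) = cov_ab(t) / sqrt(var_a(t) var_b(t))` is clipped to \[-1, 1\].
#' The same spline flexibility (equivalent degrees of freedom `df`) is used
#' for means, variances and covariances. Small `df` approaches the static
#' Pearson correlation; large `df` tracks faster changes but is noisier.
#'
#' @param x numeric T x n signal matrix (time by channel), T >= 10, no
#'   missing values.
#' @param df equivalent degrees of freedom of every smoothing spline;
#'   default `max(4, T / 10)`. Must be < T.
#' @param var_floor smoothed variances are floored at this value before
#'   division (smoothing nonnegative squares can undershoot zero); an edge
#'   whose variance floor triggers is set to weight 0 with a warning.
#' @param label label for the returned series.
#' @return a weighted [graph_series()] of T graphs on n vertices.
#' @export
time_varying_correlation <- function(x, df = NULL, var_floor = 1e-8,
                                     label = "tvcorr") {
  x <- as.matrix(x)
  T_len <- nrow(x); n <- ncol(x)
  if (T_len < 10L) stop("need at least 10 time points", call. = FALSE)
  if (anyNA(x)) stop("signal matrix contains missing values", call. = FALSE)
  if (n < 2L) stop("need at least two channels", call. = FALSE)
  if (is.null(df)) df <- max(4, T_len / 10)
  if (df >= T_len) stop("spline df must be smaller than T", call. = FALSE)
  tt <- seq_len(T_len)
  sm <- function(v) stats::predict(stats::smooth.spline(tt, v, df = df),
                                   tt)$y
  centred <- apply(x, 2L, function(v) v - sm(v))
  vars <- apply(centred^2, 2L, sm)
  floored <- vars < var_floor
  if (any(floored))
    warning("near-zero smoothed variance in ", sum(colSums(floored) > 0),
            " channel(s); affected edge weights set to 0", call. = FALSE)
  vars[floored] <- var_floor
  W <- array(0, c(n, n, T_len))
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      cab <- sm(centred[, a] * centred[, b])
      r <- cab / sqrt(vars[, a] * vars[, b])
      r[floored[, a] | floored[, b]] <- 0
      r <- pmin(1, pmax(-1, r))
      W[a, b, ] <- r
      W[b, a, ] <- r
    }
  }
  labels <- colnames(x) %||% paste0("ch", seq_len(n))
  graphs <- lapply(seq_len(T_len), function(t) {
    A <- W[, , t]
    dimnames(A) <- list(labels, labels)
    A
  })
  graph_series(graphs, label = label, weighted = TRUE, validate = FALSE)
}

#' Split a graph series into labelled subnetworks
#'
#' Induces one graph series per group label, e.g. a left- and a
#' right-hemisphere series from a whole-brain correlation series. Vertex
#' order within each group follows the original order.
#'
#' @param gs a [graph_series()].
#' @param membership vector of group labels, one per vertex.
#' @return named list of [graph_series()], one per distinct label.
#' @export
split_subnetworks <- function(gs, membership) {
  stopifnot(inherits(gs, "graph_series"))
  if (length(membership) != gs$n_vertices)
    stop("membership must label all ", gs$n_vertices, " vertices",
         call. = FALSE)
  membership <- as.character(membership)
  groups <- unique(membership)
  out <- lapply(groups, function(g) {
    idx <- which(membership == g)
    if (length(idx) < 1L) stop("empty group '", g, "'", call. = FALSE)
    graphs <- lapply(gs$graphs, function(A) A[idx, idx, drop = FALSE])
    graph_series(graphs, label = g, weighted = gs$weighted,
                 validate = FALSE)
  })
  names(out) <- groups
  out
}
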