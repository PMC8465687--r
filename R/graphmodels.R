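#' Specify a random graph model
#'
#' Bundles a random-graph family, vertex count and the family's single free
#' parameter into a validated specification. The five supported families and
#' their parameters are
#'
#' * `erdos_renyi`: edge probability `p` in \[0, 1\];
#' * `geometric`: connection radius `r >= 0`, vertices placed uniformly on
#'   the unit square;
#' * `regular`: common degree `deg` in \{0, ..., n - 1\};
#' * `watts_strogatz`: rewiring probability `pw` in \[0, 1\], with `nei`
#'   neighbours on each side of the starting ring lattice;
#' * `barabasi_albert`: preferential-attachment exponent `ps >= 0`, with
#'   `m1` edges added per incoming vertex.
#'
#' @param family one of `"erdos_renyi"`, `"geometric"`, `"regular"`,
#'   `"watts_strogatz"`, `"barabasi_albert"`.
#' @param n vertex count (>= 1).
#' @param param the family-specific parameter value (see Details).
#' @param nei ring-lattice neighbours per side (Watts-Strogatz only).
#' @param m1 edges per new vertex (Barabasi-Albert only).
#' @return an object of class `model_spec`.
#' @examples
#' model_spec("erdos_renyi", n = 50, param = 0.3)
#' model_spec("regular", n = 50, param = 3)
#' @export
model_spec <- function(family = c("erdos_renyi", "geometric", "regular",
                                  "watts_strogatz", "barabasi_albert"),
                       n, param, nei = 3L, m1 = 1L) {
  family <- match.arg(family)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer", call. = FALSE)
  if (!is.numeric(param) || length(param) != 1L || !is.finite(param))
    stop("param must be a single finite number", call. = FALSE)
  switch(family,
    erdos_renyi = if (param < 0 || param > 1)
      stop("erdos_renyi: p must lie in [0, 1]", call. = FALSE),
    geometric = if (param < 0)
      stop("geometric: radius r must be nonnegative", call. = FALSE),
    regular = {
      if (param != floor(param) || param < 0 || param > n - 1)
        stop("regular: deg must be an integer in {0, ..., n - 1}",
             call. = FALSE)
    },
    watts_strogatz = {
      if (param < 0 || param > 1)
        stop("watts_strogatz: pw must lie in [0, 1]", call. = FALSE)
      if (nei < 1L) stop("watts_strogatz: nei must be >= 1", call. = FALSE)
    },
    barabasi_albert = {
      if (param < 0)
        stop("barabasi_albert: power ps must be nonnegative", call. = FALSE)
      if (m1 < 1L) stop("barabasi_albert: m1 must be >= 1", call. = FALSE)
    })
  structure(list(family = family, n = n, param = param,
                 nei = as.integer(nei), m1 = as.integer(m1)),
            class = "model_spec")
}

#' Generate a random graph
#'
#' Draws one simple undirected graph from the family described by `spec`.
#' The draw is a pure function of `(spec, seed)`: identical arguments
#' reproduce the identical adjacency matrix.
#'
#' Erdos-Renyi graphs are sampled directly as independent Bernoulli(p)
#' upper-triangle entries; the other four families are generated with
#' igraph ([igraph::sample_grg()], [igraph::sample_k_regular()],
#' [igraph::sample_smallworld()], [igraph::sample_pa()]).
#'
#' For the regular family, a pair (n, deg) with `n * deg` odd admits no
#' graph; `deg` is then decremented by one with a warning.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed fully determining the draw.
#' @return an n x n binary adjacency matrix.
#' @examples
#' A <- generate_graph(model_spec("erdos_renyi", 10, 1), seed = 1)
#' sum(A) / 2  # 45 edges: the complete graph K10
#' @export
generate_graph <- function(spec, seed) {
  stopifnot(inherits(spec, "model_spec"))
  set.seed(as.integer(seed))
  n <- spec$n
  A <- switch(spec$family,
    erdos_renyi = {
      A <- matrix(0, n, n)
      if (n > 1L) {
        A[upper.tri(A)] <- as.numeric(stats::runif(n * (n - 1L) / 2L) <
                                        spec$param)
        A <- A + t(A)
      }
      A
    },
    geometric = {
      g <- igraph::sample_grg(n, radius = spec$param, torus = FALSE)
      dense_adjacency(g, n)
    },
    regular = {
      deg <- as.integer(spec$param)
      if ((n * deg) %% 2L == 1L) {
        warning("regular: n * deg is odd; using deg = ", deg - 1L,
                call. = FALSE)
        deg <- deg - 1L
      }
      if (deg == 0L) {
        matrix(0, n, n)
      } else {
        g <- igraph::sample_k_regular(n, deg)
        dense_adjacency(g, n)
      }
    },
    watts_strogatz = {
      g <- igraph::sample_smallworld(dim = 1, size = n, nei = spec$nei,
                                     p = spec$param, loops = FALSE,
                                     multiple = FALSE)
      dense_adjacency(g, n)
    },
    barabasi_albert = {
      g <- igraph::sample_pa(n, power = spec$param, m = spec$m1,
                             directed = FALSE)
      dense_adjacency(g, n)
    })
  A
}

# igraph -> dense base adjacency matrix (sparse intermediate is much faster
# than as_adjacency_matrix(sparse = FALSE) for n in the hundreds)
dense_adjacency <- function(g, n) {
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  dimnames(A) <- NULL
  storage.mode(A) <- "double"
  A[A > 1] <- 1  # guard against multi-edges from any generator
  diag(A) <- 0
  A
}

#' Known spectral radius of a random graph family
#'
#' Returns the closed-form or asymptotic spectral radius of the adjacency
#' matrix for families where one is known: `n * p` for Erdos-Renyi, `deg`
#' for deg-regular graphs, the dense-regime limit equal to the expected
#' degree `n * pi * r^2` for geometric graphs on the unit square, and the
#' order `sqrt(k0) * n^((ps - 1)/2)` for Barabasi-Albert graphs with
#' smallest degree `k0 = m1`. No analytic form is known for Watts-Strogatz
#' graphs.
#'
#' @param spec a [model_spec()].
#' @return a list with elements `value` (numeric or `NA`), `asymptotic`
#'   (logical: `TRUE` when the value is an asymptotic order rather than an
#'   exact/limit closed form) and `defined` (logical; `FALSE` for
#'   Watts-Strogatz).
#' @examples
#' theoretical_spectral_radius(model_spec("regular", 50, 7))$value  # 7
#' @export
theoretical_spectral_radius <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  switch(spec$family,
    erdos_renyi = list(value = spec$n * spec$param, asymptotic = FALSE,
                       defined = TRUE),
    regular = list(value = as.numeric(spec$param), asymptotic = FALSE,
                   defined = TRUE),
    geometric = {
      # dense regime: lambda1 tracks the expected degree (boundary effects
      # ignored); reported as asymptotic only
      list(value = spec$n * pi * spec$param^2, asymptotic = TRUE,
           defined = TRUE)
    },
    barabasi_albert = {
      k0 <- spec$m1
      list(value = sqrt(k0) * spec$n^((spec$param - 1) / 2),
           asymptotic = TRUE, defined = TRUE)
    },
    watts_strogatz = list(value = NA_real_, asymptotic = NA,
                          defined = FALSE))
}

#' Generate a time series of random graphs
#'
#' Draws `length(params)` independent graphs from one family, with the
#' family parameter varying over time. Graph t uses seed `seed + t`, so time
#' points are independent given the parameters and the whole series is
#' reproducible from `seed`.
#'
#' @param family random-graph family (see [model_spec()]).
#' @param n vertex count.
#' @param params numeric vector of per-time-point parameter values.
#' @param seed integer base seed.
#' @param label series label.
#' @param nei,m1 fixed family constants, as in [model_spec()].
#' @return a [graph_series()].
#' @export
generate_graph_series <- function(family, n, params, seed, label = "series",
                                  nei = 3L, m1 = 1L) {
  graphs <- vector("list", length(params))
  for (t in seq_along(params)) {
    sp <- model_spec(family, n = n, param = params[t], nei = nei, m1 = m1)
    graphs[[t]] <- generate_graph(sp, seed = (seed + t) %% .Machine$integer.max)
  }
  graph_series(graphs, label = label, weighted = FALSE, validate = FALSE)
}
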