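# Simulation scenarios: small latent VAR systems with known causal
# structure, mapped through the inverse logit onto random-graph parameters.
# Innovations are jointly normal, mean zero, variance 1, with
# cross-covariance 0.1 between every pair of series.

#' Scenario specification
#'
#' Returns the latent linear system of one of the five benchmark
#' scenarios:
#'
#' 1. two independent AR(1) series (null: no causality);
#' 2. direct effect y1 -> y2;
#' 3. common driver y1 -> y2 and y1 -> y3 (three series);
#' 4. direct and indirect effects y1 -> y2 -> y3, y1 -> y3 (at lag 2),
#'    y3 -> y4;
#' 5. feedback loop y1 -> y2 -> y3 -> y4 -> y2.
#'
#' All nonzero autoregressive coefficients are +/- 0.5.
#'
#' @param id scenario number, 1 to 5.
#' @return list of class `scenario_spec` with elements `id`, `k`,
#'   `coefficients` (data frame: source, target, lag, value), `sigma`
#'   (k x k innovation covariance: unit diagonal, 0.1 off-diagonal) and
#'   `max_lag`.
#' @export
scenario_spec <- function(id) {
  id <- as.integer(id)
  if (is.na(id) || id < 1L || id > 5L)
    stop("scenario id must be in 1..5", call. = FALSE)
  co <- function(...) {
    m <- matrix(c(...), ncol = 4, byrow = TRUE)
    data.frame(source = m[, 1], target = m[, 2], lag = m[, 3], value = m[, 4])
  }
  coefficients <- switch(id,
    co(1, 1, 1, 0.5,
       2, 2, 1, 0.5),
    co(1, 1, 1, 0.5,
       1, 2, 1, 0.5),
    co(1, 2, 1, 0.5,
       1, 3, 1, -0.5),
    co(1, 2, 1, 0.5,
       1, 3, 2, -0.5,
       2, 3, 1, 0.5,
       3, 4, 1, 0.5),
    co(1, 2, 1, 0.5,
       4, 2, 1, -0.5,
       2, 3, 2, -0.5,
       3, 4, 1, 0.5))
  k <- c(2L, 2L, 3L, 4L, 4L)[id]
  sigma <- matrix(0.1, k, k); diag(sigma) <- 1
  structure(list(id = id, k = k, coefficients = coefficients,
                 sigma = sigma, max_lag = max(coefficients$lag)),
            class = "scenario_spec")
}

#' Simulate the latent series of a scenario
#'
#' Recursion starts from zeros; `burn_in` initial steps are generated and
#' discarded so the retained T points are effectively stationary.
#' Innovations are drawn as `z %*% chol(sigma)` with iid standard-normal z.
#'
#' @param spec a [scenario_spec()].
#' @param T_len number of retained time points (>= 10).
#' @param seed integer seed.
#' @param burn_in discarded initial steps (default 50).
#' @param noise_scale multiplier on the innovations; 0 gives the noiseless
#'   recursion (useful for checking the deterministic skeleton).
#' @return T x k matrix of class `feature_series` (feature `"latent"`),
#'   with the retained innovation rows attached as attribute
#'   `"innovations"`.
#' @export
simulate_latent <- function(spec, T_len, seed, burn_in = 50L,
                            noise_scale = 1) {
  stopifnot(inherits(spec, "scenario_spec"))
  T_len <- as.integer(T_len)
  if (T_len < 10L) stop("T must be >= 10", call. = FALSE)
  set.seed(as.integer(seed))
  k <- spec$k
  q <- spec$max_lag
  total <- T_len + burn_in + q
  R <- chol(spec$sigma)
  eps <- (matrix(stats::rnorm(total * k), total, k) %*% R) * noise_scale
  y <- matrix(0, total, k)
  cf <- spec$coefficients
  for (t in (q + 1L):total) {
    acc <- eps[t, ]
    for (r in seq_len(nrow(cf)))
      acc[cf$target[r]] <- acc[cf$target[r]] +
        cf$value[r] * y[t - cf$lag[r], cf$source[r]]
    y[t, ] <- acc
  }
  keep <- (burn_in + q + 1L):total
  out <- y[keep, , drop = FALSE]
  colnames(out) <- paste0("y", seq_len(k))
  out <- feature_series(out, feature = "latent")
  attr(out, "innovations") <- eps[keep, , drop = FALSE]
  out
}

#' Inverse logit
#'
#' `1 / (1 + exp(-x))`, mapping the real line onto (0, 1). Used to turn
#' latent VAR values into valid random-graph parameters.
#'
#' @param x numeric vector.
#' @return numeric vector in (0, 1).
#' @export
inverse_logit <- function(x) 1 / (1 + exp(-x))

#' Map latent series to random-graph parameter series
#'
#' Applies the inverse logit to each latent value, giving s in (0, 1), then
#' the family-specific transform: Erdos-Renyi edge probability `p = s`;
#' geometric radius `r = s`; regular degree `deg = floor(10 * s)`;
#' Watts-Strogatz rewiring probability `pw = s`; Barabasi-Albert
#' attachment power `ps = 2 * s`.
#'
#' @param latent numeric values (typically one column of
#'   [simulate_latent()] output).
#' @param family random-graph family name.
#' @return numeric vector of graph parameters.
#' @export
map_parameters <- function(latent, family) {
  s <- inverse_logit(latent)
  switch(family,
    erdos_renyi = s,
    geometric = s,
    regular = floor(10 * s),
    watts_strogatz = s,
    barabasi_albert = 2 * s,
    stop("unknown family '", family, "'", call. = FALSE))
}

#' Build graph series from latent scenario series
#'
#' For each latent series (column) and time point, transforms the latent
#' value with [map_parameters()] and draws an independent graph. Graph
#' (i, t) uses seed `seed + (i - 1) * T + t`.
#'
#' @param latent T x k latent matrix from [simulate_latent()].
#' @param family random-graph family name.
#' @param n vertex count.
#' @param seed integer base seed for the graph draws.
#' @param nei,m1 family constants (defaults 3 and 1).
#' @return list of k [graph_series()] objects.
#' @export
latent_to_graphs <- function(latent, family, n, seed, nei = 3L, m1 = 1L) {
  latent <- as.matrix(latent)
  T_len <- nrow(latent); k <- ncol(latent)
  lapply(seq_len(k), function(i) {
    params <- map_parameters(latent[, i], family)
    generate_graph_series(family, n, params,
                          seed = (seed + (i - 1L) * T_len) %%
                            .Machine$integer.max,
                          label = colnames(latent)[i] %||% paste0("y", i),
                          nei = nei, m1 = m1)
  })
}

#' Monte-Carlo rejection-rate experiment
#'
#' Repeats the full pipeline — simulate the scenario's latent system, map to
#' graph series, extract the graph feature, fit the VAR, test every ordered
#' pair — and tabulates the fraction of replicates whose p-value falls below
#' `alpha`, for each cell of an (n, T) grid. Scenario 1 estimates the type-I
#' error (no causal pair); scenarios 2-5 estimate power along their causal
#' pairs.
#'
#' @param scenario scenario id (1-5) or a [scenario_spec()].
#' @param family random-graph family name.
#' @param n vector of vertex counts.
#' @param T_len vector of series lengths.
#' @param reps Monte-Carlo replicates per (n, T) cell.
#' @param method `"wald"` or `"bootstrap"`.
#' @param alpha rejection threshold (default 0.05).
#' @param feature graph feature (default `"spectral_radius"`).
#' @param order VAR order; `NULL` (default) uses the scenario's true
#'   maximum lag, `"auto"` selects by AIC per replicate.
#' @param n_boot bootstrap replicates (bootstrap method).
#' @param seed master seed; replicate seeds are drawn from it once.
#' @param nei,m1 family constants.
#' @return data frame: scenario, family, n, T, source, target,
#'   rejection_rate, reps_effective (replicates that completed; failures,
#'   e.g. all-empty regular graphs, are excluded and counted out).
#' @export
run_experiment <- function(scenario, family = "erdos_renyi",
                           n = 60L, T_len = 100L, reps = 100L,
                           method = c("wald", "bootstrap"), alpha = 0.05,
                           feature = "spectral_radius", order = NULL,
                           n_boot = 1000L, seed = 1L, nei = 3L, m1 = 1L) {
  method <- match.arg(method)
  spec <- if (inherits(scenario, "scenario_spec")) scenario
          else scenario_spec(scenario)
  set.seed(as.integer(seed))
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 2L * reps * length(n) * length(T_len)),
                      ncol = 2L)
  grid <- expand.grid(n = n, T_len = T_len)
  out <- list()
  cell0 <- 0L
  for (g in seq_len(nrow(grid))) {
    ng <- grid$n[g]; Tg <- grid$T_len[g]
    pmat_sum <- NULL; n_ok <- 0L
    for (r in seq_len(reps)) {
      sd2 <- rep_seeds[cell0 + r, ]
      res <- tryCatch(suppressWarnings({
        lat <- simulate_latent(spec, Tg, seed = sd2[1L])
        gs <- latent_to_graphs(lat, family, ng, seed = sd2[2L],
                               nei = nei, m1 = m1)
        y <- extract_features(gs, feature = feature, allow_empty = TRUE)
        p_use <- if (is.null(order)) spec$max_lag
                 else if (identical(order, "auto"))
                   var_select_order(y, p_max = min(10L, (Tg - 1L) %/%
                                                     (spec$k + 1L)))
                 else as.integer(order)
        tab <- test_all_pairs(y, p_use, method = method, n_boot = n_boot,
                              seed = sd2[2L])
        tab$p_value
      }), error = function(e) NULL)
      if (!is.null(res)) {
        n_ok <- n_ok + 1L
        pmat_sum <- if (is.null(pmat_sum)) as.numeric(res < alpha)
                    else pmat_sum + (res < alpha)
      }
    }
    cell0 <- cell0 + reps
    if (n_ok == 0L) next
    pairs <- expand.grid(target = seq_len(spec$k), source = seq_len(spec$k))
    pairs <- pairs[pairs$source != pairs$target, ]
    out[[g]] <- data.frame(scenario = spec$id, family = family,
                           n = ng, T = Tg,
                           source = pairs$source, target = pairs$target,
                           rejection_rate = pmat_sum / n_ok,
                           reps_effective = n_ok)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
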