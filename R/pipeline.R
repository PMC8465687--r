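#' Granger causality between time series of graphs
#'
#' End-to-end inference: each graph series is reduced to a scalar feature
#' series (spectral radius by default), the feature series are modelled
#' jointly with a VAR(p) fitted by least squares, and Granger non-causality
#' is tested for every ordered pair of series.
#'
#' @param series a list of [graph_series()] objects of equal length (>= 2
#'   series), or a ready-made T x k [feature_series()] matrix (extraction
#'   is then skipped).
#' @param feature scalar graph feature, see [centrality_feature()].
#' @param order VAR order: a positive integer, or `"auto"` to select by AIC
#'   with `p_max = min(10, floor((T - 1) / (k + 1)))`.
#' @param method `"wald"` (asymptotic chi-squared) or `"bootstrap"`.
#' @param n_boot,seed bootstrap settings, see [bootstrap_test()].
#' @param allow_empty let graphs with no edges contribute feature value 0
#'   (with a warning) instead of failing.
#' @param intercept,sigma_df passed to [var_fit()].
#' @return list of class `graph_granger` with elements `results` (the
#'   [test_all_pairs()] table), `model` (the fitted `var_model`), `order`,
#'   `feature`.
#' @examples
#' lat <- simulate_latent(scenario_spec(2), T_len = 60, seed = 7)
#' gs <- latent_to_graphs(lat, "erdos_renyi", n = 40, seed = 7)
#' gg <- graph_granger(gs, order = 1)
#' gg$results
#' @export
graph_granger <- function(series, feature = "spectral_radius",
                          order = "auto", method = c("wald", "bootstrap"),
                          n_boot = 1000L, seed = 1L, allow_empty = FALSE,
                          intercept = TRUE, sigma_df = "intercept") {
  method <- match.arg(method)
  y <- if (is.matrix(series)) series
       else withCallingHandlers(
         extract_features(series, feature = feature,
                          allow_empty = allow_empty),
         error = function(e) stop("feature extraction: ",
                                  conditionMessage(e), call. = FALSE))
  k <- ncol(y); T_len <- nrow(y)
  if (k < 2L) stop("need at least two series to test causality",
                   call. = FALSE)
  p <- if (identical(order, "auto")) {
    p_max <- min(10L, (T_len - 1L) %/% (k + 1L))
    if (p_max < 1L) stop("series too short for order selection",
                         call. = FALSE)
    as.integer(var_select_order(y, p_max, intercept = intercept))
  } else {
    as.integer(order)
  }
  results <- test_all_pairs(y, p, method = method, n_boot = n_boot,
                            seed = seed, intercept = intercept,
                            sigma_df = sigma_df)
  model <- attr(results, "model")
  if (is.null(model)) model <- var_fit(y, p, intercept = intercept,
                                       sigma_df = sigma_df)
  structure(list(results = results, model = model, order = p,
                 feature = attr(y, "feature") %||% feature),
            class = "graph_granger")
}

#' @export
print.graph_granger <- function(x, ...) {
  cat("Granger causality between graph series (feature: ", x$feature,
      ", VAR order ", x$order, ")\n\n", sep = "")
  print(as.data.frame(x$results))
  invisible(x)
}
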