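# Wald and parametric-bootstrap tests of Granger non-causality in a VAR.
#
# The null hypothesis "series i does not Granger-cause series j" is
# C beta_j = 0, where beta_j is the target column of the coefficient matrix
# and C selects the p coefficients {a_{i,j}^l : l = 1..p}.

#' Contrast matrix selecting the lags of one source series
#'
#' Returns the p x (k*p) binary matrix with row l holding a single one at
#' column `(source-1)*p + l`, i.e. the matrix C of the restriction
#' `C beta_j = 0` under the package's series-major/lag-minor coefficient
#' ordering. Each row has exactly one 1 and the rows are orthonormal, so
#' rank(C) = p.
#'
#' @param k number of series, `p` model order, `source` tested source index.
#' @param p model order.
#' @param source index of the source series whose lags are selected.
#' @return a p x (k*p) matrix.
#' @export
contrast_matrix <- function(k, p, source) {
  C <- matrix(0, p, k * p)
  C[cbind(seq_len(p), coef_index(source, seq_len(p), p))] <- 1
  C
}

#' Wald statistic for Granger non-causality
#'
#' Computes `W = (C b_j)' (C (Z'Z)^{-1} C')^{-1} (C b_j) / sigma_jj`, where
#' `b_j` is the target column of the fitted coefficients, `Z` the lagged
#' design (the intercept column, when present, enters `(Z'Z)^{-1}` with a
#' zero contrast), and `sigma_jj` the target's residual variance. Under the
#' null of non-causality W is asymptotically chi-squared with p degrees of
#' freedom.
#'
#' @param model a fitted [var_fit()] object.
#' @param source,target series indices (or labels); must differ — the
#'   framework only defines cross-series hypotheses.
#' @return the Wald statistic, a nonnegative numeric.
#' @export
wald_statistic <- function(model, source, target) {
  stopifnot(inherits(model, "var_model"))
  source <- resolve_series(model, source)
  target <- resolve_series(model, target)
  if (source == target)
    stop("source and target must differ: self-causality is not a defined ",
         "hypothesis", call. = FALSE)
  p <- model$order
  idx <- coef_index(source, seq_len(p), p)
  cb <- model$coefficients[idx, target]
  XtX <- crossprod(model$Z)
  XtXinv <- tryCatch(chol2inv(chol(XtX)),
                     error = function(e) stop("Z'Z is not invertible: ",
                                              conditionMessage(e),
                                              call. = FALSE))
  M <- XtXinv[idx, idx, drop = FALSE]  # = C (Z'Z)^{-1} C' (zero contrast on
                                       # the intercept column)
  w <- tryCatch(drop(crossprod(cb, solve(M, cb))) / model$sigma[target, target],
                error = function(e) stop("singular C (Z'Z)^{-1} C': ",
                                         conditionMessage(e), call. = FALSE))
  max(w, 0)
}

resolve_series <- function(model, s) {
  if (is.character(s)) {
    i <- match(s, model$labels)
    if (is.na(i)) stop("unknown series label '", s, "'", call. = FALSE)
    return(i)
  }
  s <- as.integer(s)
  if (is.na(s) || s < 1L || s > model$k)
    stop("series index out of range", call. = FALSE)
  s
}

gc_result <- function(source, target, statistic, df, p_value, method,
                      n_boot = NA_integer_, boot_stats = NULL,
                      labels = NULL) {
  structure(list(source = source, target = target,
                 source_label = labels[source] %||% paste0("y", source),
                 target_label = labels[target] %||% paste0("y", target),
                 statistic = statistic, df = df, p_value = p_value,
                 method = method, n_boot = n_boot, boot_stats = boot_stats),
            class = "gc_test")
}

#' @export
print.gc_test <- function(x, ...) {
  cat("Granger non-causality test (", x$method, "): ",
      x$source_label, " -> ", x$target_label, "\n", sep = "")
  cat("  W = ", format(x$statistic, digits = 5), ", df = ", x$df,
      ", p = ", format.pval(x$p_value, digits = 4),
      if (!is.na(x$n_boot)) paste0(" (", x$n_boot, " bootstrap replicates)"),
      "\n", sep = "")
  invisible(x)
}

#' Asymptotic Wald test of Granger non-causality
#'
#' Tests "series `source` does not Granger-cause series `target`" by
#' referring [wald_statistic()] to its asymptotic chi-squared distribution
#' with p degrees of freedom.
#'
#' @inheritParams wald_statistic
#' @return a `gc_test` record with fields `statistic`, `df`, `p_value`,
#'   `method = "wald_chi2"`.
#' @export
wald_test <- function(model, source, target) {
  source <- resolve_series(model, source)
  target <- resolve_series(model, target)
  W <- wald_statistic(model, source, target)
  gc_result(source, target, W, df = model$order,
            p_value = stats::pchisq(W, df = model$order, lower.tail = FALSE),
            method = "wald_chi2", labels = model$labels)
}

#' Parametric bootstrap test of Granger non-causality
#'
#' Finite-sample alternative to the asymptotic Wald test, for short series
#' where the chi-squared approximation is doubtful. The algorithm:
#'
#' 1. fit the VAR(p) on `y` and keep coefficients and residuals;
#' 2. compute the observed Wald statistic W for `source -> target`;
#' 3. form the null model by zeroing the tested coefficients
#'    `a_{source,target}^l` (l = 1..p); all other coefficients, including
#'    the intercept, stay at their unrestricted estimates;
#' 4. simulate each bootstrap series by recursing the null model, started
#'    from the first p observed values and driven by residual rows resampled
#'    with replacement — whole rows, jointly across the k series, so the
#'    contemporaneous error correlation is preserved;
#' 5. refit the VAR on each simulated series and compute W*;
#' 6. the p-value is the fraction of replicates with W* >= W.
#'
#' @param y numeric T x k matrix of feature series.
#' @param p model order.
#' @param source,target series indices or labels.
#' @param n_boot number of bootstrap replicates (>= 1).
#' @param seed integer seed making the test reproducible.
#' @param keep_boot retain the vector of W* values in the result.
#' @param p_value_adjust if `TRUE`, use `(1 + #\{W* >= W\}) / (1 + n)`
#'   instead of the plain fraction, which avoids exact-zero p-values for
#'   downstream multiplicity corrections. Default is the plain fraction.
#' @param intercept,sigma_df passed to [var_fit()].
#' @return a `gc_test` record with `method = "bootstrap"`.
#' @export
bootstrap_test <- function(y, p, source, target, n_boot = 1000L,
                           seed = 1L, keep_boot = FALSE,
                           p_value_adjust = FALSE, intercept = TRUE,
                           sigma_df = "intercept") {
  y <- as.matrix(y)
  if (n_boot < 1L) stop("n_boot must be >= 1", call. = FALSE)
  model <- var_fit(y, p, intercept = intercept, sigma_df = sigma_df)
  source <- resolve_series(model, source)
  target <- resolve_series(model, target)
  W <- wald_statistic(model, source, target)
  k <- model$k
  T_len <- model$T
  # null model: tested coefficients zeroed, everything else unrestricted
  beta0 <- model$coefficients
  beta0[coef_index(source, seq_len(p), p), target] <- 0
  v0 <- model$intercepts
  u <- model$residuals
  n_res <- nrow(u)
  set.seed(as.integer(seed))
  # one index matrix drawn up front: row b holds the resampled residual rows
  # of replicate b, so the whole test is a function of (y, seed)
  idx <- matrix(sample.int(n_res, n_boot * n_res, replace = TRUE),
                nrow = n_boot)
  Wstar <- rep(NA_real_, n_boot)
  n_fail <- 0L
  ystar <- y  # first p rows reused as initial values
  for (b in seq_len(n_boot)) {
    for (t in (p + 1L):T_len) {
      z <- c(ystar[t - seq_len(p), , drop = FALSE])  # series-major/lag-minor
      ystar[t, ] <- drop(z %*% beta0) + v0 + u[idx[b, t - p], ]
    }
    wb <- tryCatch({
      mb <- var_fit(ystar, p, intercept = intercept, sigma_df = sigma_df)
      wald_statistic(mb, source, target)
    }, error = function(e) NA_real_)
    if (is.na(wb)) n_fail <- n_fail + 1L else Wstar[b] <- wb
  }
  if (n_fail == n_boot)
    stop("all bootstrap replicates failed to refit", call. = FALSE)
  if (n_fail > 0L)
    warning(n_fail, " bootstrap replicate(s) discarded (singular refit)",
            call. = FALSE)
  Wstar <- Wstar[!is.na(Wstar)]
  n_eff <- length(Wstar)
  p_value <- if (p_value_adjust) (1 + sum(Wstar >= W)) / (1 + n_eff)
             else sum(Wstar >= W) / n_eff
  gc_result(source, target, W, df = p, p_value = p_value,
            method = "bootstrap", n_boot = n_eff,
            boot_stats = if (keep_boot) Wstar, labels = model$labels)
}

#' Test all ordered series pairs
#'
#' Runs a Granger non-causality test for every ordered pair (i, j), i != j,
#' giving k*(k-1) directed tests. Wald tests share one fitted model;
#' bootstrap tests derive a per-pair seed
#' `seed + (source - 1) * k + (target - 1)` so each pair's test is
#' independently reproducible.
#'
#' @param y numeric T x k matrix of feature series.
#' @param p model order.
#' @param method `"wald"` or `"bootstrap"`.
#' @param n_boot bootstrap replicates per pair (bootstrap method only).
#' @param seed master seed (bootstrap method only).
#' @param intercept,sigma_df passed to [var_fit()].
#' @param ... further arguments to [bootstrap_test()].
#' @return a data frame of class `gc_test_table` with one row per directed
#'   pair: source, target, statistic, df, p_value, method, n_boot. The
#'   fitted `var_model` is attached as attribute `model` (Wald method).
#' @export
test_all_pairs <- function(y, p, method = c("wald", "bootstrap"),
                           n_boot = 1000L, seed = 1L, intercept = TRUE,
                           sigma_df = "intercept", ...) {
  method <- match.arg(method)
  y <- as.matrix(y)
  k <- ncol(y)
  if (k < 2L) stop("need at least two series", call. = FALSE)
  model <- if (method == "wald")
    var_fit(y, p, intercept = intercept, sigma_df = sigma_df)
  pairs <- expand.grid(target = seq_len(k), source = seq_len(k))
  pairs <- pairs[pairs$source != pairs$target, c("source", "target")]
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs$source[r]; j <- pairs$target[r]
    res <- if (method == "wald") wald_test(model, i, j)
    else bootstrap_test(y, p, i, j, n_boot = n_boot,
                        seed = (seed + (i - 1L) * k + (j - 1L)) %%
                          .Machine$integer.max,
                        intercept = intercept, sigma_df = sigma_df, ...)
    data.frame(source = res$source_label, target = res$target_label,
               statistic = res$statistic, df = res$df,
               p_value = res$p_value, method = res$method,
               n_boot = res$n_boot, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gc_test_table", "data.frame")
  attr(out, "model") <- model
  out
}
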