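# Vector autoregression by ordinary least squares.
#
# Coefficient ordering convention, used everywhere in the package
# (design columns, coefficient rows, contrast matrices):
#   column/row (i - 1) * p + l  <->  series i at lag l   (series-major,
#   lag-minor), for i = 1..k, l = 1..p. The intercept, when present, is the
#   last design column and is reported separately from the lag coefficients.

# flat index of (series i, lag l) under the ordering above
coef_index <- function(i, l, p) (i - 1L) * p + l

#' Build the lagged VAR design
#'
#' Constructs the response matrix `Y` (rows t = p+1, ..., T) and the lagged
#' design `Z` whose row for time t holds `y[t-l, i]` in column
#' `(i-1)*p + l`, followed by an intercept column of ones (unless
#' `intercept = FALSE`).
#'
#' @param y numeric T x k matrix (a [feature_series()] or plain matrix).
#' @param p model order (number of lags), >= 1.
#' @param intercept include a constant column (default `TRUE`).
#' @return list with elements `Y` ((T-p) x k) and `Z`
#'   ((T-p) x (k*p + intercept)).
#' @export
build_var_design <- function(y, p, intercept = TRUE) {
  y <- as.matrix(y)
  T_len <- nrow(y); k <- ncol(y)
  p <- as.integer(p)
  if (p < 1L) stop("order p must be >= 1", call. = FALSE)
  n_coef <- k * p + as.integer(intercept)
  if (T_len - p <= n_coef)
    stop("insufficient data: T - p = ", T_len - p,
         " rows cannot identify ", n_coef, " coefficients per equation",
         call. = FALSE)
  Y <- y[(p + 1L):T_len, , drop = FALSE]
  Z <- matrix(NA_real_, T_len - p, k * p)
  cn <- character(k * p)
  for (i in seq_len(k)) {
    for (l in seq_len(p)) {
      Z[, coef_index(i, l, p)] <- y[(p + 1L - l):(T_len - l), i]
      cn[coef_index(i, l, p)] <- paste0(colnames(y)[i] %||% paste0("y", i),
                                        ".l", l)
    }
  }
  colnames(Z) <- cn
  if (intercept) {
    Z <- cbind(Z, const = 1)
  }
  list(Y = Y, Z = Z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a VAR(p) by ordinary least squares
#'
#' Solves the multivariate least-squares problem `Y = Z beta + u` via QR
#' (never by explicit inversion of `Z'Z`). The residual covariance is
#' `sigma = u'u / df` with `df = (T - p) - (k*p + 1)` by default,
#' accounting for the intercept; `sigma_df = "no_intercept"` uses the
#' denominator `(T - p) - k*p` that ignores the constant term.
#'
#' @param y numeric T x k matrix of feature series.
#' @param p model order.
#' @param intercept include a constant term (default `TRUE`).
#' @param sigma_df `"intercept"` (default) or `"no_intercept"`; see above.
#' @param rank_tol relative singular-value tolerance below which the design
#'   is declared singular.
#' @return an object of class `var_model`: list with `order`, `k`, `T`,
#'   `intercepts`, `coefficients` ((k*p) x k matrix, entry
#'   `[(i-1)*p + l, j]` = effect of series i at lag l on series j),
#'   `residuals`, `sigma`, `Y`, `Z`, `labels`, `df_sigma`.
#' @examples
#' y <- matrix(0.9^(0:29), ncol = 1)  # noiseless AR(1)
#' fit <- var_fit(y, p = 1)
#' fit$coefficients  # 0.9
#' @export
var_fit <- function(y, p, intercept = TRUE,
                    sigma_df = c("intercept", "no_intercept"),
                    rank_tol = 1e-10) {
  sigma_df <- match.arg(sigma_df)
  y <- as.matrix(y)
  k <- ncol(y); T_len <- nrow(y); p <- as.integer(p)
  flat <- apply(y, 2L, function(v) max(v) - min(v)) == 0
  if (any(flat))
    stop("singular design: series {",
         paste((colnames(y) %||% paste0("y", seq_len(k)))[flat],
               collapse = ", "),
         "} are constant and cannot be fitted", call. = FALSE)
  d <- build_var_design(y, p, intercept = intercept)
  sv <- svd(d$Z, nu = 0, nv = 0)$d
  if (sv[length(sv)] < rank_tol * sv[1L]) {
    qrz <- qr(d$Z, tol = rank_tol)
    bad <- colnames(d$Z)[qrz$pivot[seq_len(ncol(d$Z)) > qrz$rank]]
    stop("singular design: columns {", paste(bad, collapse = ", "),
         "} are (numerically) linearly dependent; constant or collinear ",
         "feature series cannot be fitted", call. = FALSE)
  }
  qrz <- qr(d$Z)
  beta_full <- qr.coef(qrz, d$Y)
  u <- d$Y - d$Z %*% beta_full
  n_par <- k * p + as.integer(intercept)
  df <- (T_len - p) - if (sigma_df == "intercept") n_par else k * p
  if (df <= 0) stop("nonpositive residual degrees of freedom", call. = FALSE)
  sigma <- crossprod(u) / df
  labels <- colnames(y) %||% paste0("y", seq_len(k))
  coefs <- beta_full[seq_len(k * p), , drop = FALSE]
  colnames(coefs) <- labels
  structure(list(order = p, k = k, T = T_len,
                 intercepts = if (intercept) beta_full[k * p + 1L, ]
                              else rep(0, k),
                 coefficients = coefs,
                 residuals = u, sigma = sigma,
                 Y = d$Y, Z = d$Z, labels = labels,
                 intercept = intercept, df_sigma = df,
                 sigma_df = sigma_df),
            class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  cat("VAR(", x$order, ") fit: k = ", x$k, " series, T = ", x$T,
      ", ", nrow(x$residuals), " usable observations\n", sep = "")
  cat("Residual covariance (df = ", x$df_sigma, "):\n", sep = "")
  print(round(x$sigma, 4))
  invisible(x)
}

#' Select the VAR order by AIC
#'
#' Fits candidate orders p = 1, ..., `p_max` on the common effective sample
#' aligned at `p_max` (all candidates predict the same response rows, so
#' their likelihoods are comparable) and returns the order minimising
#' `AIC(p) = log det(sigma_ml(p)) + 2 * p * k^2 / T_eff`, where `sigma_ml`
#' is the maximum-likelihood residual covariance. Ties break toward the
#' smaller order.
#'
#' @param y numeric T x k matrix.
#' @param p_max largest candidate order.
#' @param intercept include a constant term in every candidate fit.
#' @return the selected order, an integer with attribute `aic` holding the
#'   per-order criterion values.
#' @export
var_select_order <- function(y, p_max, intercept = TRUE) {
  y <- as.matrix(y)
  T_len <- nrow(y); k <- ncol(y)
  p_max <- as.integer(p_max)
  if (p_max < 1L) stop("p_max must be >= 1", call. = FALSE)
  T_eff <- T_len - p_max
  if (T_eff <= k * p_max + 1L)
    stop("insufficient data for p_max = ", p_max, call. = FALSE)
  aic <- rep(NA_real_, p_max)
  Y <- y[(p_max + 1L):T_len, , drop = FALSE]
  for (p in seq_len(p_max)) {
    Z <- matrix(NA_real_, T_eff, k * p)
    for (i in seq_len(k)) for (l in seq_len(p))
      Z[, coef_index(i, l, p)] <- y[(p_max + 1L - l):(T_len - l), i]
    if (intercept) Z <- cbind(Z, 1)
    sv <- svd(Z, nu = 0, nv = 0)$d
    if (sv[length(sv)] < 1e-10 * sv[1L]) next  # singular candidate: skip
    u <- Y - Z %*% qr.coef(qr(Z), Y)
    sig <- crossprod(u) / T_eff
    ld <- determinant(sig, logarithm = TRUE)
    if (ld$sign <= 0) next
    aic[p] <- as.numeric(ld$modulus) + 2 * p * k^2 / T_eff
  }
  if (all(is.na(aic)))
    stop("all candidate orders gave singular fits", call. = FALSE)
  structure(which.min(aic), aic = aic)
}
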