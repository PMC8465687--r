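# shared fixtures and independent oracles

path_graph <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  A
}

complete_graph <- function(n) {
  A <- matrix(1, n, n); diag(A) <- 0
  A
}

cycle_graph <- function(n) {
  A <- path_graph(n)
  A[1, n] <- A[n, 1] <- 1
  A
}

# independent spectral-radius oracle: characteristic polynomial by the
# Faddeev-LeVerrier recursion, roots by polyroot, largest real root
charpoly_spectral_radius <- function(A) {
  n <- nrow(A)
  coefs <- numeric(n + 1)  # coefs[m+1] = c_m in det(tI - A) = sum c_m t^m
  coefs[n + 1] <- 1
  M <- diag(n)
  for (m in seq_len(n)) {
    M <- A %*% M
    c_m <- -sum(diag(M)) / m
    coefs[n + 1 - m] <- c_m
    M <- M + c_m * diag(n)
  }
  roots <- polyroot(coefs)
  real_roots <- Re(roots[abs(Im(roots)) < 1e-6])
  max(real_roots)
}

# hand-built lagged design oracle (naive double loop, column
# (i-1)*p + l = series i lag l, matching the package convention)
naive_design <- function(y, p) {
  T_len <- nrow(y); k <- ncol(y)
  Z <- matrix(NA_real_, T_len - p, k * p)
  for (row in seq_len(T_len - p)) {
    t <- p + row
    for (i in seq_len(k)) for (l in seq_len(p))
      Z[row, (i - 1) * p + l] <- y[t - l, i]
  }
  list(Y = y[(p + 1):T_len, , drop = FALSE], Z = Z)
}

# small ER graph series pair with a lag-1 causal link, for pipeline tests
toy_causal_series <- function(T_len = 60, n = 40, seed = 11) {
  lat <- simulate_latent(scenario_spec(2), T_len = T_len, seed = seed)
  latent_to_graphs(lat, "erdos_renyi", n = n, seed = seed)
}
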