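test_that("contrast matrix selects exactly the source lags", {
  C <- contrast_matrix(k = 3, p = 2, source = 2)
  expect_equal(dim(C), c(2L, 6L))
  expect_equal(rowSums(C), c(1, 1))
  expect_equal(which(C[1, ] == 1), 3L)  # (source-1)*p + 1
  expect_equal(which(C[2, ] == 1), 4L)
  expect_equal(qr(C)$rank, 2L)
})

test_that("Wald statistic matches the single-restriction lm oracle", {
  # k = 2, p = 1: the restriction is scalar, so W = (coef / se)^2 with the
  # standard error from an ordinary lm fit of the target equation
  y <- cbind(y1 = c(1.2, -0.4, 0.8, 2.1, -1.0, 0.5, 1.4, 0.3),
             y2 = c(0.3, 1.1, -0.2, 0.9, 1.8, -0.7, 0.2, 1.0))
  fit <- var_fit(y, p = 1)
  W <- wald_statistic(fit, source = 1, target = 2)
  lmfit <- stats::lm(y[2:8, 2] ~ y[1:7, 1] + y[1:7, 2])
  tval <- summary(lmfit)$coefficients["y[1:7, 1]", "t value"]
  expect_equal(W, tval^2, tolerance = 1e-10)
})

test_that("zero cross-coefficients give W = 0 and p-value 1", {
  # orthogonal construction: target residual regression coefficient on the
  # source lag is exactly zero when the source column is orthogonalised out
  y <- cbind(c(1, -1, 1, -1, 1, -1, 1, -1, 1, -1),
             c(0.5, 0.2, -0.3, 0.8, 0.1, -0.6, 0.4, 0, 0.7, -0.2))
  fit <- var_fit(y, p = 1)
  fit$coefficients[1, 2] <- 0  # impose the null exactly
  expect_equal(wald_statistic(fit, 1, 2), 0)
  res <- wald_test(fit, 1, 2)
  expect_equal(res$p_value, 1)
  expect_equal(res$method, "wald_chi2")
  expect_equal(res$df, 1)
})

test_that("self-causality and bad indices are rejected", {
  y <- matrix(rnorm(60), 30, 2)
  fit <- var_fit(y, 1)
  expect_error(wald_statistic(fit, 1, 1), "self-causality")
  expect_error(wald_statistic(fit, 3, 1), "out of range")
  expect_error(wald_test(fit, "nope", 1), "unknown series label")
})

test_that("W is invariant to relabeling the non-involved series", {
  set.seed(31)
  y <- matrix(rnorm(200), 50, 4)
  W12 <- wald_statistic(var_fit(y, 1), 1, 2)
  y_swapped <- y[, c(1, 2, 4, 3)]
  expect_equal(wald_statistic(var_fit(y_swapped, 1), 1, 2), W12,
               tolerance = 1e-10)
})

test_that("null W values follow the chi-squared reference distribution", {
  W <- vapply(1:300, function(r) {
    lat <- simulate_latent(scenario_spec(1), T_len = 100, seed = 5000 + r)
    wald_statistic(var_fit(lat, 1), 1, 2)
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(W, stats::pchisq, df = 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("bootstrap p-value is the fraction of W* at least as large as W", {
  lat <- simulate_latent(scenario_spec(1), T_len = 40, seed = 8)
  res <- bootstrap_test(lat, 1, 1, 2, n_boot = 1, seed = 1, keep_boot = TRUE)
  expect_true(res$p_value %in% c(0, 1))
  expect_equal(res$p_value, as.numeric(res$boot_stats[1] >= res$statistic))
  res20 <- bootstrap_test(lat, 1, 1, 2, n_boot = 20, seed = 1,
                          keep_boot = TRUE)
  expect_equal(res20$p_value,
               mean(res20$boot_stats >= res20$statistic))
  # the adjusted variant never returns 0
  resa <- bootstrap_test(lat, 1, 1, 2, n_boot = 20, seed = 1,
                         p_value_adjust = TRUE)
  expect_gt(resa$p_value, 0)
})

test_that("bootstrap test is reproducible from its seed", {
  lat <- simulate_latent(scenario_spec(2), T_len = 50, seed = 9)
  r1 <- bootstrap_test(lat, 1, 1, 2, n_boot = 50, seed = 123)
  r2 <- bootstrap_test(lat, 1, 1, 2, n_boot = 50, seed = 123)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$statistic, r2$statistic)
})

test_that("bootstrap detects the scenario-2 causal direction at T = 100", {
  lat <- simulate_latent(scenario_spec(2), T_len = 100, seed = 10)
  fwd <- bootstrap_test(lat, 1, 1, 2, n_boot = 200, seed = 1)
  expect_lt(fwd$p_value, 0.05)
})

test_that("bootstrap and asymptotic Wald p-values agree on long series", {
  agree <- vapply(1:20, function(r) {
    lat <- simulate_latent(scenario_spec(1), T_len = 500, seed = 7000 + r)
    pw <- wald_test(var_fit(lat, 1), 1, 2)$p_value
    pb <- bootstrap_test(lat, 1, 1, 2, n_boot = 400, seed = r)$p_value
    abs(pw - pb) < 0.05
  }, logical(1))
  expect_gte(mean(agree), 0.9)
})

test_that("test_all_pairs covers every ordered pair once", {
  set.seed(41)
  y2 <- matrix(rnorm(120), 60, 2)
  t2 <- test_all_pairs(y2, 1)
  expect_equal(nrow(t2), 2L)
  y4 <- matrix(rnorm(240), 60, 4)
  t4 <- test_all_pairs(y4, 1)
  expect_equal(nrow(t4), 12L)
  expect_equal(anyDuplicated(t4[c("source", "target")]), 0L)
  expect_true(all(t4$source != t4$target))
  # wald rows equal individual tests on the shared fit
  fit <- var_fit(y4, 1)
  expect_equal(t4$statistic[t4$source == "y1" & t4$target == "y2"],
               wald_test(fit, 1, 2)$statistic)
})

test_that("bootstrap test_all_pairs equals per-pair calls with derived seeds", {
  lat <- simulate_latent(scenario_spec(2), T_len = 50, seed = 12)
  tab <- test_all_pairs(lat, 1, method = "bootstrap", n_boot = 30, seed = 77)
  k <- 2
  single <- bootstrap_test(lat, 1, 2, 1, n_boot = 30,
                           seed = 77 + (2 - 1) * k + (1 - 1))
  row <- tab[tab$source == "y2" & tab$target == "y1", ]
  expect_equal(row$p_value, single$p_value)
  expect_equal(row$statistic, single$statistic)
})
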