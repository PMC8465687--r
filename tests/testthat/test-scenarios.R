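test_that("scenario specifications encode the documented causal structures", {
  s1 <- scenario_spec(1)
  expect_equal(s1$k, 2L)
  expect_true(all(s1$coefficients$source == s1$coefficients$target))
  s2 <- scenario_spec(2)
  expect_true(any(s2$coefficients$source == 1 & s2$coefficients$target == 2 &
                    s2$coefficients$lag == 1 & s2$coefficients$value == 0.5))
  s4 <- scenario_spec(4)
  expect_equal(s4$max_lag, 2L)
  expect_true(any(s4$coefficients$source == 1 & s4$coefficients$target == 3 &
                    s4$coefficients$lag == 2 & s4$coefficients$value == -0.5))
  # scenario 5 feedback cycle 2 -> 3 -> 4 -> 2
  s5 <- scenario_spec(5)
  cf <- s5$coefficients
  expect_true(any(cf$source == 2 & cf$target == 3))
  expect_true(any(cf$source == 3 & cf$target == 4))
  expect_true(any(cf$source == 4 & cf$target == 2))
  # innovation covariance: unit diagonal, 0.1 off-diagonal, PD
  expect_equal(diag(s5$sigma), rep(1, 4))
  expect_equal(s5$sigma[1, 2], 0.1)
  expect_true(all(eigen(s5$sigma, only.values = TRUE)$values > 0))
  expect_error(scenario_spec(6), "1..5")
})

test_that("zero noise gives the all-zero latent series", {
  lat <- simulate_latent(scenario_spec(1), T_len = 30, seed = 1,
                         noise_scale = 0)
  expect_true(all(lat == 0))
})

test_that("latent simulation is reproducible and T-shaped", {
  l1 <- simulate_latent(scenario_spec(3), T_len = 40, seed = 5)
  l2 <- simulate_latent(scenario_spec(3), T_len = 40, seed = 5)
  expect_identical(unclass(l1), unclass(l2))
  expect_equal(dim(l1), c(40L, 3L))
  expect_error(simulate_latent(scenario_spec(1), T_len = 5, seed = 1),
               ">= 10")
})

test_that("injected innovations have the stated covariance", {
  lat <- simulate_latent(scenario_spec(1), T_len = 50000, seed = 6)
  e <- attr(lat, "innovations")
  S <- cov(e)
  expect_lt(abs(S[1, 2] - 0.1), 0.01)
  expect_lt(max(abs(diag(S) - 1)), 0.02)
})

test_that("scenario-1 cross coefficients are centred on zero", {
  est <- vapply(1:200, function(r) {
    lat <- simulate_latent(scenario_spec(1), T_len = 100, seed = 900 + r)
    var_fit(lat, 1)$coefficients["y1.l1", "y2"]
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est)), 3 * se)
})

test_that("inverse logit has the right values, symmetry and monotonicity", {
  expect_equal(inverse_logit(0), 0.5)
  expect_equal(inverse_logit(log(3)), 0.75)
  x <- seq(-5, 5, by = 0.25)
  s <- inverse_logit(x)
  expect_equal(s + inverse_logit(-x), rep(1, length(x)))
  expect_true(all(diff(s) > 0))
  expect_true(all(s > 0 & s < 1))
})

test_that("parameter mappings follow the family transforms", {
  expect_equal(map_parameters(0, "erdos_renyi"), 0.5)
  expect_equal(map_parameters(0, "regular"), 5)      # floor(10 * 0.5)
  expect_equal(map_parameters(0, "barabasi_albert"), 1)
  expect_equal(map_parameters(0, "watts_strogatz"), 0.5)
  expect_error(map_parameters(0, "gnm"), "unknown family")
})

test_that("latent value zero under the regular mapping gives lambda1 = 5", {
  gs <- latent_to_graphs(matrix(0, 12, 1), "regular", n = 30, seed = 2)
  y <- extract_features(gs)
  expect_true(all(abs(y - 5) < 1e-10))
})

test_that("latent-to-graph construction is deterministic given the seed", {
  lat <- simulate_latent(scenario_spec(2), T_len = 15, seed = 3)
  g1 <- latent_to_graphs(lat, "erdos_renyi", n = 20, seed = 4)
  g2 <- latent_to_graphs(lat, "erdos_renyi", n = 20, seed = 4)
  expect_identical(g1[[1]]$graphs, g2[[1]]$graphs)
  expect_identical(g1[[2]]$graphs, g2[[2]]$graphs)
})

test_that("run_experiment returns a tidy rejection-rate table", {
  tab <- run_experiment(2, "erdos_renyi", n = 30, T_len = 25, reps = 3,
                        seed = 99)
  expect_equal(nrow(tab), 2L)
  expect_setequal(names(tab), c("scenario", "family", "n", "T", "source",
                                "target", "rejection_rate",
                                "reps_effective"))
  expect_true(all(tab$reps_effective <= 3))
  # rates are integer counts over the effective replicates
  counts <- tab$rejection_rate * tab$reps_effective
  expect_equal(counts, round(counts))
  expect_true(all(tab$rejection_rate >= 0 & tab$rejection_rate <= 1))
})
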