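test_that("closed-form solution matches known special cases", {
  # beta = 1/2, V0 = 0: V = (alpha t / 2)^2
  expect_equal(power_law_solution(c(1, 4), alpha = 1, beta = 0.5),
               c(0.25, 4))
  # beta = 0 is the linear regime: V = V0 + alpha (t - t0)
  expect_equal(power_law_solution(3, alpha = 2, beta = 0, V0 = 1), 7)
  # no growth from an empty tumor
  expect_equal(power_law_solution(c(1, 10), alpha = 0, beta = 0.5), c(0, 0))
})

test_that("solution agrees with RK4 integration of the growth ODE", {
  v <- power_law_solution(10, alpha = 2.1797, beta = 0.53)
  v_rk4 <- rk4_power_law(2.1797, 0.53, 10)
  expect_equal(v, v_rk4, tolerance = 1e-3)
  expect_equal(v, 141.3, tolerance = 1e-3)
})

test_that("solution satisfies dV/dt = alpha V^beta by finite differences", {
  set.seed(11)
  for (i in 1:20) {
    alpha <- runif(1, 0.1, 2.5)
    beta <- runif(1, 0.3, 0.95)
    t <- seq(0.1, 100, length.out = 400)
    h <- 1e-4
    v <- power_law_solution(t, alpha, beta)
    dv <- (power_law_solution(t + h, alpha, beta) -
             power_law_solution(t - h, alpha, beta)) / (2 * h)
    expect_lt(max(abs(dv - alpha * v^beta) / (alpha * v^beta)), 1e-4)
  }
})

test_that("beta < 1 never blows up; beta > 1 diverges at T*", {
  expect_true(is.finite(power_law_solution(1e6, alpha = 1, beta = 0.9)))
  # V0 > 0, beta > 1: finite below T* = V0^(1-beta)/(alpha(beta-1)), error past
  alpha <- 0.5; beta <- 1.5; V0 <- 1
  t_star <- V0^(1 - beta) / (alpha * (beta - 1))
  v_near <- power_law_solution(t_star * 0.999, alpha, beta, V0 = V0)
  expect_gt(v_near, power_law_solution(t_star * 0.9, alpha, beta, V0 = V0))
  expect_error(power_law_solution(t_star * 1.01, alpha, beta, V0 = V0),
               "blow-up")
  expect_error(power_law_solution(1, alpha = 1, beta = 1), "beta = 1")
})

test_that("fit recovers parameters exactly from noiseless data", {
  t <- seq(2, 24, by = 2)
  fit <- fit_power_law(t, power_law_solution(t, 1.0, 0.5))
  expect_equal(fit$alpha, 1.0, tolerance = 1e-6)
  expect_equal(fit$beta, 0.5, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_true(fit$converged)
})

test_that("fit recovers reference HOS-143B parameters within 1e-4", {
  t <- seq(8, 21, length.out = 10)
  fit <- fit_power_law(t, power_law_solution(t, 0.8803, 0.8649))
  expect_equal(fit$alpha, 0.8803, tolerance = 1e-4)
  expect_equal(fit$beta, 0.8649, tolerance = 1e-4)
  expect_identical(fit$tier, "High")
  expect_equal(fit$beta_cluster, 5 / 6)
})

test_that("noisy fit agrees with a dense grid-search oracle", {
  truth <- ground_truth("X", alpha = 0.9, beta = 0.7, rho5 = 1.5, rho10 = 1.6)
  vol <- simulate_volume_series(truth, seq(2, 24, by = 2),
                                noise_spec(volume_sigma = 0.05, seed = 77))
  fit <- fit_power_law(vol$time_days, vol$volume_mm3)
  gs <- grid_search_power_law(vol$time_days, vol$volume_mm3)
  # LM and the zoomed exhaustive search agree to the oracle's final resolution
  expect_lt(abs(fit$alpha - gs$alpha), gs$d_alpha)
  expect_lt(abs(fit$beta - gs$beta), gs$d_beta)
  expect_lte(sum((vol$volume_mm3 - power_law_solution(
    vol$time_days, fit$alpha, fit$beta))^2), gs$sse * (1 + 1e-6))
})

test_that("R-squared degrades as volume noise grows", {
  truth <- ground_truth("X", alpha = 0.9, beta = 0.7, rho5 = 1.5, rho10 = 1.6)
  t <- seq(2, 24, by = 2)
  r2 <- vapply(c(0, 0.05, 0.2), function(s) {
    vol <- simulate_volume_series(truth, t, noise_spec(volume_sigma = s,
                                                       seed = 5))
    fit_power_law(vol$time_days, vol$volume_mm3)$r_squared
  }, numeric(1L))
  expect_true(all(diff(r2) < 0))
  expect_equal(r2[1L], 1, tolerance = 1e-12)
})

test_that("median noisy-recovery error of alpha and beta is below 10%", {
  truth <- ground_truth("X", alpha = 0.9, beta = 0.7, rho5 = 1.5, rho10 = 1.6)
  t <- seq(2, 24, length.out = 12)
  err <- t(vapply(1:200, function(i) {
    vol <- simulate_volume_series(truth, t, noise_spec(volume_sigma = 0.05,
                                                       seed = i))
    fit <- fit_power_law(vol$time_days, vol$volume_mm3)
    c(abs(fit$alpha - 0.9) / 0.9, abs(fit$beta - 0.7) / 0.7)
  }, numeric(2L)))
  expect_lt(median(err[, 1L]), 0.10)
  expect_lt(median(err[, 2L]), 0.10)
})

test_that("fit input validation", {
  expect_error(fit_power_law(c(1, 2), c(1, 4)), "at least 3")
  expect_error(fit_power_law(c(1, 2, 2.5), c(5, 5, 5)), "distinct positive")
  expect_error(fit_power_law(c(1, 3, 2), c(1, 2, 3)), "strictly increasing")
})

test_that("growth tiers follow the inclusive lower-bound rule", {
  expect_identical(classify_growth_tier(2.1797), "High")
  expect_identical(classify_growth_tier(0.4663), "Medium high")
  expect_identical(classify_growth_tier(0.15), "Medium")
  expect_identical(classify_growth_tier(0.80), "High")
  expect_identical(classify_growth_tier(0.0801), "Low")
  expect_error(classify_growth_tier(0), "positive")
  expect_error(classify_growth_tier(-1), "positive")
})

test_that("beta clusters: nearest value, ties toward the smaller cluster", {
  expect_equal(assign_beta_cluster(0.7198), 3 / 4)
  expect_equal(assign_beta_cluster(0.6696), 2 / 3)
  expect_equal(assign_beta_cluster(0.75), 3 / 4)
  mid <- (2 / 3 + 3 / 4) / 2
  expect_equal(assign_beta_cluster(mid), 2 / 3)
  expect_error(assign_beta_cluster(1.1), "\\(0, 1\\)")
})

test_that("cluster assignment reproduces the reference groupings", {
  g <- reference_estimates("growth")
  cl <- assign_beta_cluster(g$beta)
  two_thirds <- sort(g$cell_line[cl == 2 / 3])
  three_quarters <- sort(g$cell_line[cl == 3 / 4])
  five_sixths <- sort(g$cell_line[cl == 5 / 6])
  expect_identical(two_thirds, sort(c("HOS", "OHS", "IOR/OS15")))
  expect_identical(three_quarters, sort(c("OSA", "Saos-2", "IOR/OS14")))
  expect_identical(five_sixths,
                   sort(c("MHM", "G-292", "Cal-72", "HOS-MNNG", "HAL",
                          "U2OS", "MG-63", "IOR/OS9", "ZK-58", "KPD",
                          "HOS-143B")))
})
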