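test_that("noiseless volume series follows the closed-form growth curve", {
  truth <- ground_truth("A", alpha = 1, beta = 0.5, rho5 = 1, rho10 = 1)
  v <- simulate_volume_series(truth, c(1, 4), noise_spec(volume_sigma = 0))
  expect_equal(v$volume_mm3, c(0.25, 4))
  truth2 <- ground_truth("B", alpha = 2.1797, beta = 0.53, rho5 = 1, rho10 = 1)
  v2 <- simulate_volume_series(truth2, 10, noise_spec(volume_sigma = 0))
  expect_equal(v2$volume_mm3, rk4_power_law(2.1797, 0.53, 10),
               tolerance = 1e-3)
})

test_that("noiseless volume series solves the growth ODE pointwise", {
  truth <- ground_truth("A", alpha = 0.9, beta = 0.72, rho5 = 1, rho10 = 1)
  t <- seq(0.5, 40, length.out = 400)
  h <- 1e-4
  ns <- noise_spec(volume_sigma = 0)
  v <- simulate_volume_series(truth, t, ns)$volume_mm3
  v_plus <- simulate_volume_series(truth, t + h, ns)$volume_mm3
  v_minus <- simulate_volume_series(truth, t - h, ns)$volume_mm3
  dv <- (v_plus - v_minus) / (2 * h)
  rhs <- 0.9 * v^0.72
  expect_lt(max(abs(dv - rhs) / rhs), 1e-4)
})

test_that("volume noise is multiplicative lognormal and keeps positivity", {
  truth <- ground_truth("A", alpha = 0.9, beta = 0.72, rho5 = 1, rho10 = 1)
  t <- seq(1, 30, by = 1)
  v <- simulate_volume_series(truth, t, noise_spec(volume_sigma = 0.3,
                                                   seed = 3))
  expect_true(all(v$volume_mm3 > 0))
  base <- simulate_volume_series(truth, t, noise_spec(volume_sigma = 0))
  lr <- log(v$volume_mm3 / base$volume_mm3)
  expect_lt(abs(mean(lr)), 0.3)  # centered log-ratio, sd 0.3, n = 30
})

test_that("confluence series honors the seeding condition and hour grid", {
  truth <- ground_truth("A", alpha = 1, beta = 0.7, rho5 = 1.92, rho10 = 2.16)
  c5 <- simulate_confluence_series(truth, 5, c(0, 24, 48),
                                   noise_spec(confluence_sigma = 0))
  expect_equal(c5$confluence_pct[1L], 5)  # initial condition at t = 0
  # half-capacity at t = ln(19)/1.92 days = 36.81 h under the 5% condition
  t_half_h <- 24 * log(19) / 1.92
  ch <- simulate_confluence_series(truth, 5, c(1, t_half_h),
                                   noise_spec(confluence_sigma = 0))
  expect_equal(ch$confluence_pct[2L], 50, tolerance = 1e-6)
  c10 <- simulate_confluence_series(truth, 10, c(0, 24),
                                    noise_spec(confluence_sigma = 0))
  expect_equal(c10$confluence_pct[1L], 10)
  expect_gt(c10$confluence_pct[2L], c5$confluence_pct[2L])
})

test_that("noiseless confluence is increasing, bounded, and saturates", {
  truth <- ground_truth("A", alpha = 1, beta = 0.7, rho5 = 1.5, rho10 = 1.5)
  hrs <- seq(0, 24 * 30 / 1.5, length.out = 300)
  cc <- simulate_confluence_series(truth, 5, hrs,
                                   noise_spec(confluence_sigma = 0))
  expect_true(all(diff(cc$confluence_pct) > 0))
  expect_true(all(cc$confluence_pct < 100))
  expect_equal(cc$confluence_pct[300L], 100, tolerance = 1e-6)
})

test_that("noisy confluence is clipped to [0.1, 100]", {
  truth <- ground_truth("A", alpha = 1, beta = 0.7, rho5 = 2, rho10 = 2)
  cc <- simulate_confluence_series(truth, 5, seq(0, 120, by = 2),
                                   noise_spec(confluence_sigma = 25, seed = 9))
  expect_true(all(cc$confluence_pct >= 0.1 & cc$confluence_pct <= 100))
})

test_that("asymptotic radii are exactly linear; exact radii fall below", {
  truth <- ground_truth("A", alpha = 1, beta = 0.7, rho5 = 1, rho10 = 1, D = 1)
  r <- simulate_radius_series(truth, c(1, 2, 3), mode = "asymptotic")
  expect_equal(r$radius_mm, c(2, 4, 6))
  expect_equal(diff(r$radius_mm, differences = 2), 0)
  truth2 <- ground_truth("B", alpha = 1, beta = 0.7, rho5 = 1.5, rho10 = 1.5,
                         D = 0.01)
  t <- seq(5, 40, by = 5)
  ra <- simulate_radius_series(truth2, t, mode = "asymptotic")
  re <- simulate_radius_series(truth2, t, mode = "exact", u_star_ratio = 1e-3)
  log_term <- log(8 * 1e-3 * (pi * 0.01 * t)^(3 / 2))
  expect_true(all((re$radius_mm < ra$radius_mm) == (log_term > 0) |
                    log_term <= 0))
  # where the log term is negative the exact radius exceeds the front law
  expect_true(all(re$radius_mm[log_term < 0] > ra$radius_mm[log_term < 0]))
})

test_that("generator rejects invalid ground truth and time grids", {
  expect_error(ground_truth("A", alpha = 0, beta = 0.5, rho5 = 1, rho10 = 1),
               "alpha")
  expect_error(ground_truth("A", alpha = 1, beta = 1, rho5 = 1, rho10 = 1),
               "beta = 1")
  expect_error(ground_truth("A", alpha = 1, beta = 1.2, rho5 = 1, rho10 = 1),
               "blow-up")
  truth <- ground_truth("A", alpha = 1, beta = 0.5, rho5 = 1, rho10 = 1)
  expect_error(simulate_volume_series(truth, c(2, 1), noise_spec()),
               "strictly increasing")
  expect_error(simulate_confluence_series(truth, 5, numeric(0), noise_spec()),
               "non-empty")
})

test_that("identical seeds give bit-identical panels, new seeds differ", {
  truths <- ref_truths()[1:3]
  p1 <- simulate_panel(truths, noise_spec(seed = 99))
  p2 <- simulate_panel(truths, noise_spec(seed = 99))
  expect_identical(p1, p2)
  p3 <- simulate_panel(truths, noise_spec(seed = 100))
  expect_false(identical(p1$volumes$volume_mm3, p3$volumes$volume_mm3))
  # byte-identical CSV output under a fixed seed
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_output_csv(p1$volumes, f1)
  write_output_csv(p2$volumes, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("panel generation does not disturb the global RNG stream", {
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(simulate_panel(ref_truths()[1:2], noise_spec()))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("panel enforces unique ids and returns the full bundle", {
  tr <- ref_truths()[["HOS"]]
  expect_error(simulate_panel(list(tr, tr), noise_spec()), "duplicate")
  p <- simulate_panel(ref_truths(), noise_spec(seed = 1))
  expect_identical(sort(unique(p$volumes$cell_line)),
                   sort(names(ref_truths())))
  expect_setequal(unique(p$confluence$condition), c("5%", "10%"))
  # replicate structure follows the per-line n5/n10 counts
  n_rep <- tapply(p$confluence$replicate,
                  paste(p$confluence$cell_line, p$confluence$condition), max)
  expect_equal(unname(n_rep[paste("HOS", "5%")]),
               ref_truths()[["HOS"]]$n5)
})

test_that("noiseless single-line panel is recovered exactly downstream", {
  tr <- ground_truth("SOLO", alpha = 0.6, beta = 0.75, rho5 = 1.4,
                     rho10 = 1.6, n5 = 2L, n10 = 2L, D = 5e-3)
  p <- simulate_panel(list(tr), noise_spec(volume_sigma = 0,
                                           confluence_sigma = 0))
  res <- run_pipeline(p$volumes, p$confluence, p$levels)
  expect_equal(res$growth_fits$alpha, 0.6, tolerance = 1e-6)
  expect_equal(res$growth_fits$beta, 0.75, tolerance = 1e-6)
  expect_equal(res$proliferation_fits$rho5, 1.4, tolerance = 1e-6)
  expect_equal(res$proliferation_fits$rho10, 1.6, tolerance = 1e-6)
})

test_that("synthetic tumorigenicity level tracks alpha across the panel", {
  p <- simulate_panel(ref_truths(), noise_spec(seed = 4))
  expect_true(all(p$levels$TL %in% 1:4))
  expect_gt(cor(p$ground_truth$alpha, p$levels$TL, method = "spearman"), 0.9)
})
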