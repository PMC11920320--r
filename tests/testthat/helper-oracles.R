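# Independent numerical oracles used to freeze expected values.
# These deliberately avoid the package's closed-form code paths.

# RK4 integration of dV/dt = alpha * V^beta from a tiny positive volume at
# t = 0 (the V0 = 0 solution is its limit for beta < 1).
rk4_power_law <- function(alpha, beta, t_end, v_eps = 1e-12, dt = 1e-3) {
  f <- function(v) alpha * v^beta
  v <- v_eps
  n <- ceiling(t_end / dt)
  dt <- t_end / n
  for (i in seq_len(n)) {
    k1 <- f(v)
    k2 <- f(v + dt / 2 * k1)
    k3 <- f(v + dt / 2 * k2)
    k4 <- f(v + dt * k3)
    v <- v + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  v
}

# Dense grid-search least squares for the power-law fit: exhaustive search
# over (alpha, beta) in [0.01, 3] x [0.3, 0.95], zooming around the best node
# so the oracle converges to the continuous minimizer.
grid_search_power_law <- function(times, volumes, n = 61L, rounds = 4L) {
  a_range <- c(0.01, 3); b_range <- c(0.3, 0.95)
  best <- c(NA, NA); best_sse <- Inf
  for (round in seq_len(rounds)) {
    alpha_grid <- seq(a_range[1L], a_range[2L], length.out = n)
    beta_grid <- seq(b_range[1L], b_range[2L], length.out = n)
    for (b in beta_grid) {
      e <- 1 / (1 - b)
      for (a in alpha_grid) {
        pred <- (a * (1 - b) * times)^e
        sse <- sum((volumes - pred)^2)
        if (sse < best_sse) { best_sse <- sse; best <- c(a, b) }
      }
    }
    da <- diff(alpha_grid[1:2]); db <- diff(beta_grid[1:2])
    a_range <- c(max(0.001, best[1L] - 3 * da), best[1L] + 3 * da)
    b_range <- c(max(0.05, best[2L] - 3 * db), min(0.99, best[2L] + 3 * db))
  }
  list(alpha = best[1L], beta = best[2L], sse = best_sse,
       d_alpha = da, d_beta = db)
}

# 1-D least-squares oracle for the logistic rate (golden-section via optimize).
golden_rho <- function(times, confluence, N0, k = 100,
                       interval = c(0.01, 10)) {
  sse <- function(rho) {
    e <- exp(rho * times)
    sum((confluence - k * N0 * e / (k + N0 * (e - 1)))^2)
  }
  stats::optimize(sse, interval, tol = 1e-10)$minimum
}

# Thomas algorithm for tridiagonal systems (a sub, b diag, c super).
thomas_solve <- function(a, b, c, d) {
  n <- length(b)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- c[1] / b[1]; dp[1] <- d[1] / b[1]
  for (i in 2:n) {
    m <- b[i] - a[i] * cp[i - 1]
    cp[i] <- if (i < n) c[i] / m else 0
    dp[i] <- (d[i] - a[i] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

# Crank-Nicolson solve of u_t = D*Laplacian(u) + rho*u in radial coordinates
# (via w = r*u, so w_t = D*w_rr + rho*w), starting from a given radial
# profile u0(r) at t0 and integrating to t1.  Returns u(r_query, t1).
cn_radial_pde <- function(u0_fun, D, rho, t0, t1, r_query,
                          R = 4, nr = 800, nt = 1800) {
  r <- seq(0, R, length.out = nr + 1L)
  dr <- r[2L] - r[1L]
  dt <- (t1 - t0) / nt
  w <- r * u0_fun(r)
  inner <- 2:nr  # Dirichlet w = 0 at r = 0 and r = R
  aa <- D * dt / (2 * dr^2)
  bb <- rho * dt / 2
  n <- length(inner)
  sub <- rep(-aa, n); sup <- rep(-aa, n)
  diag_l <- rep(1 + 2 * aa - bb, n)
  for (step in seq_len(nt)) {
    wi <- w[inner]
    rhs <- (1 - 2 * aa + bb) * wi +
      aa * (w[inner - 1L] + w[inner + 1L])
    w[inner] <- thomas_solve(sub, diag_l, sup, rhs)
    w[1L] <- 0; w[nr + 1L] <- 0
  }
  u <- w[-1L] / r[-1L]
  stats::approx(r[-1L], u, xout = r_query)$y
}

# Shared fixture: the 17-line reference ground truth and a noiseless panel.
ref_truths <- function() reference_ground_truth()
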