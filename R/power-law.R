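#' Closed-form solution of the power-law growth model
#'
#' Tumor volume under the allometric growth law dV/dt = alpha * V^beta with
#' initial condition V(t0) = V0.  For beta != 1 the solution is
#' \deqn{V(t) = [V_0^{1-\beta} + \alpha (1-\beta)(t - t_0)]^{1/(1-\beta)}.}
#' With V0 = 0 and beta < 1 this reduces to \eqn{[\alpha(1-\beta)(t-t_0)]^{1/(1-\beta)}},
#' the convention used throughout: the tumor is assumed vanishingly small but
#' nonzero at injection, and growth is sublinear with no finite-time blow-up.
#' For beta > 1 the solution diverges at the blow-up time
#' \eqn{T^* = t_0 + V_0^{1-\beta} / (\alpha(\beta - 1))}.
#'
#' @param t time, days (vectorized).
#' @param alpha growth rate, units mm^(3(1-beta))/day; must be >= 0.
#' @param beta scale exponent (dimensionless); beta = 1 is not supported.
#' @param V0 initial volume, mm^3 (default 0).
#' @param t0 reference time, days (default 0).
#' @return volumes in mm^3, same length as `t`.
#' @examples
#' power_law_solution(c(1, 4), alpha = 1, beta = 0.5)  # (t/2)^2
#' @export
power_law_solution <- function(t, alpha, beta, V0 = 0, t0 = 0) {
  stopifnot(is.numeric(t), length(alpha) == 1L, length(beta) == 1L)
  if (!is.finite(beta) || beta == 1) {
    stop("unsupported exponent: beta = 1 is excluded (exponential limit); ",
         "use a beta != 1", call. = FALSE)
  }
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  one_m_b <- 1 - beta
  bracket <- V0^one_m_b + alpha * one_m_b * (t - t0)
  if (beta > 1 && any(bracket <= 0)) {
    t_star <- t0 + V0^one_m_b / (alpha * (beta - 1))
    stop(sprintf(
      "blow-up domain error: solution diverges at T* = %.6g days; requested times reach beyond it",
      t_star), call. = FALSE)
  }
  # bracket can be exactly 0 at t = t0 when V0 = 0 (beta < 1): volume is 0 there
  bracket[bracket < 0] <- NA_real_
  bracket^(1 / one_m_b)
}

#' Classify a growth rate into a tier
#'
#' Ranks cell lines by the fitted power-law growth rate alpha.  Boundaries are
#' inclusive at the lower end of each tier: alpha >= 0.80 is "High",
#' 0.30 <= alpha < 0.80 "Medium high", 0.15 <= alpha < 0.30 "Medium", and
#' alpha < 0.15 "Low" (defaults; configurable).
#'
#' @param alpha growth rate(s), must be > 0.
#' @param thresholds named numeric vector of strictly decreasing lower bounds
#'   for all tiers but the lowest; the final tier label is `lowest`.
#' @param lowest label for values below every threshold.
#' @return character vector of tier labels.
#' @examples
#' classify_growth_tier(c(2.1797, 0.4663, 0.15, 0.08))
#' @export
classify_growth_tier <- function(alpha,
                                 thresholds = c("High" = 0.80,
                                                "Medium high" = 0.30,
                                                "Medium" = 0.15),
                                 lowest = "Low") {
  if (any(!is.finite(alpha) | alpha <= 0)) {
    stop("alpha must be positive and finite", call. = FALSE)
  }
  classify_tier(alpha, thresholds, lowest)
}

# Shared tier machinery: first threshold met (lower bound inclusive) wins.
classify_tier <- function(x, thresholds, lowest) {
  if (is.unsorted(rev(thresholds), strictly = TRUE)) {
    stop("tier thresholds must be strictly decreasing", call. = FALSE)
  }
  labels <- c(names(thresholds), lowest)
  idx <- vapply(x, function(xi) {
    hit <- which(xi >= thresholds)
    if (length(hit)) hit[1L] else length(labels)
  }, integer(1L))
  labels[idx]
}

#' Assign a scale exponent to its nearest allometric cluster
#'
#' Fitted exponents group around the classical allometric values 2/3, 3/4 and
#' 5/6; each beta is assigned to the nearest of these, ties broken toward the
#' smaller cluster.
#'
#' @param beta scale exponent(s) in (0, 1).
#' @param clusters candidate cluster values, ascending.
#' @return numeric vector of cluster values (elements of `clusters`).
#' @examples
#' assign_beta_cluster(c(0.7198, 0.6696, 0.8649))
#' @export
assign_beta_cluster <- function(beta, clusters = c(2 / 3, 3 / 4, 5 / 6)) {
  if (any(!is.finite(beta) | beta <= 0 | beta >= 1)) {
    stop("beta must lie in (0, 1)", call. = FALSE)
  }
  clusters <- sort(clusters)
  vapply(beta, function(b) {
    d <- abs(b - clusters)
    clusters[which(d == min(d))[1L]]  # ties -> smaller cluster
  }, numeric(1L))
}

#' Fitting configuration for the growth and proliferation models
#'
#' @param seed_alpha,seed_beta starting values for the power-law fit; the
#'   defaults (0.9, 0.9) reproduce the reference analysis.
#' @param seed_rho starting value for the logistic rate fit (1/day).
#' @param max_iterations,tolerance Levenberg-Marquardt control.
#' @param alpha_tiers,rho_tiers,D_tiers named decreasing lower bounds for the
#'   growth-rate, proliferation-rate and diffusivity tiers.
#' @param cv_cutoff coefficient-of-variation validity cutoff (default 0.5).
#' @param fit_N0 logical; if TRUE the logistic initial confluence is fitted
#'   rather than fixed at the nominal seeding density.
#' @return a list of class `fit_config`.
#' @export
fit_config <- function(seed_alpha = 0.9, seed_beta = 0.9, seed_rho = 1.0,
                       max_iterations = 200L, tolerance = 1e-10,
                       alpha_tiers = c("High" = 0.80, "Medium high" = 0.30,
                                       "Medium" = 0.15),
                       rho_tiers = c("High" = 1.70, "Medium high" = 1.49,
                                     "Medium" = 1.20),
                       D_tiers = c("High" = 8e-3, "Medium high" = 1e-3,
                                   "Medium" = 3e-4),
                       cv_cutoff = 0.5,
                       fit_N0 = FALSE) {
  stopifnot(max_iterations >= 1, tolerance > 0, cv_cutoff > 0)
  for (th in list(alpha_tiers, rho_tiers, D_tiers)) {
    if (is.unsorted(rev(th), strictly = TRUE)) {
      stop("tier thresholds must be strictly decreasing", call. = FALSE)
    }
  }
  structure(list(seed_alpha = seed_alpha, seed_beta = seed_beta,
                 seed_rho = seed_rho,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 alpha_tiers = alpha_tiers, rho_tiers = rho_tiers,
                 D_tiers = D_tiers, cv_cutoff = cv_cutoff, fit_N0 = fit_N0),
            class = "fit_config")
}

#' Fit the power-law growth model to a tumor volume series
#'
#' Unconstrained least-squares fit of the two-parameter solution
#' `power_law_solution()` to observed volumes, by Levenberg-Marquardt
#' iteration started at (`seed_alpha`, `seed_beta`).  The exponent beta = 1 is
#' excluded: iterates entering |beta - 1| < 1e-6 are nudged away by 1e-4, and
#' fits ending with alpha <= 0 or beta outside (0, 1.5) are flagged
#' `converged = FALSE` rather than reported silently.
#'
#' @param times observation days, strictly increasing, >= 0.
#' @param volumes observed volumes, mm^3, >= 0.
#' @param cell_line optional label carried into the result.
#' @param V0,t0 initial condition of the model (defaults 0, 0).
#' @param config a [fit_config()].
#' @return object of class `power_law_fit`: fields `alpha`, `beta`,
#'   `r_squared`, `tier`, `beta_cluster`, `converged`, `n_points`,
#'   `cell_line`.
#' @examples
#' t <- 3:14
#' v <- power_law_solution(t, alpha = 1, beta = 0.5)
#' fit_power_law(t, v)
#' @export
fit_power_law <- function(times, volumes, cell_line = NA_character_,
                          V0 = 0, t0 = 0, config = fit_config()) {
  check_series(times, volumes, min_points = 3L, t_min = 0)
  if (any(volumes < 0)) stop("volumes must be >= 0", call. = FALSE)
  if (length(unique(volumes[volumes > 0])) < 2L) {
    stop("need at least 2 distinct positive volumes to fit", call. = FALSE)
  }
  model <- function(t, alpha, beta) {
    # keep LM iterates off the removable singularity at beta = 1
    if (abs(beta - 1) < 1e-6) beta <- beta + sign(beta - 1 + 1e-12) * 1e-4
    one_m_b <- 1 - beta
    br <- V0^one_m_b + alpha * one_m_b * (t - t0)
    br[br < 0] <- 0
    br^(1 / one_m_b)
  }
  dat <- data.frame(t = times, V = volumes)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      V ~ model(t, alpha, beta), data = dat,
      start = list(alpha = config$seed_alpha, beta = config$seed_beta),
      control = minpack.lm::nls.lm.control(
        maxiter = config$max_iterations, ftol = config$tolerance)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- power_law_fit(NA_real_, NA_real_, NA_real_, NA_character_,
                         NA_real_, FALSE, length(times), cell_line)
    return(out)
  }
  cf <- stats::coef(fit)
  alpha_hat <- unname(cf["alpha"]); beta_hat <- unname(cf["beta"])
  pred <- model(times, alpha_hat, beta_hat)
  r2 <- r_squared(volumes, pred)
  ok <- is.finite(alpha_hat) && is.finite(beta_hat) &&
    alpha_hat > 0 && beta_hat > 0 && beta_hat < 1.5
  tier <- if (ok) classify_tier(alpha_hat, config$alpha_tiers, "Low") else NA_character_
  cluster <- if (ok && beta_hat > 0 && beta_hat < 1) {
    assign_beta_cluster(beta_hat)
  } else NA_real_
  power_law_fit(alpha_hat, beta_hat, r2, tier, cluster, ok,
                length(times), cell_line)
}

power_law_fit <- function(alpha, beta, r_squared, tier, beta_cluster,
                          converged, n_points, cell_line) {
  structure(list(cell_line = cell_line, alpha = alpha, beta = beta,
                 r_squared = r_squared, tier = tier,
                 beta_cluster = beta_cluster, converged = converged,
                 n_points = n_points),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("Power-law growth fit",
      if (!is.na(x$cell_line)) paste0("(", x$cell_line, ")"), "\n")
  cat(sprintf("  alpha = %.4f  beta = %.4f  R^2 = %.4f\n",
              x$alpha, x$beta, x$r_squared))
  cat(sprintf("  tier: %s   beta cluster: %s   n = %d   converged: %s\n",
              x$tier, format_cluster(x$beta_cluster), x$n_points, x$converged))
  invisible(x)
}

format_cluster <- function(cl) {
  if (is.na(cl)) return(NA_character_)
  lab <- c("2/3", "3/4", "5/6")
  val <- c(2 / 3, 3 / 4, 5 / 6)
  i <- which(abs(val - cl) < 1e-9)
  if (length(i)) lab[i] else format(cl)
}

r_squared <- function(obs, pred) {
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - ss_res / ss_tot
}

check_series <- function(times, values, min_points = 2L, t_min = -Inf,
                         strict_positive_t = FALSE) {
  if (length(times) != length(values)) {
    stop("times and values must have equal length", call. = FALSE)
  }
  if (length(times) < min_points) {
    stop(sprintf("need at least %d points", min_points), call. = FALSE)
  }
  if (any(!is.finite(times)) || any(!is.finite(values))) {
    stop("times and values must be finite", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (strict_positive_t && any(times <= 0)) {
    stop("times must be > 0", call. = FALSE)
  }
  if (any(times < t_min)) {
    stop(sprintf("times must be >= %g", t_min), call. = FALSE)
  }
  invisible(TRUE)
}
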