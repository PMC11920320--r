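#' Closed-form solution of the logistic confluence model
#'
#' Cell confluence under dN/dt = rho * N * (1 - N/k), N(0) = N0:
#' \deqn{N(t) = \frac{k N_0 e^{\rho t}}{k + N_0 (e^{\rho t} - 1)}.}
#' N is the percentage of the culture surface covered; the carrying capacity k
#' is 100 percent by convention.
#'
#' @param t time, days (vectorized).
#' @param rho proliferation rate, 1/day.
#' @param N0 initial confluence percent, in (0, k]; N0 = 0 is rejected.
#' @param k carrying capacity percent (default 100).
#' @return confluence percentages, same length as `t`.
#' @examples
#' logistic_solution(0:4, rho = 1.5, N0 = 5)
#' @export
logistic_solution <- function(t, rho, N0, k = 100) {
  stopifnot(is.numeric(t), length(rho) == 1L, length(N0) == 1L, length(k) == 1L)
  if (k <= 0) stop("carrying capacity k must be > 0", call. = FALSE)
  if (N0 <= 0 || N0 > k) {
    stop("N0 must lie in (0, k]: the model requires a nonzero inoculum",
         call. = FALSE)
  }
  e <- exp(rho * t)
  k * N0 * e / (k + N0 * (e - 1))
}

#' Fit the logistic model to pooled confluence replicates
#'
#' Least-squares estimate of the proliferation rate rho for one cell line and
#' seeding condition.  All replicate observations are pooled into a single
#' residual vector (so the fit is invariant to replicate order and uses every
#' point); N0 is fixed at the nominal seeding density by default, or fitted
#' jointly when `config$fit_N0` is TRUE.  Times are in days.
#'
#' @param times observation times in days (pooled across replicates; within
#'   each replicate strictly increasing).
#' @param confluence observed confluence percentages in [0, 100].
#' @param N0 nominal initial confluence percent (5 or 10 in the reference
#'   design).
#' @param cell_line,condition optional labels carried into the result.
#' @param n_replicates number of independent experiments pooled.
#' @param k carrying capacity percent, fixed (default 100).
#' @param config a [fit_config()].
#' @return object of class `logistic_fit`: `rho`, `N0`, `k`, `r_squared`,
#'   `n_replicates`, `n_points`, `converged`.
#' @examples
#' t <- seq(0, 4, by = 0.25)
#' fit_logistic(t, logistic_solution(t, 1.92, 5), N0 = 5)
#' @export
fit_logistic <- function(times, confluence, N0,
                         cell_line = NA_character_, condition = NA_character_,
                         n_replicates = 1L, k = 100, config = fit_config()) {
  if (length(times) != length(confluence)) {
    stop("times and confluence must have equal length", call. = FALSE)
  }
  if (length(times) < 3L) stop("need at least 3 points", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(confluence))) {
    stop("times and confluence must be finite", call. = FALSE)
  }
  if (any(confluence < 0 | confluence > 100)) {
    stop("confluence must lie in [0, 100]", call. = FALSE)
  }
  if (max(confluence) - min(confluence) < sqrt(.Machine$double.eps)) {
    stop("degenerate fit: confluence series is constant", call. = FALSE)
  }
  dat <- data.frame(t = times, N = confluence)
  ctrl <- minpack.lm::nls.lm.control(maxiter = config$max_iterations,
                                     ftol = config$tolerance)
  if (isTRUE(config$fit_N0)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(N ~ logistic_solution(t, rho, n0, k), data = dat,
                        start = list(rho = config$seed_rho, n0 = N0),
                        lower = c(-Inf, 1e-6), upper = c(Inf, k),
                        control = ctrl),
      error = function(e) NULL)
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(N ~ logistic_solution(t, rho, N0, k), data = dat,
                        start = list(rho = config$seed_rho), control = ctrl),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    return(structure(list(cell_line = cell_line, condition = condition,
                          rho = NA_real_, N0 = N0, k = k,
                          r_squared = NA_real_,
                          n_replicates = as.integer(n_replicates),
                          n_points = length(times), converged = FALSE),
                     class = "logistic_fit"))
  }
  cf <- stats::coef(fit)
  rho_hat <- unname(cf["rho"])
  N0_hat <- if (isTRUE(config$fit_N0)) unname(cf["n0"]) else N0
  pred <- logistic_solution(times, rho_hat, N0_hat, k)
  structure(list(cell_line = cell_line, condition = condition,
                 rho = rho_hat, N0 = N0_hat, k = k,
                 r_squared = r_squared(confluence, pred),
                 n_replicates = as.integer(n_replicates),
                 n_points = length(times), converged = is.finite(rho_hat)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  label <- if (!is.na(x$cell_line)) {
    paste0(" (", x$cell_line,
           if (!is.na(x$condition)) paste0(", ", x$condition), ")")
  } else ""
  cat("Logistic proliferation fit", label, "\n", sep = "")
  cat(sprintf("  rho = %.4f /day  N0 = %.2f%%  k = %g%%  R^2 = %.4f  (n = %d, %d pts)\n",
              x$rho, x$N0, x$k, x$r_squared, x$n_replicates, x$n_points))
  invisible(x)
}

#' Replicate-weighted average proliferation rate
#'
#' Combines the rates fitted at the 5 and 10 percent seeding conditions into
#' a single rate weighted by the number of independent experiments:
#' (rho5*n5 + rho10*n10) / (n5 + n10), and assigns a proliferation tier.
#'
#' @param rho5,rho10 fitted rates (1/day) at 5 and 10 percent seeding.
#' @param n5,n10 numbers of independent experiments (>= 1).
#' @param thresholds named decreasing lower bounds for the tiers.
#' @param lowest label below all thresholds.
#' @return object of class `weighted_rate` with fields `rho5`, `n5`, `rho10`,
#'   `n10`, `weighted_average`, `tier`.
#' @examples
#' weighted_average_rate(1.77, 4, 2.88, 2)  # 2.14
#' @export
weighted_average_rate <- function(rho5, n5, rho10, n10,
                                  thresholds = c("High" = 1.70,
                                                 "Medium high" = 1.49,
                                                 "Medium" = 1.20),
                                  lowest = "Low") {
  if (n5 < 1 || n10 < 1) stop("replicate counts must be >= 1", call. = FALSE)
  if ((n5 + n10) <= 0) stop("zero total replicates", call. = FALSE)
  wa <- (rho5 * n5 + rho10 * n10) / (n5 + n10)
  structure(list(rho5 = rho5, n5 = as.integer(n5),
                 rho10 = rho10, n10 = as.integer(n10),
                 weighted_average = wa,
                 tier = classify_tier(wa, thresholds, lowest)),
            class = "weighted_rate")
}

#' @export
print.weighted_rate <- function(x, ...) {
  cat(sprintf(
    "Weighted proliferation rate: (%.2f x %d + %.2f x %d)/%d = %.2f /day [%s]\n",
    x$rho5, x$n5, x$rho10, x$n10, x$n5 + x$n10, x$weighted_average, x$tier))
  invisible(x)
}
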