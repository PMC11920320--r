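#' Radius of a sphere of given volume
#'
#' Solid tumors are assumed to grow as spheres, so an observed volume V maps
#' to the radius r = (3V / (4*pi))^(1/3).
#'
#' @param volume volume(s), mm^3, >= 0.
#' @return radius in mm.
#' @examples
#' volume_to_radius(4 * pi / 3)  # 1
#' @export
volume_to_radius <- function(volume) {
  if (any(!is.finite(volume) | volume < 0)) {
    stop("volume must be finite and >= 0", call. = FALSE)
  }
  (3 * volume / (4 * pi))^(1 / 3)
}

#' Point-source solution of the linearized reaction-diffusion equation
#'
#' Cell density for u_t = D*Laplacian(u) + rho*u in three dimensions with a
#' Dirac point source of C0 cells at the origin at t = 0:
#' \deqn{u(r,t) = \frac{C_0}{8 (\pi D t)^{3/2}} \exp\left[\rho t - \frac{r^2}{4 D t}\right].}
#' A spreading Gaussian whose total mass grows as C0 * exp(rho*t).
#'
#' @param r radial distance, mm, >= 0 (vectorized; recycled against `t`).
#' @param t time, days, > 0 (the Dirac initial condition is singular at 0).
#' @param D diffusion coefficient, mm^2/day, > 0.
#' @param rho proliferation rate, 1/day.
#' @param C0 initial cell count at the source, > 0.
#' @return cell densities, cells/mm^3.
#' @export
point_source_density <- function(r, t, D, rho, C0) {
  stopifnot(length(D) == 1L, length(rho) == 1L, length(C0) == 1L)
  if (D <= 0 || C0 <= 0) stop("D and C0 must be > 0", call. = FALSE)
  if (any(t <= 0)) {
    stop("t must be > 0: the point-source solution is singular at t = 0",
         call. = FALSE)
  }
  if (any(r < 0)) stop("r must be >= 0", call. = FALSE)
  C0 / (8 * (pi * D * t)^(3 / 2)) * exp(rho * t - r^2 / (4 * D * t))
}

#' Squared detectable tumor radius of the point-source model
#'
#' The radius r* at which the density falls to the detection threshold u*
#' satisfies u(r*, t) = u*, giving
#' \deqn{r_*^2 = 4 D \rho t^2 - 4 D t \ln\left(\frac{8 u_*}{C_0} (\pi D t)^{3/2}\right).}
#' Only the ratio u*/C0 enters.  For large t the log term (order t*ln t) is
#' negligible against the leading 4*D*rho*t^2 term, so r* ~ 2*sqrt(D*rho)*t:
#' the front speed of the Fisher-Kolmogorov equation.
#'
#' @param t time(s), days, > 0.
#' @param D diffusion coefficient, mm^2/day, > 0.
#' @param rho proliferation rate, 1/day, > 0.
#' @param u_star_ratio detection threshold ratio u*/C0, 1/mm^3, > 0.
#' @return squared radii, mm^2.
#' @examples
#' detectable_radius_squared(20, D = 0.01, rho = 1.5, u_star_ratio = 1e-3)
#' @export
detectable_radius_squared <- function(t, D, rho, u_star_ratio) {
  stopifnot(length(D) == 1L, length(rho) == 1L, length(u_star_ratio) == 1L)
  if (D <= 0 || rho <= 0 || u_star_ratio <= 0) {
    stop("D, rho and u_star_ratio must be > 0", call. = FALSE)
  }
  if (any(t <= 0)) stop("t must be > 0", call. = FALSE)
  r2 <- 4 * D * rho * t^2 - 4 * D * t * log(8 * u_star_ratio * (pi * D * t)^(3 / 2))
  if (any(r2 < 0)) {
    bad <- t[r2 < 0][1L]
    stop(sprintf(
      "tumor not yet detectable at t = %g days (density everywhere below u*)",
      bad), call. = FALSE)
  }
  r2
}

#' Per-timepoint diffusion coefficient estimates from a radius trajectory
#'
#' Inverts the asymptotic front law r*^2 ~ 4*D*rho*t^2 at each observation:
#' D_i = r_i^2 / (4 * rho * t_i^2).  The summary reports their mean
#' (`D_bar`), sample standard deviation, coefficient of variation
#' cv = sd/D_bar, a validity flag (cv below `cv_cutoff`, default 50 percent
#' -- when the radius really grows linearly the per-timepoint estimates are
#' near-constant and the model is deemed to apply), and a diffusivity tier.
#'
#' @param times observation days, strictly increasing, all > 0.
#' @param radii tumor radii, mm, >= 0.
#' @param rho proliferation rate used in the inversion, 1/day, > 0 (in the
#'   pipeline this is the replicate-weighted in vitro rate of the cell line).
#' @param cell_line optional label.
#' @param cv_cutoff validity cutoff on the coefficient of variation.
#' @param thresholds named decreasing lower bounds for diffusivity tiers
#'   (mm^2/day).
#' @return object of class `diffusion_summary`: `per_timepoint_D`, `D_bar`,
#'   `sd`, `cv`, `valid`, `t_range`, `tier`, `n_points`.
#' @examples
#' t <- 5:15
#' r <- 2 * sqrt(0.0119 * 1.5) * t         # exactly linear front
#' estimate_diffusion(t, r, rho = 1.5)     # every estimate 0.0119, cv = 0
#' @export
estimate_diffusion <- function(times, radii, rho, cell_line = NA_character_,
                               cv_cutoff = 0.5,
                               thresholds = c("High" = 8e-3,
                                              "Medium high" = 1e-3,
                                              "Medium" = 3e-4)) {
  check_series(times, radii, min_points = 2L, strict_positive_t = TRUE)
  if (any(radii < 0)) stop("radii must be >= 0", call. = FALSE)
  if (rho <= 0) stop("rho must be > 0", call. = FALSE)
  D_i <- radii^2 / (4 * rho * times^2)
  D_bar <- mean(D_i)
  s <- stats::sd(D_i)  # sample (n-1) standard deviation
  cv <- s / D_bar
  structure(list(cell_line = cell_line,
                 per_timepoint_D = D_i, D_bar = D_bar, sd = s, cv = cv,
                 valid = cv < cv_cutoff,
                 t_range = c(times[1L], times[length(times)]),
                 tier = classify_tier(D_bar, thresholds, "Low"),
                 n_points = length(times)),
            class = "diffusion_summary")
}

#' @export
print.diffusion_summary <- function(x, ...) {
  cat("Diffusion estimate",
      if (!is.na(x$cell_line)) paste0("(", x$cell_line, ")"), "\n")
  cat(sprintf("  D_bar = %.3g mm^2/day  sd = %.3g  CV = %.0f%%  [%s, %s]\n",
              x$D_bar, x$sd, 100 * x$cv,
              if (x$valid) "model applies" else "model rejected", x$tier))
  cat(sprintf("  over days %g-%g (%d timepoints)\n",
              x$t_range[1L], x$t_range[2L], x$n_points))
  invisible(x)
}

#' Linear fit of a tumor radius trajectory
#'
#' Ordinary least-squares line through (t, r).  Under the point-source model
#' the detectable radius grows asymptotically at the Fisher-Kolmogorov front
#' speed v = 2*sqrt(D*rho), so the slope yields the cross-check estimate
#' D = slope^2 / (4*rho).
#'
#' @param times observation days, strictly increasing (>= 2 distinct values).
#' @param radii tumor radii, mm.
#' @param rho optional proliferation rate; if supplied, the slope-implied
#'   diffusion coefficient is included.
#' @return list: `slope` (mm/day), `intercept` (mm), `r_squared`, and
#'   `D_implied` when `rho` is given.
#' @export
fit_radius_linear <- function(times, radii, rho = NULL) {
  if (length(times) != length(radii)) {
    stop("times and radii must have equal length", call. = FALSE)
  }
  if (length(times) < 2L) stop("need at least 2 points", call. = FALSE)
  if (length(unique(times)) < 2L) {
    stop("singular design: all times identical", call. = FALSE)
  }
  fit <- stats::lm(radii ~ times)
  cf <- stats::coef(fit)
  out <- list(slope = unname(cf["times"]), intercept = unname(cf["(Intercept)"]),
              r_squared = r_squared(radii, stats::fitted(fit)))
  if (!is.null(rho)) {
    if (rho <= 0) stop("rho must be > 0", call. = FALSE)
    out$D_implied <- out$slope^2 / (4 * rho)
  }
  out
}
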