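#' Noise specification for the synthetic-data generator
#'
#' Volumes receive multiplicative lognormal noise (they span three orders of
#' magnitude and must stay positive); confluence receives additive Gaussian
#' noise clipped to [0.1, 100] (percent scale with hard bounds).  The same
#' seed always yields bit-identical output.
#'
#' @param volume_sigma sd of the lognormal log-scale term (dimensionless).
#' @param confluence_sigma additive sd in percentage points.
#' @param seed integer RNG seed.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(volume_sigma = 0.05, confluence_sigma = 2.0,
                       seed = 1L) {
  stopifnot(volume_sigma >= 0, confluence_sigma >= 0)
  structure(list(volume_sigma = volume_sigma,
                 confluence_sigma = confluence_sigma,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Ground-truth parameters for one synthetic cell line
#'
#' @param cell_line_id label.
#' @param alpha power-law growth rate (> 0), mm^(3(1-beta))/day.
#' @param beta scale exponent in (0, 1] excluding 1 (set
#'   `allow_blow_up = TRUE` to permit beta > 1 scenarios).
#' @param rho5,rho10 proliferation rates (1/day, > 0) at 5/10 percent seeding.
#' @param n5,n10 replicate counts (positive integers).
#' @param D diffusion coefficient (mm^2/day, > 0).
#' @param t_appearance day the tumor first becomes detectable (>= 0).
#' @param allow_blow_up permit beta outside (0, 1).
#' @return list of class `ground_truth`.
#' @export
ground_truth <- function(cell_line_id, alpha, beta, rho5, rho10,
                         n5 = 3L, n10 = 2L, D = 1e-3, t_appearance = 5,
                         allow_blow_up = FALSE) {
  stopifnot(length(cell_line_id) == 1L)
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (beta == 1) stop("beta = 1 is excluded", call. = FALSE)
  if (!allow_blow_up && (beta <= 0 || beta > 1)) {
    stop("beta must lie in (0, 1) unless blow-up scenarios are requested",
         call. = FALSE)
  }
  if (rho5 <= 0 || rho10 <= 0) stop("rho5 and rho10 must be > 0", call. = FALSE)
  if (n5 < 1 || n10 < 1) stop("replicate counts must be >= 1", call. = FALSE)
  if (D <= 0) stop("D must be > 0", call. = FALSE)
  if (t_appearance < 0) stop("t_appearance must be >= 0", call. = FALSE)
  structure(list(cell_line_id = as.character(cell_line_id), alpha = alpha,
                 beta = beta, rho5 = rho5, rho10 = rho10,
                 n5 = as.integer(n5), n10 = as.integer(n10), D = D,
                 t_appearance = t_appearance),
            class = "ground_truth")
}

# Run expr with a private RNG stream; global .Random.seed is untouched.
with_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate an in vivo tumor-volume series
#'
#' Evaluates the power-law solution with t0 = 0, V0 = 0 at the requested days
#' and applies multiplicative lognormal noise exp(eps),
#' eps ~ N(0, volume_sigma^2).
#'
#' @param truth a [ground_truth()].
#' @param times observation days, strictly increasing, >= 0.
#' @param noise a [noise_spec()].
#' @return data.frame with columns `cell_line`, `time_days`, `volume_mm3`.
#' @export
simulate_volume_series <- function(truth, times, noise = noise_spec()) {
  stopifnot(inherits(truth, "ground_truth"), inherits(noise, "noise_spec"))
  check_series(times, numeric(length(times)), min_points = 1L, t_min = 0)
  v <- power_law_solution(times, truth$alpha, truth$beta, V0 = 0, t0 = 0)
  if (noise$volume_sigma > 0) {
    eps <- with_rng(noise$seed,
                    stats::rnorm(length(times), 0, noise$volume_sigma))
    v <- v * exp(eps)
  }
  data.frame(cell_line = truth$cell_line_id, time_days = times,
             volume_mm3 = v, stringsAsFactors = FALSE)
}

#' Simulate an in vitro confluence series
#'
#' Evaluates the logistic solution (k = 100) for the chosen seeding condition
#' at the requested hours.  The time grid is generated in hours and converted
#' to days before the rate applies, matching the ingest convention.  Additive
#' Gaussian noise is clipped to [0.1, 100].
#'
#' @param truth a [ground_truth()].
#' @param condition seeding condition: 5 or 10 (percent).
#' @param times_hours observation hours, strictly increasing, >= 0.
#' @param noise a [noise_spec()].
#' @param replicate replicate index recorded in the output.
#' @return data.frame with columns `cell_line`, `condition`, `replicate`,
#'   `time_hours`, `confluence_pct`.
#' @export
simulate_confluence_series <- function(truth, condition = c(5, 10),
                                       times_hours, noise = noise_spec(),
                                       replicate = 1L) {
  stopifnot(inherits(truth, "ground_truth"), inherits(noise, "noise_spec"))
  condition <- match.arg(as.character(condition[1L]), c("5", "10"))
  if (length(times_hours) == 0L) stop("times must be non-empty", call. = FALSE)
  if (is.unsorted(times_hours, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  N0 <- as.numeric(condition)
  rho <- if (condition == "5") truth$rho5 else truth$rho10
  n <- logistic_solution(times_hours / 24, rho, N0, k = 100)
  if (noise$confluence_sigma > 0) {
    eps <- with_rng(noise$seed + replicate,
                    stats::rnorm(length(n), 0, noise$confluence_sigma))
    n <- pmin(pmax(n + eps, 0.1), 100)
  }
  data.frame(cell_line = truth$cell_line_id, condition = paste0(condition, "%"),
             replicate = as.integer(replicate), time_hours = times_hours,
             confluence_pct = n, stringsAsFactors = FALSE)
}

#' Simulate a detectable-radius series
#'
#' In `asymptotic` mode the radius follows the Fisher-Kolmogorov front law
#' exactly: r = 2*sqrt(D*rho)*t (linear in time).  In `exact` mode it is the
#' square root of the full detectable-radius law, which subtracts the
#' logarithmic correction; a time at which the tumor is not yet detectable
#' raises an error naming that time.
#'
#' @param truth a [ground_truth()]; its `D` and `rho5` are used (the 5 percent
#'   rate stands in for the in vitro rate).
#' @param times observation days, strictly increasing, all > 0.
#' @param mode `"asymptotic"` or `"exact"`.
#' @param u_star_ratio detection ratio u*/C0 for exact mode, in (0, 1).
#' @return data.frame with columns `cell_line`, `time_days`, `radius_mm`.
#' @export
simulate_radius_series <- function(truth, times,
                                   mode = c("asymptotic", "exact"),
                                   u_star_ratio = 1e-3) {
  stopifnot(inherits(truth, "ground_truth"))
  mode <- match.arg(mode)
  check_series(times, numeric(length(times)), min_points = 1L,
               strict_positive_t = TRUE)
  r <- if (mode == "asymptotic") {
    2 * sqrt(truth$D * truth$rho5) * times
  } else {
    if (u_star_ratio <= 0 || u_star_ratio >= 1) {
      stop("u_star_ratio must lie in (0, 1)", call. = FALSE)
    }
    sqrt(detectable_radius_squared(times, truth$D, truth$rho5, u_star_ratio))
  }
  data.frame(cell_line = truth$cell_line_id, time_days = times,
             radius_mm = r, stringsAsFactors = FALSE)
}

#' Simulate a full cell-line panel
#'
#' Generates, for each ground-truth line, one in vivo volume series, the two
#' confluence conditions with their replicate series, and synthetic phenotype
#' levels.  Tumorigenicity (TL) is an integer 1-4 assigned by alpha quartile
#' with small seed-controlled jitter, so it is monotone in alpha up to
#' bounded noise; PL is assigned the same way from the replicate-weighted
#' proliferation rate; CL, IL and ML are count-like scores monotone in alpha.
#' Output is deterministic under a fixed seed.
#'
#' @param truths list of [ground_truth()] objects with unique ids.
#' @param noise a [noise_spec()].
#' @param volume_times default in vivo grid (days); per-line grids start at
#'   each line's `t_appearance`.
#' @param confluence_hours in vitro grid (hours).
#' @param n_volume_points number of in vivo observations per line.
#' @return list of class `synthetic_panel` with data.frames `volumes`,
#'   `confluence`, `levels`, `ground_truth`.
#' @export
simulate_panel <- function(truths, noise = noise_spec(),
                           volume_times = NULL,
                           confluence_hours = seq(0, 120, by = 4),
                           n_volume_points = 12L) {
  if (length(truths) < 1L) stop("need at least one cell line", call. = FALSE)
  if (inherits(truths, "ground_truth")) truths <- list(truths)
  ids <- vapply(truths, `[[`, character(1L), "cell_line_id")
  if (anyDuplicated(ids)) {
    stop("duplicate cell line ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  vols <- list(); conf <- list()
  for (i in seq_along(truths)) {
    tr <- truths[[i]]
    tv <- if (is.null(volume_times)) {
      # observation window scales with growth: slow lines are followed longer
      t_end <- max(tr$t_appearance + 14, min(172, 25 / max(tr$alpha, 0.1)))
      seq(max(tr$t_appearance, 1), t_end, length.out = n_volume_points)
    } else volume_times
    ns <- noise; ns$seed <- noise$seed + 1000L * i
    vols[[i]] <- simulate_volume_series(tr, tv, ns)
    for (cond in c(5, 10)) {
      n_rep <- if (cond == 5) tr$n5 else tr$n10
      for (r in seq_len(n_rep)) {
        ns$seed <- noise$seed + 1000L * i + 100L * (cond == 10)
        conf[[length(conf) + 1L]] <-
          simulate_confluence_series(tr, cond, confluence_hours, ns,
                                     replicate = r)
      }
    }
  }
  truth_df <- data.frame(
    cell_line = ids,
    alpha = vapply(truths, `[[`, numeric(1L), "alpha"),
    beta = vapply(truths, `[[`, numeric(1L), "beta"),
    rho5 = vapply(truths, `[[`, numeric(1L), "rho5"),
    rho10 = vapply(truths, `[[`, numeric(1L), "rho10"),
    n5 = vapply(truths, `[[`, integer(1L), "n5"),
    n10 = vapply(truths, `[[`, integer(1L), "n10"),
    D = vapply(truths, `[[`, numeric(1L), "D"),
    stringsAsFactors = FALSE)
  levels_df <- with_rng(noise$seed + 7L, synth_levels(truth_df))
  structure(list(volumes = do.call(rbind, vols),
                 confluence = do.call(rbind, conf),
                 levels = levels_df, ground_truth = truth_df),
            class = "synthetic_panel")
}

# Ordinal 1-4 by quantile with occasional +/-1 jitter, clamped.
quartile_level <- function(x, jitter_p = 0.1) {
  q <- as.integer(cut(rank(x, ties.method = "first"), breaks = 4,
                      labels = FALSE))
  if (length(x) < 4L) q <- pmax(q, 1L)
  j <- stats::rbinom(length(x), 1L, jitter_p) *
    sample(c(-1L, 1L), length(x), replace = TRUE)
  pmin(pmax(q + j, 1L), 4L)
}

synth_levels <- function(truth_df) {
  alpha <- truth_df$alpha
  rho_w <- (truth_df$rho5 * truth_df$n5 + truth_df$rho10 * truth_df$n10) /
    (truth_df$n5 + truth_df$n10)
  n <- length(alpha)
  # count-like assay scores, monotone in alpha with ~10% relative jitter
  mono <- function(base) {
    round(base * (alpha / max(alpha)) * exp(stats::rnorm(n, 0, 0.1)))
  }
  data.frame(cell_line = truth_df$cell_line,
             TL = quartile_level(alpha),
             CL = mono(500), IL = mono(1200), ML = mono(2400),
             PL = quartile_level(rho_w),
             stringsAsFactors = FALSE)
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf(
    "Synthetic cell-line panel: %d lines, %d volume obs, %d confluence obs\n",
    nrow(x$ground_truth), nrow(x$volumes), nrow(x$confluence)))
  invisible(x)
}
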