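#' Pipeline configuration
#'
#' Bundles every tunable of the analysis: the fit seeds and tolerances, the
#' tier thresholds for alpha, rho and D, the CV validity cutoff, the
#' synthetic-noise specification and master seed, and the unit conventions
#' (days, mm, mm^3, percent).  Round-trips losslessly through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param fit a [fit_config()].
#' @param noise a [noise_spec()].
#' @param seed master seed for synthetic stages.
#' @param units fixed unit labels (informational).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(fit = fit_config(), noise = noise_spec(),
                            seed = 1L,
                            units = c(time = "days", length = "mm",
                                      volume = "mm3", confluence = "percent")) {
  structure(list(fit = fit, noise = noise, seed = as.integer(seed),
                 units = units),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- list(fit = unclass(config$fit), noise = unclass(config$noise),
            seed = config$seed, units = as.list(config$units))
  x$fit$alpha_tiers <- as.list(x$fit$alpha_tiers)
  x$fit$rho_tiers <- as.list(x$fit$rho_tiers)
  x$fit$D_tiers <- as.list(x$fit$D_tiers)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  f <- x$fit
  pipeline_config(
    fit = fit_config(seed_alpha = f$seed_alpha, seed_beta = f$seed_beta,
                     seed_rho = f$seed_rho,
                     max_iterations = f$max_iterations,
                     tolerance = f$tolerance,
                     alpha_tiers = unlist(f$alpha_tiers),
                     rho_tiers = unlist(f$rho_tiers),
                     D_tiers = unlist(f$D_tiers),
                     cv_cutoff = f$cv_cutoff, fit_N0 = f$fit_N0),
    noise = noise_spec(x$noise$volume_sigma, x$noise$confluence_sigma,
                       x$noise$seed),
    seed = x$seed, units = unlist(x$units))
}

new_run_log <- function() {
  env <- new.env(parent = emptyenv())
  env$entries <- character(0)
  env
}

log_event <- function(log, level, msg) {
  entry <- sprintf("%s [%s] %s",
                   format(Sys.time(), "%Y-%m-%d %H:%M:%S"), level, msg)
  log$entries <- c(log$entries, entry)
  invisible(entry)
}

# Small stable FNV-1a hash of the serialized config, for the run log.
config_hash <- function(config) {
  bytes <- serialize(unclass(config), NULL, version = 2L)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619 %% 2^31
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Fit the growth model to every cell line of a volume table
#'
#' @param volumes data.frame in the `volumes` schema
#'   (`cell_line,time_days,volume_mm3`).
#' @param config a [fit_config()].
#' @param log optional run log (internal).
#' @return data.frame: `cell_line`, `alpha`, `beta`, `r_squared`, `tier`,
#'   `beta_cluster`, `n_points`, `converged`; one row per line, failed lines
#'   carried with `converged = FALSE` / NA parameters.
#' @export
fit_growth_panel <- function(volumes, config = fit_config(), log = NULL) {
  rows <- lapply(split(volumes, volumes$cell_line), function(d) {
    d <- d[order(d$time_days), ]
    f <- tryCatch(
      fit_power_law(d$time_days, d$volume_mm3, cell_line = d$cell_line[1L],
                    config = config),
      error = function(e) {
        if (!is.null(log)) {
          log_event(log, "WARN", sprintf("growth fit failed for %s: %s",
                                         d$cell_line[1L], conditionMessage(e)))
        }
        NULL
      })
    if (is.null(f)) {
      return(data.frame(cell_line = d$cell_line[1L], alpha = NA_real_,
                        beta = NA_real_, r_squared = NA_real_,
                        tier = NA_character_, beta_cluster = NA_real_,
                        n_points = nrow(d), converged = FALSE,
                        stringsAsFactors = FALSE))
    }
    data.frame(cell_line = f$cell_line, alpha = f$alpha, beta = f$beta,
               r_squared = f$r_squared, tier = f$tier,
               beta_cluster = f$beta_cluster, n_points = f$n_points,
               converged = f$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(-out$alpha, out$cell_line, na.last = TRUE), , drop = FALSE]
}

#' Fit the logistic model to every (cell line, condition) of a confluence table
#'
#' Replicates are pooled into one residual vector per condition; the two
#' conditions are fit independently and combined by the replicate-weighted
#' average.  Number of replicates = number of distinct replicate indices.
#'
#' @param confluence data.frame in the `confluence` schema, with `time_days`
#'   present (as produced by [read_timeseries_csv()]) or computed from
#'   `time_hours`.
#' @param config a [fit_config()].
#' @param log optional run log (internal).
#' @return data.frame: `cell_line`, `rho5`, `n5`, `r2_5`, `rho10`, `n10`,
#'   `r2_10`, `weighted_average`, `tier`.
#' @export
fit_proliferation_panel <- function(confluence, config = fit_config(),
                                    log = NULL) {
  if (is.null(confluence$time_days)) {
    confluence$time_days <- confluence$time_hours / 24
  }
  fit_cond <- function(d, nominal) {
    d <- d[order(d$replicate, d$time_days), ]
    fit_logistic(d$time_days, d$confluence_pct, N0 = nominal,
                 cell_line = d$cell_line[1L],
                 condition = paste0(nominal, "%"),
                 n_replicates = length(unique(d$replicate)), config = config)
  }
  rows <- lapply(split(confluence, confluence$cell_line), function(d) {
    id <- d$cell_line[1L]
    res <- lapply(c(5, 10), function(nom) {
      di <- d[d$condition == paste0(nom, "%"), ]
      if (nrow(di) == 0L) return(NULL)
      tryCatch(fit_cond(di, nom), error = function(e) {
        if (!is.null(log)) {
          log_event(log, "WARN", sprintf(
            "logistic fit failed for %s at %d%%: %s", id, nom,
            conditionMessage(e)))
        }
        NULL
      })
    })
    f5 <- res[[1L]]; f10 <- res[[2L]]
    if (is.null(f5) || is.null(f10) || !f5$converged || !f10$converged) {
      return(data.frame(cell_line = id, rho5 = NA_real_, n5 = NA_integer_,
                        r2_5 = NA_real_, rho10 = NA_real_, n10 = NA_integer_,
                        r2_10 = NA_real_, weighted_average = NA_real_,
                        tier = NA_character_, stringsAsFactors = FALSE))
    }
    w <- weighted_average_rate(f5$rho, f5$n_replicates, f10$rho,
                               f10$n_replicates,
                               thresholds = config$rho_tiers)
    data.frame(cell_line = id, rho5 = f5$rho, n5 = f5$n_replicates,
               r2_5 = f5$r_squared, rho10 = f10$rho, n10 = f10$n_replicates,
               r2_10 = f10$r_squared, weighted_average = w$weighted_average,
               tier = w$tier, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(-out$weighted_average, out$cell_line, na.last = TRUE), ,
      drop = FALSE]
}

#' Estimate diffusion coefficients for every cell line
#'
#' Converts each line's tumor volumes to spherical radii, drops any t = 0
#' observation (the front law divides by t), and inverts the asymptotic front
#' law at each remaining timepoint using that line's replicate-weighted in
#' vitro proliferation rate.
#'
#' @param volumes data.frame in the `volumes` schema.
#' @param proliferation_fits output of [fit_proliferation_panel()].
#' @param config a [fit_config()].
#' @param log optional run log (internal).
#' @return data.frame: `cell_line`, `t_first`, `t_last`, `D_bar`, `sd`, `cv`,
#'   `valid`, `tier`.
#' @export
estimate_diffusion_panel <- function(volumes, proliferation_fits,
                                     config = fit_config(), log = NULL) {
  rows <- lapply(split(volumes, volumes$cell_line), function(d) {
    id <- d$cell_line[1L]
    empty <- data.frame(cell_line = id, t_first = NA_real_, t_last = NA_real_,
                        D_bar = NA_real_, sd = NA_real_, cv = NA_real_,
                        valid = NA, tier = NA_character_,
                        stringsAsFactors = FALSE)
    rho <- proliferation_fits$weighted_average[
      match(id, proliferation_fits$cell_line)]
    if (length(rho) != 1L || is.na(rho)) {
      if (!is.null(log)) {
        log_event(log, "WARN", sprintf(
          "no proliferation rate for %s; diffusion skipped", id))
      }
      return(empty)
    }
    d <- d[order(d$time_days), ]
    d <- d[d$time_days > 0, ]
    s <- tryCatch(
      estimate_diffusion(d$time_days, volume_to_radius(d$volume_mm3), rho,
                         cell_line = id, cv_cutoff = config$cv_cutoff,
                         thresholds = config$D_tiers),
      error = function(e) {
        if (!is.null(log)) {
          log_event(log, "WARN", sprintf(
            "diffusion estimate failed for %s: %s", id, conditionMessage(e)))
        }
        NULL
      })
    if (is.null(s)) return(empty)
    data.frame(cell_line = id, t_first = s$t_range[1L], t_last = s$t_range[2L],
               D_bar = s$D_bar, sd = s$sd, cv = s$cv, valid = s$valid,
               tier = s$tier, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(-out$D_bar, out$cell_line, na.last = TRUE), , drop = FALSE]
}

#' Run the full analysis pipeline
#'
#' Growth fits, proliferation fits, diffusion estimates, the joined phenotype
#' panel and its correlation matrix, in that order.  Inputs may be data
#' frames or CSV paths (validated by [read_timeseries_csv()]).  A failed fit
#' for one cell line never aborts the run: the line is logged and excluded
#' from downstream stages.  Output is deterministic for fixed inputs and
#' seed.
#'
#' @param volumes volumes table or CSV path.
#' @param confluence confluence table or CSV path.
#' @param levels phenotype-levels table or CSV path, or NULL to skip the
#'   panel/correlation stages.
#' @param config a [pipeline_config()].
#' @param output_dir if non-NULL, writes `growth_fits.csv`,
#'   `proliferation_fits.csv`, `diffusion.csv`, `panel.csv`,
#'   `correlation.csv` and `run_log.txt` there.
#' @return list of class `pipeline_result` with elements `growth_fits`,
#'   `proliferation_fits`, `diffusion`, `panel`, `correlation`, `log`.
#' @export
run_pipeline <- function(volumes, confluence, levels = NULL,
                         config = pipeline_config(), output_dir = NULL) {
  log <- new_run_log()
  log_event(log, "INFO", sprintf("osteokin %s, R %s, config %s",
                                 as.character(utils::packageVersion("osteokin")),
                                 getRversion(), config_hash(config)))
  if (is.character(volumes)) volumes <- read_timeseries_csv(volumes, "volumes")
  if (is.character(confluence)) {
    confluence <- read_timeseries_csv(confluence, "confluence")
  }
  if (is.character(levels)) levels <- read_timeseries_csv(levels, "levels")

  log_event(log, "INFO", "stage growth: fitting power-law model")
  growth <- fit_growth_panel(volumes, config$fit, log)
  if (all(!growth$converged)) {
    stop("pipeline error: no cell line produced a usable growth fit",
         call. = FALSE)
  }
  log_event(log, "INFO", "stage proliferation: fitting logistic model")
  prolif <- fit_proliferation_panel(confluence, config$fit, log)
  log_event(log, "INFO", "stage diffusion: estimating diffusion coefficients")
  diff <- estimate_diffusion_panel(volumes, prolif, config$fit, log)

  panel <- NULL; corr <- NULL
  if (!is.null(levels)) {
    log_event(log, "INFO", "stage panel: joining fits with phenotype levels")
    panel <- withCallingHandlers(
      build_panel(growth[growth$converged, , drop = FALSE], prolif, diff,
                  levels),
      warning = function(w) {
        log_event(log, "WARN", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (nrow(panel) >= 3L) {
      log_event(log, "INFO", "stage correlate: computing correlation matrix")
      corr <- correlation_matrix(panel)
    } else {
      log_event(log, "INFO",
                "stage correlate: skipped (fewer than 3 panel lines)")
    }
  }
  out <- structure(list(growth_fits = growth, proliferation_fits = prolif,
                        diffusion = diff, panel = panel, correlation = corr,
                        log = log$entries),
                   class = "pipeline_result")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_output_csv(growth, file.path(output_dir, "growth_fits.csv"))
    write_output_csv(prolif, file.path(output_dir, "proliferation_fits.csv"))
    write_output_csv(diff, file.path(output_dir, "diffusion.csv"))
    if (!is.null(panel)) {
      write_output_csv(panel, file.path(output_dir, "panel.csv"))
      write_correlation_csv(corr, file.path(output_dir, "correlation.csv"))
    }
    writeLines(log$entries, file.path(output_dir, "run_log.txt"))
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("osteokin pipeline result\n")
  cat(sprintf("  growth fits:        %d lines (%d converged)\n",
              nrow(x$growth_fits), sum(x$growth_fits$converged)))
  cat(sprintf("  proliferation fits: %d lines\n", nrow(x$proliferation_fits)))
  cat(sprintf("  diffusion:          %d lines (%d valid by CV rule)\n",
              nrow(x$diffusion), sum(x$diffusion$valid, na.rm = TRUE)))
  if (!is.null(x$panel)) {
    cat(sprintf("  panel:              %d lines x %d variables\n",
                nrow(x$panel), ncol(x$panel) - 1L))
  }
  invisible(x)
}
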