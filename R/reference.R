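#' Reference parameter estimates for the osteosarcoma cell-line panel
#'
#' Published kinetic parameter estimates for the osteosarcoma cell-line panel
#' of Lauvrak et al. (2013, British Journal of Cancer 109:2228-2236), obtained
#' by fitting the three models of this package to the panel's in vivo growth
#' and in vitro confluence curves, together with the panel's experimental
#' phenotype levels.  Four tables are shipped as plain CSV under
#' `inst/extdata`:
#'
#' * `"growth"` - per-line power-law growth rate `alpha`, scale exponent
#'   `beta`, fit R^2 (percent) and growth tier (17 lines).
#' * `"proliferation"` - logistic rates at 5 and 10 percent seeding with
#'   replicate counts, fit R^2 (percent), the replicate-weighted average rate
#'   and proliferation tier (21 lines).
#' * `"diffusion"` - mean diffusion coefficient `D_bar` (mm^2/day), its
#'   standard deviation, coefficient of variation (percent), the experimental
#'   time window and diffusivity tier (17 lines).
#' * `"panel"` - the joined summary: fitted `alpha`, `beta`, weighted `rho`,
#'   `D_bar` plus experimental phenotype levels TL (tumorigenicity), CL
#'   (colony formation), IL (invasion), ML (migration), PL (proliferation)
#'   (17 lines).
#'
#' The rates and coefficients are rounded as published (rates at 2 decimals,
#' diffusion values at 3 significant figures), so arithmetic recomputed from
#' these columns carries the corresponding propagated rounding error.
#'
#' @param table which table to return.
#' @return a data.frame.
#' @examples
#' head(reference_estimates("growth"))
#' @export
reference_estimates <- function(table = c("growth", "proliferation",
                                          "diffusion", "panel")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0("reference_", table, ".csv"),
                      package = "osteokin", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Ground-truth panel built from the reference estimates
#'
#' Assembles [ground_truth()] objects for the 17 cell lines present in all
#' three reference tables, using the published `alpha`, `beta`, `rho5`,
#' `rho10`, replicate counts and `D_bar`, with each line's first experimental
#' day as its tumor-appearance time.  This is the default parameterization of
#' the synthetic-data generator: simulations run under it share the parameter
#' ranges, observation windows and replicate structure of the real panel.
#'
#' @return named list of `ground_truth` objects.
#' @examples
#' names(reference_ground_truth())
#' @export
reference_ground_truth <- function() {
  g <- reference_estimates("growth")
  p <- reference_estimates("proliferation")
  d <- reference_estimates("diffusion")
  ids <- intersect(intersect(g$cell_line, p$cell_line), d$cell_line)
  out <- lapply(ids, function(id) {
    gi <- g[g$cell_line == id, ]; pi <- p[p$cell_line == id, ]
    di <- d[d$cell_line == id, ]
    ground_truth(id, alpha = gi$alpha, beta = gi$beta,
                 rho5 = pi$rho5, rho10 = pi$rho10,
                 n5 = pi$n5, n10 = pi$n10, D = di$D_bar,
                 t_appearance = di$t_first_days)
  })
  names(out) <- ids
  out
}
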