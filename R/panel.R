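#' Join fitted parameters with experimental phenotype levels
#'
#' Inner join of the three fit tables and the phenotype-level table on
#' `cell_line`.  Lines missing from any source are dropped with a warning
#' (only lines with every characteristic available enter the summary panel);
#' an empty join is an error.
#'
#' @param growth_fits data.frame with `cell_line`, `alpha`, `beta` (output of
#'   the growth stage).
#' @param proliferation_fits data.frame with `cell_line`,
#'   `weighted_average`.
#' @param diffusion data.frame with `cell_line`, `D_bar`.
#' @param levels data.frame with `cell_line`, `TL`, `CL`, `IL`, `ML`, `PL`.
#' @return data.frame with one row per retained cell line and columns
#'   `cell_line`, `alpha`, `beta`, `rho_weighted`, `D_bar`, `TL`, `CL`, `IL`,
#'   `ML`, `PL`.
#' @export
build_panel <- function(growth_fits, proliferation_fits, diffusion, levels) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("%s is missing column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  need(growth_fits, c("cell_line", "alpha", "beta"), "growth_fits")
  need(proliferation_fits, c("cell_line", "weighted_average"),
       "proliferation_fits")
  need(diffusion, c("cell_line", "D_bar"), "diffusion")
  need(levels, c("cell_line", "TL", "CL", "IL", "ML", "PL"), "levels")

  g <- growth_fits[stats::complete.cases(
    growth_fits[, c("cell_line", "alpha", "beta")]), ]
  all_ids <- unique(c(g$cell_line, proliferation_fits$cell_line,
                      diffusion$cell_line, levels$cell_line))
  keep <- Reduce(intersect, list(
    g$cell_line, proliferation_fits$cell_line, diffusion$cell_line,
    levels$cell_line[stats::complete.cases(levels)]))
  if (length(keep) == 0L) {
    stop("empty join: no cell line is present in all four inputs",
         call. = FALSE)
  }
  dropped <- setdiff(all_ids, keep)
  if (length(dropped)) {
    warning("dropped cell line(s) missing in one or more inputs: ",
            paste(sort(dropped), collapse = ", "), call. = FALSE)
  }
  m <- function(df, id) df[match(id, df$cell_line), , drop = FALSE]
  out <- data.frame(cell_line = keep,
                    alpha = m(g, keep)$alpha,
                    beta = m(g, keep)$beta,
                    rho_weighted = m(proliferation_fits, keep)$weighted_average,
                    D_bar = m(diffusion, keep)$D_bar,
                    stringsAsFactors = FALSE)
  cbind(out, m(levels, keep)[, c("TL", "CL", "IL", "ML", "PL"), drop = FALSE],
        row.names = NULL)
}

#' Correlation matrix of fitted parameters and phenotype levels
#'
#' Pairwise correlations over the panel variables (by default the four fitted
#' parameters and the five phenotype levels).  Pearson correlation on the raw
#' values is the default; Spearman is available for rank-based analysis of
#' the ordinal levels.
#'
#' @param panel data.frame as returned by [build_panel()].
#' @param variables columns to correlate.
#' @param method `"pearson"` or `"spearman"`.
#' @return square correlation matrix of class `correlation_matrix` (symmetric,
#'   unit diagonal) with a `method` attribute.
#' @export
correlation_matrix <- function(panel,
                               variables = c("alpha", "beta", "rho_weighted",
                                             "D_bar", "TL", "CL", "IL", "ML",
                                             "PL"),
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  miss <- setdiff(variables, names(panel))
  if (length(miss)) {
    stop("panel is missing variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(panel) < 3L) stop("need at least 3 records", call. = FALSE)
  x <- as.matrix(panel[, variables, drop = FALSE])
  if (!is.numeric(x)) stop("panel variables must be numeric", call. = FALSE)
  const <- variables[apply(x, 2L, function(v) stats::sd(v) == 0)]
  if (length(const)) {
    stop("correlation undefined for constant column(s): ",
         paste(const, collapse = ", "), call. = FALSE)
  }
  m <- stats::cor(x, method = method)
  structure(m, method = method, class = c("correlation_matrix", "matrix",
                                          "array"))
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("Correlation matrix (%s), %d variables\n",
              attr(x, "method"), ncol(x)))
  print(round(unclass(x), digits))
  invisible(x)
}
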