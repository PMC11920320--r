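ok_schemas <- list(
  volumes = c("cell_line", "time_days", "volume_mm3"),
  confluence = c("cell_line", "condition", "replicate", "time_hours",
                 "confluence_pct"),
  levels = c("cell_line", "TL", "CL", "IL", "ML", "PL")
)

#' Read and validate a pipeline input CSV
#'
#' Strict reader for the three input schemas (comma-separated, UTF-8, decimal
#' point, exact header):
#' * `volumes`: `cell_line,time_days,volume_mm3`
#' * `confluence`: `cell_line,condition,replicate,time_hours,confluence_pct`
#' * `levels`: `cell_line,TL,CL,IL,ML,PL`
#'
#' Non-numeric cells, negative values, and duplicate (cell line, time) keys
#' are parse errors reporting the offending data row.  Series are returned
#' sorted by time within each cell line (and condition/replicate).  For the
#' confluence schema the hour grid is converted to days in an added
#' `time_days` column, so that all rates downstream are per day.
#'
#' @param path CSV file path.
#' @param schema one of `"volumes"`, `"confluence"`, `"levels"`.
#' @return validated data.frame.
#' @export
read_timeseries_csv <- function(path, schema = c("volumes", "confluence",
                                                 "levels")) {
  schema <- match.arg(schema)
  expected <- ok_schemas[[schema]]
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  if (!identical(names(df), expected)) {
    stop(sprintf("%s: header must be exactly '%s' (got '%s')", path,
                 paste(expected, collapse = ","),
                 paste(names(df), collapse = ",")), call. = FALSE)
  }
  num_cols <- setdiff(expected, c("cell_line", "condition"))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & nzchar(df[[col]]))
    if (length(bad) || anyNA(v)) {
      row <- if (length(bad)) bad[1L] else which(is.na(v))[1L]
      stop(sprintf("%s: non-numeric value in column '%s' at data row %d",
                   path, col, row), call. = FALSE)
    }
    if (any(v < 0)) {
      stop(sprintf("%s: negative value in column '%s' at data row %d",
                   path, col, which(v < 0)[1L]), call. = FALSE)
    }
    df[[col]] <- v
  }
  if (schema == "volumes") {
    key <- paste(df$cell_line, df$time_days)
    if (anyDuplicated(key)) {
      stop(sprintf("%s: duplicate (cell_line, time) key at data row %d",
                   path, anyDuplicated(key)), call. = FALSE)
    }
    df <- df[order(df$cell_line, df$time_days), , drop = FALSE]
  } else if (schema == "confluence") {
    if (!all(df$condition %in% c("5%", "10%"))) {
      bad <- which(!(df$condition %in% c("5%", "10%")))[1L]
      stop(sprintf("%s: condition must be '5%%' or '10%%' at data row %d",
                   path, bad), call. = FALSE)
    }
    key <- paste(df$cell_line, df$condition, df$replicate, df$time_hours)
    if (anyDuplicated(key)) {
      stop(sprintf("%s: duplicate (cell_line, condition, replicate, time) key at data row %d",
                   path, anyDuplicated(key)), call. = FALSE)
    }
    if (any(df$confluence_pct > 100)) {
      stop(sprintf("%s: confluence above 100%% at data row %d", path,
                   which(df$confluence_pct > 100)[1L]), call. = FALSE)
    }
    df <- df[order(df$cell_line, df$condition, df$replicate, df$time_hours),
             , drop = FALSE]
    df$time_days <- df$time_hours / 24
  } else {
    if (anyDuplicated(df$cell_line)) {
      stop(sprintf("%s: duplicate cell_line at data row %d", path,
                   anyDuplicated(df$cell_line)), call. = FALSE)
    }
  }
  rownames(df) <- NULL
  df
}

#' Write a pipeline output CSV
#'
#' Unquoted comma-separated output.  With `digits = NULL` (machine mode)
#' numeric columns are written at full precision and the write-read-write
#' cycle is idempotent; with `digits` set (report mode) numerics are rounded,
#' mirroring the published tables' 4-decimal presentation.
#'
#' @param df data.frame.
#' @param path output path.
#' @param digits optional decimal places for report mode.
#' @return `path`, invisibly.
#' @export
write_output_csv <- function(df, path, digits = NULL) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- if (is.null(digits)) {
        vapply(out[[col]], function(x) {
          if (is.na(x)) "NA" else format(x, digits = 17, scientific = FALSE,
                                         trim = TRUE)
        }, character(1L))
      } else sprintf(paste0("%.", digits, "f"), out[[col]])
    }
  }
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a correlation matrix as a square CSV
#'
#' @param m a [correlation_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(m, path) {
  df <- data.frame(variable = rownames(m), as.data.frame(unclass(m),
                                                         check.names = FALSE),
                   check.names = FALSE)
  write_output_csv(df, path)
}

#' Read back a correlation CSV written by [write_correlation_csv()]
#'
#' @param path CSV path.
#' @return matrix with row and column names.
#' @export
read_correlation_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
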