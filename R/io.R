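#' Read and write pipeline CSV tables
#'
#' All pipeline tables are plain CSV with a header row; [write_table_csv()]
#' prepends a `#`-prefixed comment line carrying the units of each column
#' (the pipeline mixes pg, pg/mL and per-1e5-cell scales), and
#' [read_table_csv()] skips such comment lines.
#'
#' @param path File path.
#' @param x Data frame to write.
#' @param units Optional named character vector or single string recorded
#'   in the unit comment line.
#' @return `read_table_csv()` returns a data frame; `write_table_csv()`
#'   returns `path` invisibly.
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  fileEncoding = "UTF-8")
}

#' @rdname read_table_csv
#' @export
write_table_csv <- function(x, path, units = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(units)) {
    line <- if (is.null(names(units))) paste(units, collapse = "; ")
            else paste(names(units), units, sep = ": ", collapse = "; ")
    writeLines(paste("# units:", line), con)
  }
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

# required columns and per-schema checks
csv_schemas <- list(
  standards = list(
    columns = c("concentration_pg_ml", "mfi"),
    numeric = c("concentration_pg_ml", "mfi")
  ),
  events = list(
    columns = c("cell_id", "donor", "condition", "tnfa_signal", "il10_signal"),
    numeric = c("tnfa_signal", "il10_signal")
  ),
  elisa = list(
    columns = c("sample_id", "donor", "condition", "timepoint_h",
                "concentration_pg_ml", "volume_ml", "cell_count"),
    numeric = c("timepoint_h", "concentration_pg_ml", "volume_ml", "cell_count")
  ),
  timecourse = list(
    columns = c("donor", "condition", "timepoint_h", "amount_pg_per_1e5_cells"),
    numeric = c("timepoint_h", "amount_pg_per_1e5_cells")
  ),
  droplets = list(
    columns = c("droplet_id", "n_cells"),
    numeric = c("n_cells")
  )
)

#' Validate a pipeline CSV against its schema
#'
#' Checks required columns, numeric types, nonnegativity of signals and
#' counts, and monotonicity where the schema demands it (titration
#' standards must be strictly increasing in both concentration and
#' signal; timepoints must be strictly increasing within each
#' donor-condition series).
#'
#' @param path Path to the CSV file.
#' @param schema One of `"standards"`, `"events"`, `"elisa"`,
#'   `"timecourse"`, `"droplets"`.
#' @return `TRUE` (invisibly) if valid, otherwise a character vector of
#'   violations, each naming the offending column or row. An unreadable
#'   file raises an I/O error (distinct from schema violations).
#' @export
validate_csv <- function(path, schema) {
  schema <- match.arg(schema, names(csv_schemas))
  df <- read_table_csv(path)  # I/O errors propagate
  sc <- csv_schemas[[schema]]
  violations <- character()
  missing <- setdiff(sc$columns, names(df))
  if (length(missing)) {
    violations <- c(violations,
                    sprintf("missing required column `%s`", missing))
    return(violations)
  }
  for (col in sc$numeric) {
    if (!is.numeric(df[[col]]))
      violations <- c(violations, sprintf("column `%s` must be numeric", col))
  }
  if (length(violations)) return(violations)

  nonneg <- intersect(c("tnfa_signal", "il10_signal", "concentration_pg_ml",
                        "mfi", "n_cells", "amount_pg_per_1e5_cells",
                        "cell_count", "volume_ml"), names(df))
  for (col in nonneg) {
    bad <- which(df[[col]] < 0)
    if (length(bad))
      violations <- c(violations,
                      sprintf("column `%s` negative at row %d", col, bad[1]))
  }
  if (schema == "standards") {
    df <- df[order(df$concentration_pg_ml), , drop = FALSE]
    bad <- which(diff(df$mfi) <= 0)
    if (length(bad))
      violations <- c(violations,
                      sprintf("standards not strictly increasing in mfi at row %d", bad[1] + 1L))
    if (anyDuplicated(df$concentration_pg_ml))
      violations <- c(violations, "duplicate standard concentrations")
  }
  if (schema %in% c("timecourse", "elisa")) {
    key <- interaction(df$donor, df$condition,
                       if ("cytokine" %in% names(df)) df$cytokine else "",
                       drop = TRUE)
    for (g in split(df, key)) {
      if (anyDuplicated(g$timepoint_h)) {
        violations <- c(violations,
                        sprintf("duplicate timepoints in series %s/%s",
                                g$donor[1], g$condition[1]))
      }
    }
  }
  if (schema == "events" && anyDuplicated(df$cell_id))
    violations <- c(violations, "duplicate cell_id values")
  if (length(violations)) violations else invisible(TRUE)
}
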