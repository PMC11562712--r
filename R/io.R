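#' Write a table as CSV with full numeric precision
#'
#' Numbers are written with R's default 15-significant-digit conversion,
#' so they round-trip losslessly at the precision written.
#'
#' @param df data.frame.
#' @param path output file.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a long-format incubation area table
#'
#' Expects the dialect written by [generate_experiment()]: columns `site`,
#' `country`, `compound`, `vessel_type` (TEST/SC/HC), `replicate`,
#' `time_days` (or `time_hours`, converted to days on read), `area`,
#' `censored`. Schema violations are reported with the file and column.
#'
#' @param path CSV file.
#' @return data.frame in days.
#' @export
read_incubation_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("time_hours" %in% names(d) && !"time_days" %in% names(d)) {
    d$time_days <- d$time_hours / 24
    d$time_hours <- NULL
  }
  needed <- c("site", "country", "compound", "vessel_type", "replicate",
              "time_days", "area", "censored")
  missing <- setdiff(needed, names(d))
  if (length(missing)) {
    stop(path, ": missing columns: ", paste(missing, collapse = ", "))
  }
  if (!all(d$vessel_type %in% c("TEST", "SC", "HC"))) {
    bad <- which(!d$vessel_type %in% c("TEST", "SC", "HC"))[1L]
    stop(path, ": line ", bad + 1L, ", column vessel_type: unknown type '",
         d$vessel_type[bad], "'")
  }
  d$censored <- as.logical(d$censored)
  d
}

#' Write a rate matrix as wide CSVs
#'
#' Emits one compounds x sites CSV of values and one of per-cell statuses.
#'
#' @param rm a [rate_matrix()].
#' @param prefix path prefix; `<prefix>_values.csv` and
#'   `<prefix>_status.csv` are written.
#' @export
write_rate_matrix_csv <- function(rm, prefix) {
  vals <- data.frame(compound = rm$compounds, rm$values,
                     check.names = FALSE)
  stat <- data.frame(compound = rm$compounds, rm$status,
                     check.names = FALSE)
  write_table_csv(vals, paste0(prefix, "_values.csv"))
  write_table_csv(stat, paste0(prefix, "_status.csv"))
  invisible(prefix)
}
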