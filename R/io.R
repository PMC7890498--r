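# Result serialization: delimited time-series tables and JSON summaries
# with enough provenance (parameters, seed, schedule, version, config
# hash) to re-run any output exactly.

format_numeric_table <- function(df) {
  as.data.frame(lapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.12g", col) else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a simulation time series to a delimited text file
#'
#' Tab-separated, 12 significant digits, one row per output time.  An
#' empty result writes a header-only table.
#'
#' @param result a data frame ([run_treatment()] result, envelope, sweep
#'   table, ...).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(result, path) {
  ok <- tryCatch({
    write.table(format_numeric_table(as.data.frame(result)), path,
                sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_braintherm(sprintf("failed to write time series to '%s': %s",
                            path, conditionMessage(ok)),
                    "braintherm_io_error")
  invisible(path)
}

config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

provenance_block <- function(params = NULL, schedule = NULL, seed = NULL,
                             extra = list()) {
  prov <- list(
    package = "braintherm",
    version = as.character(packageVersion("braintherm")),
    seed = seed,
    parameters = if (!is.null(params)) unclass(params),
    schedule = if (!is.null(schedule)) unclass(schedule)
  )
  prov <- c(prov, extra)
  prov$config_hash <- config_hash(prov[c("parameters", "schedule", "seed")])
  prov
}

#' Write a summary (plus provenance) as JSON
#'
#' The file carries the metrics themselves and a provenance block with
#' the parameter set, schedule, seed, package version and a hash of the
#' configuration, so the run can be reproduced exactly.
#'
#' @param metrics an `ht_summary` (or any list of named scalars).
#' @param path output file path.
#' @param params,schedule,seed provenance; taken from `metrics`'
#'   originating result when passed explicitly by the caller.
#' @return `path`, invisibly.
#' @export
write_summary <- function(metrics, path, params = NULL, schedule = NULL,
                          seed = NULL) {
  payload <- list(
    summary = unclass(metrics),
    provenance = provenance_block(params, schedule, seed)
  )
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE, na = "null")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_braintherm(sprintf("failed to write summary to '%s': %s",
                            path, conditionMessage(ok)),
                    "braintherm_io_error")
  invisible(path)
}
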