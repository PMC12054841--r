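# Run artifacts: long-format CSV for field data, JSON sidecars and
# summaries. Writers are deterministic (fixed formatting, no timestamps in
# data files) so identical configs yield byte-identical CSVs.

.write_csv <- function(df, path) {
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  path
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  path
}

#' Write a field series as CSV plus JSON metadata sidecar
#'
#' @param fs a [field_series()].
#' @param path CSV path; the sidecar goes to `<path>.json`.
#' @param scenario optional `scenario` whose hash is recorded.
#' @return character vector of the files written.
#' @export
write_field_series <- function(fs, path, scenario = NULL) {
  stopifnot(inherits(fs, "field_series"))
  .write_csv(as.data.frame(fs), path)
  meta <- list(
    field_kind = fs$kind,
    units = switch(fs$kind, pressure = "Pa", concentration = "mol m^-3 (normalized)",
                   strain = "1"),
    mesh = list(length_m = fs$mesh$length, n_cells = fs$mesh$n_cells,
                dx_m = fs$mesh$dx, x0_m = fs$mesh$x0),
    n_times = length(fs$times), t_end_s = max(fs$times),
    scenario_hash = if (!is.null(scenario)) scenario_hash(scenario) else NULL)
  .write_json(meta, paste0(path, ".json"))
  c(path, paste0(path, ".json"))
}

#' Write a front trace as two-column CSV
#' @param ft a `front_trace`.
#' @param path CSV path.
#' @export
write_front_trace <- function(ft, path) {
  stopifnot(inherits(ft, "front_trace"))
  .write_csv(data.frame(time_s = ft$times, distance_m = ft$d), path)
}

#' Read an observed front from a two-column CSV (time_s, distance_m)
#' @param path CSV path.
#' @export
read_front_trace <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stop("observed front CSV needs two columns")
  structure(list(times = as.numeric(df[[1]]), d = as.numeric(df[[2]]),
                 theta_frac = NA_real_, definition = "observed"),
            class = "front_trace", crossed = TRUE)
}

#' Load a run configuration file (JSON)
#'
#' Top-level keys: `preset` (required), `overrides` (scenario fields, bare SI
#' numbers or `{value, unit}` records), `solver` (arguments of
#' [solver_config()]), `output` (free-form, recorded in the manifest).
#'
#' @param path JSON file path.
#' @return list with `scenario`, `solver`, `output`, `raw`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$preset)) stop("config: top-level 'preset' is required")
  s <- tryCatch(
    make_scenario(raw$preset, raw$overrides %||% list()),
    error = function(e) stop(sprintf("config field error under 'overrides': %s",
                                     conditionMessage(e)), call. = FALSE))
  solver <- do.call(solver_config, raw$solver %||% list())
  list(scenario = s, solver = solver, output = raw$output %||% list(),
       raw = raw)
}
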