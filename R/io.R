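#' Write a simulation trace to CSV
#'
#' Writes the canonical trace columns
#' `t_min,f_d,fgf,v_a,f_i,f_a,f_vrg,f_mus,f_fat,f_mv`, one row per
#' reporting interval, at full double precision so that
#' [read_timeseries()] round-trips losslessly.
#'
#' @param x a trace tibble, [simulate_phases()] result, or
#'   [simulate_scenario()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path) {
  trace <- as_trace(x)
  missing <- setdiff(trace_columns, names(trace))
  if (length(missing) > 0)
    abort(sprintf("trace is missing required columns: %s",
                  paste(missing, collapse = ", ")))
  if (nrow(trace) == 0L) abort("refusing to write an empty trace")
  readr::write_csv(trace[, trace_columns], path)
  invisible(path)
}

#' Read a simulation trace from CSV
#'
#' @param path path to a CSV written by [write_timeseries()].
#' @return A trace tibble with the canonical columns.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) abort(sprintf("trace file not found: %s", path))
  trace <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                    progress = FALSE),
    error = function(e) abort(sprintf("failed to read trace %s: %s", path,
                                      conditionMessage(e))))
  if (!identical(names(trace), trace_columns))
    abort(sprintf("unexpected header in %s: expected %s", path,
                  paste(trace_columns, collapse = ",")))
  if (nrow(trace) == 0L) abort(sprintf("trace file %s is empty", path))
  trace
}

#' Build a run manifest
#'
#' Collects everything needed to reproduce a simulation bit-identically:
#' package version, parameter provenance, scenario description, and
#' integrator settings.
#'
#' @param x an `emergence_sim` or `uptake_sim` object.
#' @param params_source provenance of the model parameters (`"packaged"`
#'   or a file path).
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(x, params_source = "packaged") {
  sim <- if (inherits(x, "emergence_sim")) x$sim else x
  stopifnot(inherits(sim, "uptake_sim"))
  scenario <- if (inherits(x, "emergence_sim")) {
    s <- x$scenario
    list(agent = s$agent$name, washout_va = s$washout_va,
         post_recovery_va = s$post_recovery_va,
         maintenance_min = s$maintenance_min,
         observation_min = s$observation_min,
         target_mac_multiple = s$target_mac_multiple)
  } else list(agent = sim$agent$name,
              phases = as.list(sim$phase_log$phase))
  structure(list(
    tool = "macawake",
    version = as.character(utils::packageVersion("macawake")),
    params_source = params_source,
    scenario = scenario,
    integrator = list(scheme = "rk4-fixed", dt_s = sim$dt * 60,
                      report_dt_s = sim$report_dt * 60),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
}

#' Write / read a run manifest
#'
#' @param manifest a [run_manifest()] object.
#' @param path output path (JSON).
#' @return `path` invisibly; `read_run_manifest()` returns the manifest
#'   list.
#' @export
write_run_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_manifest
#' @export
read_run_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("manifest not found: %s", path))
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "run_manifest")
}
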