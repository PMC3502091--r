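#' Tidy an emergence simulation
#'
#' @param x an [simulate_scenario()] result.
#' @param ... unused.
#' @return One row per scenario: washout time to MACawake, maintenance
#'   vessel-rich pressure, rehypnotization verdict, post-recovery peak.
#' @export
tidy.emergence_sim <- function(x, ...) {
  x$result
}

#' @rdname tidy.emergence_sim
#' @export
glance.emergence_sim <- function(x, ...) {
  dplyr::bind_cols(
    x$result[, c("agent", "t_macawake_min", "rehypnotized")],
    tibble(dt_s = x$sim$dt * 60, report_dt_s = x$sim$report_dt * 60,
           n_reported = nrow(x$sim$trace)))
}

#' Tidy a study grid
#'
#' @param x an [run_study()] result.
#' @param ... unused.
#' @return `tidy()`: one row per scenario with all emergence metrics.
#'   `glance()`: a one-row study summary.
#' @export
tidy.emergence_study <- function(x, ...) {
  x$results
}

#' @rdname tidy.emergence_study
#' @export
glance.emergence_study <- function(x, ...) {
  tibble(n_scenarios = nrow(x$results),
         n_agents = length(unique(x$results$agent)),
         n_rehypnotized = sum(x$results$rehypnotized),
         t_macawake_min_range = paste(
           round(range(x$times$t_macawake_min), 2), collapse = "-"),
         maintenance_min = x$settings$maintenance_min,
         observation_min = x$settings$observation_min)
}
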