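#' Ventilatory clearance of an inhaled agent
#'
#' Fraction of agent returning to the lung that is eliminated by
#' ventilation: `1 / (1 + lambda_B/G * Q / V_A)`.  Clearance rises with
#' alveolar ventilation and falls with blood solubility and cardiac
#' output, which is why ventilation changes move emergence times more for
#' soluble agents.
#'
#' @param lambda_blood blood/gas partition coefficient (>= 0).
#' @param q_total cardiac output, L/min (> 0).
#' @param v_a alveolar minute ventilation, L/min (> 0).
#' @return Clearance fraction in `[0, 1]`; vectorised over its arguments.
#' @examples
#' clearance(1.3, 5, 5)   # isoflurane baseline
#' clearance(0.42, 5, 10) # desflurane, hyperventilation
#' @export
clearance <- function(lambda_blood, q_total, v_a) {
  if (any(lambda_blood < 0)) abort_schema("lambda_blood", "must be non-negative")
  if (any(q_total <= 0)) abort_schema("q_total", "must be positive")
  if (any(v_a <= 0)) abort_schema("v_a", "must be positive")
  1 / (1 + lambda_blood * q_total / v_a)
}

#' Clearance across a cardiac output / ventilation grid
#'
#' Evaluates [clearance()] for each agent over a grid of cardiac outputs
#' and alveolar ventilations and expresses every cell as a percentage of
#' the baseline cell (Q = 5, V_A = 5 L/min by default).  Presentation
#' columns round to the conventional precisions (clearance to 2 decimals,
#' percentages to integers).
#'
#' @param agents a named list of [agent_params()] objects.
#' @param grid a data frame with columns `q_total` and `v_a`; must contain
#'   the baseline combination.
#' @param baseline baseline `c(q_total, v_a)` pair.
#' @return A tibble with one row per agent x grid cell: raw `clearance`
#'   and `pct_baseline` plus rounded `clearance_2dp` and
#'   `pct_baseline_int`.
#' @export
clearance_table <- function(agents = default_agents(),
                            grid = tibble(q_total = c(5, 5, 5, 2.5, 10),
                                          v_a = c(5, 2.5, 10, 5, 5)),
                            baseline = c(5, 5)) {
  if (!any(grid$q_total == baseline[1] & grid$v_a == baseline[2]))
    abort_schema("grid", "must contain the baseline (q_total, v_a) combination")
  purrr::map_dfr(agents, function(a) {
    cl <- clearance(a$lambda_blood, grid$q_total, grid$v_a)
    base <- clearance(a$lambda_blood, baseline[1], baseline[2])
    tibble(agent = a$name, q_total = grid$q_total, v_a = grid$v_a,
           clearance = cl, pct_baseline = 100 * cl / base,
           clearance_2dp = round(cl, 2),
           pct_baseline_int = round(100 * cl / base))
  })
}

#' First threshold crossing of a trace variable
#'
#' Locates the first time after `from_t` at which `variable` crosses
#' `level`, by linear interpolation between adjacent reported samples.
#' The crossing direction is inferred from the first sample at or after
#' `from_t`: a trace starting above the level is searched for a downward
#' crossing and vice versa.
#'
#' @param trace a trace tibble, [simulate_phases()] result, or
#'   [simulate_scenario()] result.
#' @param variable trace column to monitor (e.g. `"f_vrg"`).
#' @param level threshold, vol%.
#' @param from_t search start, min (absolute simulation time).
#' @return Crossing time, min (absolute); errors if the trace never
#'   crosses.
#' @export
time_to_threshold <- function(trace, variable = "f_vrg", level, from_t = 0) {
  trace <- as_trace(trace)
  if (!variable %in% names(trace))
    abort_schema("variable", sprintf("column '%s' not present in trace", variable))
  check_positive(level, "level")
  keep <- trace$t_min >= from_t - 1e-9
  if (!any(keep)) abort("`from_t` lies beyond the end of the trace")
  tt <- trace$t_min[keep]
  x <- trace[[variable]][keep]
  downward <- x[1] > level
  hit <- if (downward) which(x <= level) else which(x >= level)
  if (length(hit) == 0L)
    abort(sprintf("trace never crosses %s = %g vol%% after t = %g min",
                  variable, level, from_t),
          class = "macawake_no_crossing")
  i <- hit[1]
  if (i == 1L) return(tt[1])
  frac <- (x[i - 1] - level) / (x[i - 1] - x[i])
  tt[i - 1] + frac * (tt[i] - tt[i - 1])
}

#' Percent reduction of a recovery time
#'
#' `100 * (t_nv - t_hv) / t_nv`: the fraction of the normoventilation
#' recovery time saved by hyperventilation.  Rounding to integer percent
#' is left to presentation.
#'
#' @param t_nv recovery time under normoventilation, min (> 0).
#' @param t_hv recovery time under hyperventilation, min.
#' @return Percent reduction; vectorised.
#' @export
percent_reduction <- function(t_nv, t_hv) {
  if (any(t_nv <= 0)) abort_schema("t_nv", "must be positive")
  100 * (t_nv - t_hv) / t_nv
}

#' Detect rehypnotization after the MACawake crossing
#'
#' Scans the vessel-rich trace strictly after the MACawake crossing;
#' rehypnotization is declared iff any later sample exceeds 0.3 MAC
#' (strict inequality; touching the threshold does not count).  Also
#' returns the post-crossing peak and the decrement fractions
#' `F_VRG(t) / F_VRG(maintenance)` at the probe times, measured from agent
#' cut-off.
#'
#' @param trace trace tibble or simulation object extending beyond the
#'   crossing by at least 10 min.
#' @param agent an [agent_params()] object.
#' @param t_macawake crossing time, min from agent cut-off.
#' @param t_cutoff absolute time of agent cut-off in the trace, min.
#' @param baseline_fvrg maintenance vessel-rich pressure used for the
#'   decrement fractions; defaults to the trace value at `t_cutoff`.
#' @param probe_times probe times for decrement fractions, min from
#'   cut-off.
#' @param mac_multiple maintenance depth in MAC (the MACawake threshold is
#'   `0.3 * mac_multiple * mac`).
#' @return List with `result` (one-row tibble: `rehypnotized`,
#'   `peak_post_fvrg`, `t_peak_min` in min from cut-off) and `probes`
#'   (tibble of probe times, pressures, and fractions).
#' @export
detect_rehypnotization <- function(trace, agent, t_macawake, t_cutoff = 0,
                                   baseline_fvrg = NULL, probe_times = 30,
                                   mac_multiple = 1) {
  trace <- as_trace(trace)
  stopifnot(inherits(agent, "anes_agent"))
  threshold <- 0.3 * mac_multiple * agent$mac
  t_cross_abs <- t_cutoff + t_macawake
  post <- trace[trace$t_min > t_cross_abs + 1e-9, , drop = FALSE]
  if (nrow(post) == 0L || max(post$t_min) - t_cross_abs < 10)
    abort("post-crossing window shorter than 10 min; extend the observation window",
          class = "macawake_short_window")
  i_peak <- which.max(post$f_vrg)
  if (is.null(baseline_fvrg)) {
    at_cut <- which(trace$t_min <= t_cutoff + 1e-9)
    baseline_fvrg <- if (length(at_cut)) trace$f_vrg[max(at_cut)] else NA_real_
  }
  probes <- tibble(
    probe_min = probe_times,
    f_vrg = vapply(probe_times, function(p) {
      stats::approx(trace$t_min, trace$f_vrg, xout = t_cutoff + p)$y
    }, numeric(1)))
  probes$fraction <- probes$f_vrg / baseline_fvrg
  list(result = tibble(rehypnotized = any(post$f_vrg > threshold),
                       peak_post_fvrg = post$f_vrg[i_peak],
                       t_peak_min = post$t_min[i_peak] - t_cutoff),
       probes = probes)
}
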