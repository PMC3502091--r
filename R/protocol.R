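#' Define an emergence scenario
#'
#' One cell of the study design: an agent held at 1 MAC for a maintenance
#' period, washed out at high fresh gas flow under normo- or
#' hyperventilation until the vessel-rich group reaches MACawake
#' (0.3 MAC), then observed under a fixed post-recovery ventilation level.
#'
#' @param agent an [agent_params()] object or packaged agent name.
#' @param washout_va alveolar ventilation during washout, L/min (5 =
#'   normoventilation, 10 = hyperventilation).
#' @param post_recovery_va alveolar ventilation after the MACawake
#'   crossing, L/min; the studied grid is 0.5, 1, 1.5, 2.5 (hypoventilation)
#'   and 5, 10 (continued normo-/hyperventilation).
#' @param maintenance_min duration of 1-MAC maintenance, min.
#' @param observation_min length of the post-recovery observation window,
#'   min.
#' @param target_mac_multiple alveolar target during maintenance, in MAC.
#' @return An object of class `anes_scenario`.
#' @export
paper_scenario <- function(agent, washout_va = 5, post_recovery_va = 5,
                           maintenance_min = 480, observation_min = 120,
                           target_mac_multiple = 1) {
  if (is.character(agent)) agent <- agent_params(agent)
  if (!inherits(agent, "anes_agent")) abort("`agent` must be an agent_params() object")
  check_positive(washout_va, "washout_va")
  check_positive(post_recovery_va, "post_recovery_va")
  check_positive(maintenance_min, "maintenance_min")
  check_positive(observation_min, "observation_min")
  check_positive(target_mac_multiple, "target_mac_multiple")
  structure(list(agent = agent, washout_va = washout_va,
                 post_recovery_va = post_recovery_va,
                 maintenance_min = maintenance_min,
                 observation_min = observation_min,
                 target_mac_multiple = target_mac_multiple),
            class = "anes_scenario")
}

#' @export
print.anes_scenario <- function(x, ...) {
  cat(sprintf(
    "<anes_scenario> %s: %g min at %g MAC; washout V_A %g, post-recovery V_A %g L/min (%g min)\n",
    x$agent$name, x$maintenance_min, x$target_mac_multiple, x$washout_va,
    x$post_recovery_va, x$observation_min))
  invisible(x)
}

#' Overpressure induction and alveolar clamp phases
#'
#' Delivery controller for induction and maintenance: the vaporizer is held
#' at an overpressure setting until the alveolar pressure first attains the
#' target (a threshold event), after which the alveolar pressure is clamped
#' exactly at target and the delivered pressure is back-computed from the
#' circuit balance each step, bounded to `[0, overpressure_fd]`.  If the
#' target is never attained within the maintenance window an
#' unreachable-target error is raised by the integrator.
#'
#' @inheritParams paper_scenario
#' @param overpressure_fd vaporizer setting during wash-in, vol%; must
#'   exceed the target pressure.  Defaults to the agent's packaged value.
#' @param fgf,v_a fresh gas flow and alveolar ventilation during induction
#'   and maintenance, L/min.
#' @return A two-row phase schedule (see [sim_phase()]).
#' @export
induction_phases <- function(agent, target_mac_multiple = 1,
                             overpressure_fd = NULL, maintenance_min = 480,
                             fgf = 1, v_a = 5) {
  if (is.character(agent)) agent <- agent_params(agent)
  overpressure_fd <- overpressure_fd %||% agent$overpressure_fd
  target <- target_mac_multiple * agent$mac
  if (is.na(overpressure_fd))
    abort_schema("overpressure_fd", "no packaged overpressure setting for this agent; supply one")
  if (overpressure_fd <= target)
    abort_schema("overpressure_fd",
                 sprintf("overpressure (%g) must exceed the target pressure (%g vol%%)",
                         overpressure_fd, target))
  dplyr::bind_rows(
    sim_phase("washin", f_d = overpressure_fd, fgf = fgf, v_a = v_a,
              end = list(var = "f_a", cmp = ">=", level = target),
              cap = maintenance_min, on_cap = "error"),
    sim_phase("maintenance", fgf = fgf, v_a = v_a, mode = "clamp",
              clamp_target = target, fd_max = overpressure_fd,
              until = maintenance_min))
}

#' Build the full emergence protocol for a scenario
#'
#' Three stages: (1) overpressure induction plus 1-MAC alveolar clamp at
#' fresh gas flow 1 L/min and ventilation 5 L/min for the maintenance
#' period; (2) washout with delivery off and fresh gas flow raised to
#' 10 L/min (rebreathing-free) at the scenario's washout ventilation,
#' ending when the vessel-rich group falls to 0.3 MAC (MACawake), with a
#' `washout_cap` safety limit; (3) a fixed post-recovery observation window
#' at the scenario's post-recovery ventilation.
#'
#' @param scenario a [paper_scenario()] object.
#' @param washout_cap maximum washout duration before an error is raised,
#'   min.
#' @return A four-row phase schedule.
#' @export
build_protocol <- function(scenario, washout_cap = 240) {
  stopifnot(inherits(scenario, "anes_scenario"))
  agent <- scenario$agent
  macawake <- 0.3 * scenario$target_mac_multiple * agent$mac
  dplyr::bind_rows(
    induction_phases(agent, scenario$target_mac_multiple,
                     maintenance_min = scenario$maintenance_min),
    sim_phase("washout", f_d = 0, fgf = 10, v_a = scenario$washout_va,
              end = list(var = "f_vrg", cmp = "<=", level = macawake),
              cap = washout_cap, on_cap = "error"),
    sim_phase("post_recovery", f_d = 0, fgf = 10,
              v_a = scenario$post_recovery_va,
              duration = scenario$observation_min))
}

#' Simulate one emergence scenario end to end
#'
#' Runs [build_protocol()] through the integrator and derives the
#' emergence metrics: time from agent cut-off for the vessel-rich group to
#' reach MACawake (0.3 MAC, located by linear interpolation), the peak
#' post-recovery vessel-rich pressure, the rehypnotization verdict (any
#' sample strictly above 0.3 MAC after the crossing), and the decrement
#' fraction at the probe times.
#'
#' @inheritParams simulate_phases
#' @param scenario a [paper_scenario()] object.
#' @param probe_times times from agent cut-off (min) at which the
#'   vessel-rich decrement fraction is recorded.
#' @param washout_cap see [build_protocol()].
#' @return An object of class `emergence_sim`: list with `result` (one-row
#'   tibble of metrics), `probes` (decrement fractions), `sim` (the full
#'   [simulate_phases()] object), and the scenario.
#' @export
simulate_scenario <- function(scenario, body = body_params(),
                              dt = 0.25 / 60, report_dt = 1 / 60,
                              probe_times = 30, washout_cap = 240) {
  stopifnot(inherits(scenario, "anes_scenario"))
  sim <- simulate_phases(build_protocol(scenario, washout_cap),
                         scenario$agent, body, dt = dt, report_dt = report_dt)
  res <- emergence_metrics(sim, scenario, probe_times = probe_times)
  structure(c(res, list(sim = sim, scenario = scenario, body = body)),
            class = "emergence_sim")
}

# Shared metric extraction for a simulated scenario trace.  `sim` must
# contain the maintenance/washout/post_recovery phases of build_protocol().
emergence_metrics <- function(sim, scenario, probe_times = 30) {
  agent <- scenario$agent
  t_cut <- scenario$maintenance_min
  macawake <- 0.3 * scenario$target_mac_multiple * agent$mac
  trace <- sim$trace
  fvrg_maint <- trace$f_vrg[max(which(trace$t_min <= t_cut + 1e-9))]
  t_cross_abs <- time_to_threshold(trace, "f_vrg", macawake, from_t = t_cut)
  det <- detect_rehypnotization(trace, agent, t_macawake = t_cross_abs - t_cut,
                                t_cutoff = t_cut, baseline_fvrg = fvrg_maint,
                                probe_times = probe_times,
                                mac_multiple = scenario$target_mac_multiple)
  result <- tibble(
    agent = agent$name,
    washout_va = scenario$washout_va,
    post_recovery_va = scenario$post_recovery_va,
    maintenance_min = scenario$maintenance_min,
    fvrg_maintenance = fvrg_maint,
    t_macawake_min = t_cross_abs - t_cut,
    rehypnotized = det$result$rehypnotized,
    peak_post_fvrg = det$result$peak_post_fvrg,
    t_peak_min = det$result$t_peak_min)
  list(result = result, probes = det$probes)
}

#' @export
print.emergence_sim <- function(x, ...) {
  r <- x$result
  cat(sprintf("<emergence_sim> %s, washout V_A %g, post V_A %g L/min\n",
              r$agent, r$washout_va, r$post_recovery_va))
  cat(sprintf("  time to MACawake: %s after cut-off; rehypnotization: %s (peak F_VRG %.3f vol%% at %.1f min)\n",
              format_mmss(r$t_macawake_min), ifelse(r$rehypnotized, "YES", "no"),
              r$peak_post_fvrg, r$t_peak_min))
  invisible(x)
}

#' Format minutes as "m:ss"
#'
#' @param t_min time in minutes.
#' @return Character vector, whole minutes and seconds.
#' @export
format_mmss <- function(t_min) {
  sec <- round(t_min * 60)
  sprintf("%d min %02d s", sec %/% 60, sec %% 60)
}
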