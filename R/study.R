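#' Run the full emergence study grid
#'
#' Simulates every combination of agent x washout ventilation x
#' post-recovery ventilation (by default 3 x 2 x 6 = 36 scenarios:
#' desflurane/sevoflurane/isoflurane; washout under normoventilation
#' 5 L/min or hyperventilation 10 L/min; post-recovery ventilation 0.5, 1,
#' 1.5, 2.5, 5, 10 L/min) after 8 h of 1-MAC maintenance, and collects the
#' washout times to MACawake, the percent reductions achieved by
#' hyperventilation, the rehypnotization matrix, and decimated vessel-rich
#' traces for plotting.
#'
#' The maintenance and washout segments are integrated once per agent and
#' washout mode; the post-recovery arms branch from the stored state at
#' the MACawake crossing, so all arms of one agent/mode share their
#' crossing time exactly.
#'
#' @inheritParams simulate_scenario
#' @param agents named list of [agent_params()] objects.
#' @param washout_va washout ventilation levels, L/min.
#' @param post_recovery_va post-recovery ventilation levels, L/min.
#' @param maintenance_min,observation_min protocol durations, min.
#' @param trace_dt sampling interval of the stored plotting traces, min.
#' @return An object of class `emergence_study`: list with `times` (one
#'   row per agent x washout mode), `reductions` (per agent),
#'   `results` (one row per scenario, with rehypnotization verdicts,
#'   post-recovery peaks, and decrement fractions), `traces` (decimated
#'   vessel-rich trajectories from agent cut-off), and `settings`.
#' @export
run_study <- function(agents = default_agents(), body = body_params(),
                      washout_va = c(5, 10),
                      post_recovery_va = c(0.5, 1, 1.5, 2.5, 5, 10),
                      maintenance_min = 480, observation_min = 120,
                      dt = 0.25 / 60, report_dt = 1 / 60,
                      probe_times = 30, trace_dt = 0.1, washout_cap = 240) {
  arms <- tidyr::expand_grid(agent = names(agents), washout_va = washout_va)
  per_arm <- purrr::pmap(arms, function(agent, washout_va) {
    a <- agents[[agent]]
    macawake <- 0.3 * a$mac
    phases <- dplyr::bind_rows(
      induction_phases(a, maintenance_min = maintenance_min),
      sim_phase("washout", f_d = 0, fgf = 10, v_a = washout_va,
                end = list(var = "f_vrg", cmp = "<=", level = macawake),
                cap = washout_cap, on_cap = "error"))
    base <- simulate_phases(phases, a, body, dt = dt, report_dt = report_dt)
    trace <- base$trace
    t_cross_step <- base$phase_log$t_end[base$phase_log$phase == "washout"]
    t_cross <- time_to_threshold(trace, "f_vrg", macawake, from_t = maintenance_min)
    cut_idx <- max(which(trace$t_min <= maintenance_min + 1e-9))
    state_cross <- sim_state(
      f_i = trace$f_i[nrow(trace)], f_a = trace$f_a[nrow(trace)],
      f_vrg = trace$f_vrg[nrow(trace)], f_mus = trace$f_mus[nrow(trace)],
      f_fat = trace$f_fat[nrow(trace)])
    list(agent = a, washout_va = washout_va, base = base,
         t_cross_step = t_cross_step, t_macawake = t_cross - maintenance_min,
         fvrg_maint = trace$f_vrg[cut_idx], state_cross = state_cross)
  })

  results <- list(); traces <- list()
  for (arm in per_arm) {
    a <- arm$agent
    wash_trace <- arm$base$trace
    wash_trace <- wash_trace[wash_trace$t_min >= maintenance_min - 1e-9, , drop = FALSE]
    for (pv in post_recovery_va) {
      post <- simulate_phases(
        sim_phase("post_recovery", f_d = 0, fgf = 10, v_a = pv,
                  duration = observation_min),
        a, body, init = arm$state_cross, dt = dt, report_dt = report_dt,
        t0 = arm$t_cross_step)
      full <- dplyr::bind_rows(wash_trace, post$trace[-1, , drop = FALSE])
      det <- detect_rehypnotization(full, a, t_macawake = arm$t_macawake,
                                    t_cutoff = maintenance_min,
                                    baseline_fvrg = arm$fvrg_maint,
                                    probe_times = probe_times)
      frac <- stats::setNames(det$probes$fraction,
                              paste0("frac_", det$probes$probe_min, "min"))
      results[[length(results) + 1L]] <- dplyr::bind_cols(
        tibble(agent = a$name, washout_va = arm$washout_va,
               post_recovery_va = pv,
               t_macawake_min = arm$t_macawake,
               fvrg_maintenance = arm$fvrg_maint,
               rehypnotized = det$result$rehypnotized,
               peak_post_fvrg = det$result$peak_post_fvrg,
               t_peak_min = det$result$t_peak_min),
        as_tibble(as.list(frac)))
      grid_t <- seq(0, max(full$t_min) - maintenance_min, by = trace_dt)
      traces[[length(traces) + 1L]] <- tibble(
        agent = a$name, washout_va = arm$washout_va, post_recovery_va = pv,
        t_from_cutoff = grid_t,
        f_vrg = stats::approx(full$t_min - maintenance_min, full$f_vrg,
                              xout = grid_t)$y,
        mac = a$mac)
    }
  }
  results <- dplyr::bind_rows(results)
  times <- purrr::map_dfr(per_arm, ~ tibble(
    agent = .x$agent$name, washout_va = .x$washout_va,
    t_macawake_min = .x$t_macawake))
  reductions <- NULL
  if (length(washout_va) == 2L) {
    reductions <- times %>%
      dplyr::mutate(mode = ifelse(.data$washout_va == max(washout_va),
                                  "t_hv", "t_nv")) %>%
      dplyr::select("agent", "mode", "t_macawake_min") %>%
      tidyr::pivot_wider(names_from = "mode", values_from = "t_macawake_min") %>%
      dplyr::mutate(pct_reduction = percent_reduction(.data$t_nv, .data$t_hv))
  }
  structure(list(times = times, reductions = reductions, results = results,
                 traces = dplyr::bind_rows(traces),
                 settings = list(maintenance_min = maintenance_min,
                                 observation_min = observation_min,
                                 washout_va = washout_va,
                                 post_recovery_va = post_recovery_va,
                                 dt = dt, report_dt = report_dt,
                                 probe_times = probe_times)),
            class = "emergence_study")
}

#' @export
print.emergence_study <- function(x, ...) {
  cat(sprintf("<emergence_study> %d scenarios (%d agents x %d washout modes x %d post-recovery levels)\n",
              nrow(x$results), length(unique(x$results$agent)),
              length(x$settings$washout_va), length(x$settings$post_recovery_va)))
  cat("\nTime to MACawake (0.3 MAC in the vessel-rich group) from agent cut-off:\n")
  tw <- x$times %>%
    dplyr::mutate(time = format_mmss(.data$t_macawake_min))
  print(as.data.frame(tw), row.names = FALSE)
  if (!is.null(x$reductions)) {
    cat("\nReduction by hyperventilation (%):\n")
    rd <- x$reductions %>% dplyr::mutate(pct = round(.data$pct_reduction))
    print(as.data.frame(rd[, c("agent", "pct")]), row.names = FALSE)
  }
  cat("\nRehypnotization (post-recovery V_A with F_VRG rebound > 0.3 MAC):\n")
  m <- rehypnotization_matrix(x)
  print(as.data.frame(m), row.names = FALSE)
  invisible(x)
}

#' Rehypnotization verdicts in matrix layout
#'
#' @param study an [run_study()] result.
#' @return A tibble, one row per agent x washout mode, one logical column
#'   per post-recovery ventilation level.
#' @export
rehypnotization_matrix <- function(study) {
  stopifnot(inherits(study, "emergence_study"))
  study$results %>%
    dplyr::select("agent", "washout_va", "post_recovery_va", "rehypnotized") %>%
    tidyr::pivot_wider(names_from = "post_recovery_va",
                       values_from = "rehypnotized",
                       names_prefix = "va_")
}

#' Write study report files
#'
#' Emits the study summary (washout times and hyperventilation
#' reductions), the rehypnotization matrix, and one decimated vessel-rich
#' trace CSV per scenario, at conventional precisions (times to 1 s,
#' percents to integers).
#'
#' @param study an [run_study()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study_reports <- function(study, dir) {
  stopifnot(inherits(study, "emergence_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary_path <- file.path(dir, "study_summary.csv")
  times <- study$times %>%
    dplyr::mutate(t_macawake = format_mmss(.data$t_macawake_min),
                  t_macawake_s = round(.data$t_macawake_min * 60))
  red <- study$reductions %>%
    dplyr::mutate(pct_reduction = round(.data$pct_reduction))
  readr::write_csv(dplyr::left_join(times, red, by = "agent"), summary_path)
  matrix_path <- file.path(dir, "rehypnotization_matrix.csv")
  readr::write_csv(rehypnotization_matrix(study), matrix_path)
  trace_paths <- study$traces %>%
    dplyr::group_by(.data$agent, .data$washout_va, .data$post_recovery_va) %>%
    dplyr::group_map(function(tr, key) {
      p <- file.path(dir, sprintf("trace_%s_wash%g_post%g.csv",
                                  key$agent, key$washout_va,
                                  key$post_recovery_va))
      readr::write_csv(tr, p)
      p
    })
  invisible(c(summary_path, matrix_path, unlist(trace_paths)))
}
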