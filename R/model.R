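#' Model state vector
#'
#' Partial pressures (vol% of 1 atm) of the five model compartments:
#' breathing circuit (`f_i`, the inspired pressure), alveoli (`f_a`; the
#' model assumes instantaneous alveolo-capillary equilibration so the
#' arterial pressure equals `f_a`), and the vessel-rich, muscle and fat
#' tissue groups.
#'
#' @param f_i,f_a,f_vrg,f_mus,f_fat compartment partial pressures, vol%.
#' @return A named numeric vector of length 5.
#' @export
sim_state <- function(f_i = 0, f_a = 0, f_vrg = 0, f_mus = 0, f_fat = 0) {
  s <- c(f_i = f_i, f_a = f_a, f_vrg = f_vrg, f_mus = f_mus, f_fat = f_fat)
  if (any(!is.finite(s)) || any(s < 0))
    abort_schema("state", "partial pressures must be finite and non-negative")
  s
}

#' Mixed venous partial pressure
#'
#' Flow-weighted average of the tissue partial pressures returning to the
#' lung: `sum(Q_i * F_i) / sum(Q_i)` over the three tissue groups, with
#' `Q_i` the absolute tissue blood flows.  Because blood is treated as a
#' carrier with no volume of its own, this is an algebraic function of the
#' state, not a state variable.
#'
#' @param state a [sim_state()] vector.
#' @param body a [body_params()] object.
#' @return Mixed venous partial pressure, vol%.
#' @export
mixed_venous <- function(state, body = body_params()) {
  q <- body$q_total * c(body$f_vrg, body$f_mus, body$f_fat)
  sum(q * state[c("f_vrg", "f_mus", "f_fat")]) / sum(q)
}

#' Rate of change of the compartment pressures
#'
#' The mass-balance ODE system.  Circuit: fresh gas delivers `FGF * F_D`
#' and carries away `FGF * F_I`, while ventilation exchanges `V_A * (F_A -
#' F_I)` with the alveoli.  Alveoli: ventilation brings `V_A * (F_I -
#' F_A)`; pulmonary blood removes `lambda_B/G * Q_p * (F_A - F_v)` where
#' `F_v` is the mixed venous pressure and `Q_p` the perfused cardiac
#' output.  Each perfusion-limited tissue equilibrates with arterial blood
#' at rate `lambda_B/G * Q_i * (F_A - F_i) / (V_i * lambda_i)`.
#'
#' @inheritParams mixed_venous
#' @param vent a [vent_settings()] object.
#' @param agent an [agent_params()] object.
#' @return Named numeric vector of derivatives, vol%/min.
#' @export
uptake_derivative <- function(state, vent, agent, body = body_params()) {
  if (body$v_circuit <= 0 || body$frc <= 0)
    abort_schema("v_circuit", "circuit and alveolar volumes must be positive")
  lam <- c(agent$lambda_vrg, agent$lambda_mus, agent$lambda_fat)
  vl <- c(body$v_vrg, body$v_mus, body$v_fat) * lam
  if (any(vl <= 0))
    abort_schema("v_vrg", "tissue capacities V_i * lambda_i must be positive")
  q <- body$q_total * c(body$f_vrg, body$f_mus, body$f_fat)
  qp <- sum(q)
  fv <- sum(q * state[c("f_vrg", "f_mus", "f_fat")]) / qp
  ft <- state[c("f_vrg", "f_mus", "f_fat")]
  d <- c(
    f_i = (vent$fgf * (vent$f_d - state[["f_i"]]) +
             vent$v_a * (state[["f_a"]] - state[["f_i"]])) / body$v_circuit,
    f_a = (vent$v_a * (state[["f_i"]] - state[["f_a"]]) -
             agent$lambda_blood * qp * (state[["f_a"]] - fv)) / body$frc)
  dt_tissue <- agent$lambda_blood * q * (state[["f_a"]] - ft) / vl
  names(dt_tissue) <- c("f_vrg", "f_mus", "f_fat")
  c(d, dt_tissue)
}

#' Construct a protocol phase
#'
#' One row of a phase schedule: constant ventilation/delivery settings plus
#' exactly one end condition.  Phases are integrated in order by
#' [simulate_phases()].
#'
#' @param name phase label.
#' @param f_d delivered partial pressure, vol% (ignored in `"clamp"` mode).
#' @param fgf fresh gas flow, L/min.
#' @param v_a alveolar minute ventilation, L/min.
#' @param duration fixed phase length, min (one of `duration`, `until`,
#'   `end` must be given).
#' @param until absolute simulation time at which the phase ends, min.
#' @param end threshold end condition: a list `list(var =, cmp =, level =)`
#'   where `var` is a state column (`"f_i"`, `"f_a"`, `"f_vrg"`, `"f_mus"`,
#'   `"f_fat"`), `cmp` is `">="` or `"<="`, and `level` is in vol%.
#' @param cap maximum duration for a threshold phase, min.
#' @param on_cap what to do if the cap is hit before the threshold:
#'   `"stop"` ends the phase quietly, `"error"` raises a condition.
#' @param mode `"fixed"` integrates the full ODE at constant `f_d`;
#'   `"clamp"` holds the alveolar pressure at `clamp_target` and
#'   back-computes the delivered pressure from the circuit balance each
#'   step, bounded to `[0, fd_max]`.
#' @param clamp_target alveolar pressure held in `"clamp"` mode, vol%.
#' @param fd_max delivered-pressure bound in `"clamp"` mode, vol%.
#' @return A one-row tibble.
#' @export
sim_phase <- function(name, f_d = 0, fgf = 1, v_a = 5,
                      duration = NULL, until = NULL, end = NULL,
                      cap = 240, on_cap = c("stop", "error"),
                      mode = c("fixed", "clamp"),
                      clamp_target = NA_real_, fd_max = Inf) {
  mode <- match.arg(mode)
  on_cap <- match.arg(on_cap)
  vent <- vent_settings(f_d = f_d, fgf = fgf, v_a = v_a)
  n_end <- sum(!is.null(duration), !is.null(until), !is.null(end))
  if (n_end != 1L)
    abort_schema("end", "exactly one of `duration`, `until`, `end` must be given")
  state_vars <- c("f_i", "f_a", "f_vrg", "f_mus", "f_fat")
  if (!is.null(end)) {
    if (!is.list(end) || !all(c("var", "cmp", "level") %in% names(end)))
      abort_schema("end", "must be list(var =, cmp =, level =)")
    if (!end$var %in% state_vars)
      abort_schema("end$var", "must be one of the state columns")
    if (!end$cmp %in% c(">=", "<="))
      abort_schema("end$cmp", "must be \">=\" or \"<=\"")
    check_positive(end$level, "end$level")
    check_positive(cap, "cap")
  }
  if (!is.null(duration)) check_positive(duration, "duration")
  if (mode == "clamp") check_positive(clamp_target, "clamp_target")
  tibble(
    name = name, mode = mode,
    f_d = vent$f_d, fgf = vent$fgf, v_a = vent$v_a,
    clamp_target = clamp_target, fd_max = fd_max,
    end_kind = if (!is.null(duration)) "duration" else if (!is.null(until)) "until" else "threshold",
    duration_min = duration %||% NA_real_,
    until_min = until %||% NA_real_,
    end_var = if (is.null(end)) NA_character_ else end$var,
    end_cmp = if (is.null(end)) NA_character_ else end$cmp,
    end_level = if (is.null(end)) NA_real_ else end$level,
    cap_min = cap, on_cap = on_cap)
}

#' Integrate a phase schedule
#'
#' Deterministic fixed-step 4th-order Runge-Kutta integration of the
#' mass-balance system across a sequence of protocol phases.  The default
#' internal step is 0.25 s; the system is non-stiff at these time constants
#' (the fastest mode, the circuit under high fresh gas flow, has a time
#' constant of tens of seconds) and halving the step changes reported
#' pressures by well under 1e-6 vol%.  States are reported every
#' `report_dt` (default 1 s); phase switches are applied exactly at their
#' boundary step.
#'
#' @param phases a phase schedule: one or more [sim_phase()] rows bound
#'   into a tibble.
#' @param agent an [agent_params()] object.
#' @param body a [body_params()] object.
#' @param init initial [sim_state()].
#' @param dt internal integration step, min (default 0.25 s).
#' @param report_dt reporting interval, min; must be an integer multiple of
#'   `dt` (default 1 s).
#' @param t0 simulation time of `init`, min.
#' @return An object of class `uptake_sim`: a list with `trace` (tibble of
#'   reported states with the ventilation settings active on each row and
#'   the mixed venous pressure `f_mv`), `phase_log` (per-phase start/end
#'   times and end reasons), `mass` (cumulative agent volume delivered and
#'   vented by fresh gas, L vol%, for balance checks), and the inputs.
#' @export
simulate_phases <- function(phases, agent, body = body_params(),
                            init = sim_state(), dt = 0.25 / 60,
                            report_dt = 1 / 60, t0 = 0) {
  if (!is.data.frame(phases) || nrow(phases) == 0L)
    abort("`phases` must be a non-empty phase schedule (see sim_phase())")
  if (!inherits(agent, "anes_agent")) abort("`agent` must be an agent_params() object")
  if (!inherits(body, "anes_body")) abort("`body` must be a body_params() object")
  check_positive(dt, "dt")
  rep_every <- round(report_dt / dt)
  if (rep_every < 1 || abs(report_dt - rep_every * dt) > 1e-9)
    abort_schema("report_dt", "must be a positive integer multiple of `dt`")
  state_vars <- c("f_i", "f_a", "f_vrg", "f_mus", "f_fat")

  ph <- phases
  ph$mode_i <- ifelse(ph$mode == "clamp", 1, 0)
  ph$end_kind_i <- match(ph$end_kind, c("duration", "until", "threshold")) - 1
  ph$end_var_i <- match(ph$end_var, state_vars) - 1
  ph$end_var_i[is.na(ph$end_var_i)] <- 0
  ph$end_cmp_i <- ifelse(is.na(ph$end_cmp), 1, ifelse(ph$end_cmp == ">=", 1, -1))
  ph$end_level[is.na(ph$end_level)] <- 0
  ph$duration_min[is.na(ph$duration_min)] <- 0
  ph$until_min[is.na(ph$until_min)] <- 0
  ph$cap_min[is.na(ph$cap_min)] <- 0
  ph$clamp_target[is.na(ph$clamp_target)] <- 0

  res <- cpp_simulate(unname(init[state_vars]), as.data.frame(ph),
                      unclass(agent), unclass(body), dt, as.integer(rep_every), t0)
  tr <- res$trace
  colnames(tr) <- c(trace_columns, "e_in", "e_out")
  trace <- as_tibble(tr[, trace_columns, drop = FALSE])
  mass <- as_tibble(tr[, c("t_min", "e_in", "e_out"), drop = FALSE])
  reasons <- c("completed", "threshold", "cap")[res$phase_reason + 1]
  phase_log <- tibble(phase = phases$name, t_start = res$phase_start,
                      t_end = res$phase_end, end_reason = reasons)
  capped <- which(reasons == "cap" & phases$on_cap == "error")
  if (length(capped) > 0)
    abort(sprintf(
      "phase '%s': threshold %s %s %g vol%% not reached within the %g-min cap",
      phases$name[capped[1]], phases$end_var[capped[1]],
      phases$end_cmp[capped[1]], phases$end_level[capped[1]],
      phases$cap_min[capped[1]]),
      class = "macawake_threshold_error")
  structure(list(trace = trace, phase_log = phase_log, mass = mass,
                 agent = agent, body = body, dt = dt, report_dt = report_dt),
            class = "uptake_sim")
}

#' @export
print.uptake_sim <- function(x, ...) {
  cat(sprintf("<uptake_sim> %s: %d phases, t = [%g, %g] min, %d reported states\n",
              x$agent$name, nrow(x$phase_log), min(x$trace$t_min),
              max(x$trace$t_min), nrow(x$trace)))
  print(x$phase_log)
  invisible(x)
}
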