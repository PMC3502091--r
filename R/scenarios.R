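#' The study scenario grid
#'
#' Expands the full factorial of agents, washout ventilation modes, and
#' post-recovery ventilation levels into a tibble of scenarios — by
#' default the 36-cell study design (3 agents x 2 washout modes x 6
#' post-recovery levels after 8 h of 1-MAC maintenance).
#'
#' @param agents agent names (packaged names or prefixes).
#' @param washout_va washout ventilation levels, L/min.
#' @param post_recovery_va post-recovery ventilation levels, L/min.
#' @param maintenance_min,observation_min protocol durations, min.
#' @return A tibble with one row per scenario and a `scenario` list-column
#'   of [paper_scenario()] objects.
#' @export
scenario_grid <- function(agents = c("desflurane", "sevoflurane", "isoflurane"),
                          washout_va = c(5, 10),
                          post_recovery_va = c(0.5, 1, 1.5, 2.5, 5, 10),
                          maintenance_min = 480, observation_min = 120) {
  grid <- tidyr::expand_grid(agent = agents, washout_va = washout_va,
                             post_recovery_va = post_recovery_va)
  grid$maintenance_min <- maintenance_min
  grid$observation_min <- observation_min
  grid$scenario <- purrr::pmap(grid, function(agent, washout_va,
                                              post_recovery_va,
                                              maintenance_min,
                                              observation_min) {
    paper_scenario(agent, washout_va = washout_va,
                   post_recovery_va = post_recovery_va,
                   maintenance_min = maintenance_min,
                   observation_min = observation_min)
  })
  grid
}

#' Define a parameter perturbation
#'
#' Describes a one-parameter sensitivity sweep: multiplicative scale
#' factors applied to a patient parameter (`v_mus`, `v_fat`, `q_total`) or
#' to the maintenance duration (`maintenance_min`, alias
#' `maintenance_duration`).  Optionally augments the explicit multipliers
#' with `n_random` draws sampled uniformly between their extremes; the
#' draws are fixed at construction time from `seed`, so a spec expands to
#' the same scenario list on every use.
#'
#' @param parameter parameter to scale.
#' @param multipliers positive scale factors.
#' @param seed integer seed for the optional random multipliers.
#' @param n_random number of additional uniformly sampled multipliers.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(parameter = c("v_mus", "v_fat", "q_total",
                                            "maintenance_min",
                                            "maintenance_duration"),
                              multipliers, seed = NULL, n_random = 0) {
  parameter <- match.arg(parameter)
  if (parameter == "maintenance_duration") parameter <- "maintenance_min"
  if (!is.numeric(multipliers) || length(multipliers) == 0 ||
      any(!is.finite(multipliers)) || any(multipliers <= 0))
    abort_schema("multipliers", "must be positive finite scale factors")
  if (n_random > 0) {
    if (is.null(seed)) abort_schema("seed", "required when n_random > 0")
    rng <- local({
      old <- globalenv()$.Random.seed
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
              else suppressWarnings(rm(".Random.seed", envir = globalenv())))
      set.seed(as.integer(seed))
      stats::runif(n_random, min(multipliers), max(multipliers))
    })
    multipliers <- c(multipliers, rng)
  }
  structure(list(parameter = parameter, multipliers = multipliers,
                 seed = seed), class = "perturbation_spec")
}

#' Expand a perturbation over a base scenario
#'
#' Applies each multiplier of a [perturbation_spec()] to the base scenario
#' and patient, producing one scenario per multiplier.  Patient parameters
#' are scaled independently with no anthropometric closure: in particular,
#' scaling a tissue volume keeps the fractional blood flows fixed, so
#' perfusion per unit tissue falls as the tissue grows (see the package
#' vignette).  The identity multiplier returns the base objects unchanged.
#'
#' @param base a [paper_scenario()] object.
#' @param spec a [perturbation_spec()].
#' @param body the base [body_params()].
#' @return A tibble with columns `parameter`, `multiplier`, and
#'   list-columns `scenario` and `body` ready for
#'   [simulate_scenario()].
#' @export
perturb_scenarios <- function(base, spec, body = body_params()) {
  stopifnot(inherits(base, "anes_scenario"), inherits(spec, "perturbation_spec"))
  rows <- purrr::map(spec$multipliers, function(m) {
    sc <- base; bd <- body
    if (spec$parameter == "maintenance_min") {
      sc$maintenance_min <- base$maintenance_min * m
      check_positive(sc$maintenance_min, "maintenance_min")
    } else {
      bd[[spec$parameter]] <- body[[spec$parameter]] * m
      bd <- do.call(body_params, unclass(bd))
    }
    tibble(parameter = spec$parameter, multiplier = m,
           scenario = list(sc), body = list(bd))
  })
  dplyr::bind_rows(rows)
}
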