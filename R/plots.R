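#' Plot a simulated scenario
#'
#' Compartment partial pressures over time, with the MACawake threshold
#' (0.3 MAC) marked.  With `from_cutoff = TRUE` the x axis starts at agent
#' cut-off, the emergence view.
#'
#' @param object an [simulate_scenario()] result.
#' @param from_cutoff start the time axis at agent cut-off?
#' @param compartments trace columns to draw.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.emergence_sim <- function(object, from_cutoff = TRUE,
                                   compartments = c("f_i", "f_a", "f_vrg",
                                                    "f_mus", "f_fat"),
                                   ...) {
  agent <- object$scenario$agent
  t0 <- if (from_cutoff) object$scenario$maintenance_min else 0
  long <- object$sim$trace %>%
    dplyr::filter(.data$t_min >= t0) %>%
    dplyr::mutate(t = .data$t_min - t0) %>%
    tidyr::pivot_longer(dplyr::all_of(compartments),
                        names_to = "compartment", values_to = "pressure")
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$pressure,
                                     colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.3 * agent$mac, linetype = "dashed") +
    ggplot2::labs(
      x = if (from_cutoff) "time from agent cut-off (min)" else "time (min)",
      y = "partial pressure (vol%)",
      colour = NULL,
      title = sprintf("%s: washout V_A %g, post-recovery V_A %g L/min",
                      agent$name, object$scenario$washout_va,
                      object$scenario$post_recovery_va),
      subtitle = "dashed line: MACawake (0.3 MAC)") +
    ggplot2::theme_minimal()
}

#' Plot a study grid
#'
#' Vessel-rich partial pressure (in MAC units) versus time from agent
#' cut-off for every scenario, faceted by agent and washout mode, one
#' curve per post-recovery ventilation level; curves crossing back above
#' the dashed MACawake line indicate rehypnotization.
#'
#' @param object an [run_study()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.emergence_study <- function(object, ...) {
  tr <- object$traces %>%
    dplyr::mutate(
      fvrg_mac = .data$f_vrg / .data$mac,
      washout = factor(ifelse(.data$washout_va == max(.data$washout_va),
                              "hyperventilation washout",
                              "normoventilation washout")),
      post = factor(.data$post_recovery_va))
  ggplot2::ggplot(tr, ggplot2::aes(.data$t_from_cutoff, .data$fvrg_mac,
                                   colour = .data$post)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.3, linetype = "dashed") +
    ggplot2::facet_grid(ggplot2::vars(.data$agent),
                        ggplot2::vars(.data$washout)) +
    ggplot2::labs(x = "time from agent cut-off (min)",
                  y = expression(F[VRG] ~ "(MAC)"),
                  colour = expression(V[A] ~ "(L/min)"),
                  subtitle = "dashed line: MACawake (0.3 MAC)") +
    ggplot2::theme_minimal()
}
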