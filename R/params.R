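#' Anesthetic agent parameters
#'
#' Bundle the physicochemical constants of one volatile anesthetic: its
#' 1-MAC partial pressure and the blood/gas and tissue/gas partition
#' coefficients that set the capacity of each perfusion-limited compartment
#' (capacity = volume x lambda).  Called with just a name it returns the
#' packaged parameter set for that agent (see [default_agents()]).
#'
#' @param name agent name; `"desflurane"`, `"sevoflurane"` and
#'   `"isoflurane"` (or unambiguous prefixes) resolve to the packaged sets.
#' @param mac partial pressure at 1 MAC, vol% of 1 atm.
#' @param lambda_blood blood/gas partition coefficient (dimensionless).
#' @param lambda_vrg,lambda_mus,lambda_fat tissue/gas partition coefficients
#'   for the vessel-rich, muscle, and fat groups.
#' @param overpressure_fd vaporizer setting used for overpressure induction,
#'   vol%; optional unless the agent is run through the induction protocol.
#' @return An object of class `anes_agent` (a named list).
#' @examples
#' agent_params("iso")
#' agent_params("xenon-like", mac = 0.7, lambda_blood = 0.115,
#'              lambda_vrg = 0.13, lambda_mus = 0.15, lambda_fat = 1.9)
#' @export
agent_params <- function(name, mac = NULL, lambda_blood = NULL,
                         lambda_vrg = NULL, lambda_mus = NULL,
                         lambda_fat = NULL, overpressure_fd = NA_real_) {
  if (is.null(mac) && is.null(lambda_blood)) {
    agents <- default_agents()
    hit <- which(startsWith(names(agents), tolower(name)))
    if (length(hit) != 1L)
      abort_schema("name", sprintf(
        "'%s' does not match exactly one packaged agent (%s)",
        name, paste(names(agents), collapse = ", ")))
    return(agents[[hit]])
  }
  check_positive(mac, "mac")
  check_positive(lambda_blood, "lambda_blood")
  check_positive(lambda_vrg, "lambda_vrg")
  check_positive(lambda_mus, "lambda_mus")
  check_positive(lambda_fat, "lambda_fat")
  if (lambda_fat <= lambda_mus)
    abort_schema("lambda_fat", "fat solubility must exceed muscle solubility")
  if (!is.na(overpressure_fd)) check_positive(overpressure_fd, "overpressure_fd")
  structure(list(name = as.character(name), mac = mac,
                 lambda_blood = lambda_blood, lambda_vrg = lambda_vrg,
                 lambda_mus = lambda_mus, lambda_fat = lambda_fat,
                 overpressure_fd = overpressure_fd),
            class = "anes_agent")
}

#' @export
print.anes_agent <- function(x, ...) {
  cat(sprintf("<anes_agent> %s: MAC %g vol%%, lambda B/G %g, VRG %g, MUS %g, FAT %g\n",
              x$name, x$mac, x$lambda_blood, x$lambda_vrg, x$lambda_mus,
              x$lambda_fat))
  invisible(x)
}

#' Patient and breathing-circuit parameters
#'
#' Compartment volumes and blood flows of the standard simulated patient:
#' a well-mixed anesthesia circuit, the lung FRC acting as the alveolar
#' compartment, and three perfusion-limited tissue groups (vessel-rich,
#' muscle, fat).  Defaults describe a 70 kg adult.
#'
#' @param weight body weight, kg (metadata only).
#' @param v_circuit breathing-circuit volume, L.
#' @param frc functional residual capacity, L.
#' @param q_total cardiac output, L/min.
#' @param v_vrg,v_mus,v_fat tissue volumes, L.
#' @param f_vrg,f_mus,f_fat fractional blood flows to each tissue group.
#'   The defaults sum to 0.998 and are used verbatim; venous return is
#'   weighted by the perfused fraction, not renormalised.
#' @return An object of class `anes_body` (a named list).
#' @export
body_params <- function(weight = 70, v_circuit = 8, frc = 2.5, q_total = 5,
                        v_vrg = 6, v_mus = 33, v_fat = 14.5,
                        f_vrg = 0.758, f_mus = 0.18, f_fat = 0.06) {
  check_positive(weight, "weight")
  check_positive(v_circuit, "v_circuit")
  check_positive(frc, "frc")
  check_positive(q_total, "q_total")
  check_positive(v_vrg, "v_vrg")
  check_positive(v_mus, "v_mus")
  check_positive(v_fat, "v_fat")
  check_nonneg(f_vrg, "f_vrg")
  check_nonneg(f_mus, "f_mus")
  check_nonneg(f_fat, "f_fat")
  fsum <- f_vrg + f_mus + f_fat
  if (fsum <= 0 || fsum > 1)
    abort_schema("f_vrg", sprintf(
      "tissue flow fractions must sum to (0, 1]; got %.4g", fsum))
  structure(list(weight = weight, v_circuit = v_circuit, frc = frc,
                 q_total = q_total, v_vrg = v_vrg, v_mus = v_mus,
                 v_fat = v_fat, f_vrg = f_vrg, f_mus = f_mus, f_fat = f_fat),
            class = "anes_body")
}

#' @export
print.anes_body <- function(x, ...) {
  cat(sprintf(paste0("<anes_body> %g kg; circuit %g L, FRC %g L, Q %g L/min; ",
                     "V (VRG/MUS/FAT) %g/%g/%g L; flow fractions %g/%g/%g\n"),
              x$weight, x$v_circuit, x$frc, x$q_total,
              x$v_vrg, x$v_mus, x$v_fat, x$f_vrg, x$f_mus, x$f_fat))
  invisible(x)
}

#' Ventilation and delivery settings
#'
#' Piecewise-constant controls for one protocol phase: the delivered
#' (vaporizer) partial pressure, the fresh gas flow into the circuit, and
#' the alveolar minute ventilation.
#'
#' @param f_d delivered partial pressure, vol% (0-100).
#' @param fgf fresh gas flow, L/min.
#' @param v_a alveolar minute ventilation, L/min.
#' @return An object of class `vent_settings` (a named list).
#' @export
vent_settings <- function(f_d = 0, fgf = 1, v_a = 5) {
  if (!is.numeric(f_d) || length(f_d) != 1L || !is.finite(f_d) ||
      f_d < 0 || f_d > 100)
    abort_schema("f_d", "delivered partial pressure must lie in [0, 100] vol%")
  check_nonneg(fgf, "fgf")
  check_nonneg(v_a, "v_a")
  structure(list(f_d = f_d, fgf = fgf, v_a = v_a), class = "vent_settings")
}

#' Packaged agent parameter sets
#'
#' The three packaged volatile agents (desflurane, sevoflurane, isoflurane)
#' read from the parameter file shipped under `extdata`.
#'
#' @param path optional path to an alternative parameter file in the same
#'   JSON layout.
#' @return A named list of [agent_params()] objects.
#' @seealso [load_params()] for the file format, [default_body()].
#' @export
default_agents <- function(path = NULL) {
  load_params(path)$agents
}

#' Default patient/circuit parameter set
#'
#' @inheritParams default_agents
#' @return An [body_params()] object for the standard 70 kg patient.
#' @export
default_body <- function(path = NULL) {
  load_params(path)$body
}

#' Read a model parameter file
#'
#' Parameter files are plain JSON with an `agents` array (keys `name`,
#' `mac`, `lambda_blood`, `lambda_vrg`, `lambda_mus`, `lambda_fat`, and
#' optionally `overpressure_fd`) and a `body` object with the
#' [body_params()] fields.  All values are validated against the type
#' invariants; a violation raises a schema error naming the offending
#' field.
#'
#' @param path path to a parameter file; `NULL` uses the packaged defaults.
#' @return A list of class `anes_params` with elements `agents` (named list
#'   of `anes_agent`) and `body` (`anes_body`).
#' @export
load_params <- function(path = NULL) {
  path <- path %||% system.file("extdata", "gasman_params.json",
                                package = "macawake", mustWork = TRUE)
  if (!file.exists(path))
    abort(sprintf("parameter file not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$agents) || is.null(raw$body))
    abort(sprintf("parameter file %s must contain `agents` and `body`", path))
  agents <- lapply(raw$agents, function(a) {
    agent_params(name = a$name, mac = a$mac, lambda_blood = a$lambda_blood,
                 lambda_vrg = a$lambda_vrg, lambda_mus = a$lambda_mus,
                 lambda_fat = a$lambda_fat,
                 overpressure_fd = a$overpressure_fd %||% NA_real_)
  })
  names(agents) <- vapply(agents, `[[`, character(1), "name")
  b <- raw$body
  body <- body_params(weight = b$weight %||% 70, v_circuit = b$v_circuit,
                      frc = b$frc, q_total = b$q_total, v_vrg = b$v_vrg,
                      v_mus = b$v_mus, v_fat = b$v_fat, f_vrg = b$f_vrg,
                      f_mus = b$f_mus, f_fat = b$f_fat)
  structure(list(agents = agents, body = body), class = "anes_params")
}

#' Write a model parameter file
#'
#' Inverse of [load_params()]: serialises a parameter set back to JSON so
#' that `load_params(save_params(p, f))` round-trips exactly.
#'
#' @param params an `anes_params` list as returned by [load_params()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_params <- function(params, path) {
  if (!inherits(params, "anes_params"))
    abort("`params` must be an `anes_params` object from load_params()")
  out <- list(
    agents = lapply(unname(params$agents), function(a) a[!is.na(a)]),
    body = unclass(params$body))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Tabulate agent parameters
#'
#' @param agents a named list of [agent_params()] objects.
#' @return A tibble with one row per agent.
#' @export
agent_table <- function(agents = default_agents()) {
  purrr::map_dfr(agents, ~ as_tibble(.x[!vapply(.x, is.na, logical(1))]))
}
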