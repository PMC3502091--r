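abort_schema <- function(field, msg) {
  abort(sprintf("invalid parameter `%s`: %s", field, msg),
        class = "macawake_schema_error", field = field)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    abort_schema(field, "must be a single positive finite number")
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    abort_schema(field, "must be a single non-negative finite number")
  invisible(x)
}

# Accept an uptake_sim, emergence_sim, or bare trace tibble and return the
# trace tibble with the canonical columns.
as_trace <- function(x) {
  if (inherits(x, "emergence_sim")) x <- x$sim
  if (inherits(x, "uptake_sim")) x <- x$trace
  if (!is.data.frame(x) || !all(c("t_min", "f_vrg") %in% names(x)))
    abort("expected a simulation object or a trace data frame with at least `t_min` and `f_vrg` columns")
  as_tibble(x)
}

trace_columns <- c("t_min", "f_d", "fgf", "v_a", "f_i", "f_a",
                   "f_vrg", "f_mus", "f_fat", "f_mv")
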