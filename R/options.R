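#' Simulation options
#'
#' SPICE-style transient-analysis options plus solver internals. `reltol`
#' drives the local-truncation-error step control; `abstol` (mol/l) is the
#' absolute floor that keeps the error test meaningful near zero
#' concentrations; `numdgt` affects only text output formatting, never
#' arithmetic. The print grid (`print_step`) is produced by interpolation on
#' the adaptive mesh and does not constrain it.
#'
#' @param total_time Simulated time span, s (> 0).
#' @param print_step Print (output) time between data, s (> 0, <= total_time).
#' @param reltol Relative error tolerance in (0, 0.1]; default 1e-3.
#' @param numdgt Number of significant digits in text output; default 6.
#' @param abstol Absolute error floor, mol/l; default 1e-12.
#' @param method `"tr-gear"` (default: trapezoidal with a BDF2 fallback when
#'   trapezoidal ringing is detected), `"trapezoidal"`, or `"gear2"` (pure
#'   variable-step BDF2, seeded by a backward-Euler step).
#' @param max_step,min_step,initial_step Step-size bounds, s. Defaults:
#'   `max_step = total_time / 10`, `initial_step = print_step * 1e-6`,
#'   `min_step = initial_step * 1e-10`.
#' @param newton_tol Newton convergence factor relative to the step error
#'   tolerance; default 1e-2.
#' @param newton_max_iter Maximum Newton iterations per step; default 8.
#' @param seed Unused placeholder kept for interface stability (the
#'   integrator is deterministic).
#' @return An object of class `sim_options`.
#' @export
sim_options <- function(total_time, print_step, reltol = 1e-3, numdgt = 6L,
                        abstol = 1e-12,
                        method = c("tr-gear", "trapezoidal", "gear2"),
                        max_step = NULL, min_step = NULL, initial_step = NULL,
                        newton_tol = 1e-2, newton_max_iter = 8L, seed = NULL) {
  method <- match.arg(method)
  if (!is.numeric(total_time) || length(total_time) != 1L ||
      !is.finite(total_time) || total_time <= 0) {
    stop("`total_time` must be a positive number (s)", call. = FALSE)
  }
  if (!is.numeric(print_step) || length(print_step) != 1L ||
      !is.finite(print_step) || print_step <= 0 || print_step > total_time) {
    stop("`print_step` must satisfy 0 < print_step <= total_time", call. = FALSE)
  }
  if (!is.numeric(reltol) || reltol <= 0 || reltol > 0.1) {
    stop("`reltol` must lie in (0, 0.1]", call. = FALSE)
  }
  if (!is.numeric(abstol) || abstol < 0) stop("`abstol` must be >= 0", call. = FALSE)
  numdgt <- as.integer(numdgt)
  if (numdgt < 1L) stop("`numdgt` must be >= 1", call. = FALSE)
  max_step <- max_step %||% (total_time / 10)
  initial_step <- initial_step %||% min(print_step * 1e-6, max_step)
  min_step <- min_step %||% (initial_step * 1e-10)
  if (!(min_step < initial_step && initial_step <= max_step)) {
    stop("step bounds must satisfy min_step < initial_step <= max_step",
         call. = FALSE)
  }
  structure(
    list(total_time = total_time, print_step = print_step, reltol = reltol,
         numdgt = numdgt, abstol = abstol, method = method,
         max_step = max_step, min_step = min_step,
         initial_step = initial_step, newton_tol = newton_tol,
         newton_max_iter = as.integer(newton_max_iter), seed = seed),
    class = "sim_options"
  )
}

#' @export
print.sim_options <- function(x, ...) {
  cat(sprintf(
    "Simulation options: total time %g s, print step %g s, RELTOL %g, NUMDGT %d, method %s\n",
    x$total_time, x$print_step, x$reltol, x$numdgt, x$method))
  invisible(x)
}
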