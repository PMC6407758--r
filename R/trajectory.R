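#' Trajectory objects
#'
#' The solver's output: a strictly increasing print-time grid from 0 to the
#' total time, one state (concentration) vector per time, the options used
#' and step statistics.
#'
#' @param times Numeric vector of print times.
#' @param states Matrix, one row per time, one column per species.
#' @param species Character vector of species names.
#' @param options The [sim_options()] used (may be `NULL` for externally
#'   built trajectories).
#' @param stats List of step statistics.
#' @return An object of class `kin_trajectory`.
#' @export
new_trajectory <- function(times, states, species, options = NULL,
                           stats = list()) {
  states <- as.matrix(states)
  stopifnot(length(times) == nrow(states), length(species) == ncol(states),
            !is.unsorted(times, strictly = TRUE))
  colnames(states) <- species
  structure(list(times = times, states = states, species = species,
                 options = options, stats = stats),
            class = "kin_trajectory")
}

#' @export
print.kin_trajectory <- function(x, ...) {
  cat(sprintf("Kinetic trajectory: %d species over [0, %g] s (%d print points)\n",
              length(x$species), max(x$times), length(x$times)))
  if (length(x$stats)) {
    cat(sprintf("  steps: %d accepted, %d rejected, %d Newton iterations\n",
                x$stats$accepted %||% NA_integer_,
                x$stats$rejected %||% NA_integer_,
                x$stats$newton_iterations %||% NA_integer_))
  }
  cat("  final state:", paste(sprintf("[%s] = %.6g", x$species,
                                      x$states[nrow(x$states), ]),
                              collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.kin_trajectory <- function(x, ...) {
  data.frame(t = x$times, x$states, check.names = FALSE)
}

#' @export
plot.kin_trajectory <- function(x, species = NULL, log_time = FALSE, ...) {
  sel <- species %||% x$species
  m <- x$states[, sel, drop = FALSE]
  graphics::matplot(x$times, m, type = "l", lty = 1,
                    xlab = "time (s)", ylab = "concentration (mol/l)",
                    log = if (log_time) "x" else "", ...)
  graphics::legend("topright", legend = sel, lty = 1,
                   col = seq_along(sel), bty = "n")
  invisible(x)
}

#' Final state of a trajectory
#'
#' @param trajectory A `kin_trajectory`.
#' @return Named numeric vector: the state at the last print time.
#' @export
final_state <- function(trajectory) {
  stopifnot(inherits(trajectory, "kin_trajectory"))
  setNames(trajectory$states[nrow(trajectory$states), ], trajectory$species)
}
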