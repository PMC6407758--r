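#' Fixed-step classical Runge-Kutta reference integration
#'
#' Brute-force 4th-order Runge-Kutta at a fixed step, used as the
#' independent reference against which the native variable-step implicit
#' integrator is validated. For a [kinetic_scheme()] the inner loop runs in
#' compiled code on the flattened term table; for a plain function the loop
#' runs in R (suitable for small step counts only).
#'
#' @param x A [kinetic_scheme()] or a function `f(t, x)`.
#' @param total_time Time span, s.
#' @param n_steps Number of fixed steps (rounded up to a multiple of
#'   `n_print`).
#' @param n_print Number of recorded intervals (the output has
#'   `n_print + 1` rows).
#' @param x0 Initial state (required for the function method).
#' @return A `kin_trajectory`.
#' @export
integrate_rk4 <- function(x, total_time, n_steps, n_print = 200L, x0 = NULL) {
  stopifnot(total_time > 0, n_steps >= 1)
  n_print <- min(as.integer(n_print), as.integer(n_steps))
  n_steps <- as.integer(ceiling(n_steps / n_print) * n_print)
  if (inherits(x, "kinetic_scheme")) {
    rhs <- compile_rhs(x)
    tab <- attr(rhs, "table")
    x0 <- x0 %||% x$species
    states <- nk_rk4(as.numeric(x0), 0, total_time, n_steps, n_print,
                     tab$w, tab$target, tab$E)
    species <- names(x$species)
  } else {
    stopifnot(is.function(x), !is.null(x0))
    every <- n_steps %/% n_print
    h <- total_time / n_steps
    states <- matrix(NA_real_, n_print + 1L, length(x0))
    states[1, ] <- x0
    xx <- as.numeric(x0)
    t <- 0
    row <- 2L
    for (s in seq_len(n_steps)) {
      k1 <- x(t, xx)
      k2 <- x(t + h / 2, xx + h / 2 * k1)
      k3 <- x(t + h / 2, xx + h / 2 * k2)
      k4 <- x(t + h, xx + h * k3)
      xx <- xx + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
      if (s %% every == 0L) {
        states[row, ] <- xx
        row <- row + 1L
      }
    }
    species <- names(x0) %||% paste0("x", seq_along(x0))
  }
  new_trajectory(times = seq(0, total_time, length.out = n_print + 1L),
                 states = states, species = species,
                 stats = list(accepted = n_steps, rejected = 0L,
                              newton_iterations = 0L))
}
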