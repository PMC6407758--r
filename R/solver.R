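# Native NSM integrator: variable-step implicit trapezoidal rule with a
# variable-coefficient BDF2 ("Gear 2nd order") companion, Newton iteration on
# the analytic mass-action Jacobian, and SPICE-style local-truncation-error
# step control driven by RELTOL. This is the numerical contract the circuit
# simulator fulfils in the original workflow, implemented natively.

# Step-controller target for the weighted LTE ratio. Steps are accepted up
# to ratio 1 but sized towards this value, so the accumulated (global) error
# stays within a few RELTOL rather than drifting to N_steps * RELTOL.
.nk_lte_target <- 0.3

# Cubic Hermite value at fraction s in [0,1] of a step (x0,f0) -> (x1,f1), h.
.nk_hermite <- function(s, x0, f0, x1, f1, h) {
  s2 <- s * s; s3 <- s2 * s
  (2 * s3 - 3 * s2 + 1) * x0 + (s3 - 2 * s2 + s) * h * f0 +
    (-2 * s3 + 3 * s2) * x1 + (s3 - s2) * h * f1
}

# Solve y = const + gamma*h*f(t_new, y) by Newton; returns y, f(y), n iter.
.nk_newton <- function(rhs, jac, t_new, cst, gh, y0, opt) {
  n <- length(y0)
  y <- y0
  for (it in seq_len(opt$newton_max_iter)) {
    fy <- rhs(t_new, y)
    if (!all(is.finite(fy))) return(list(ok = FALSE, niter = it, blowup = TRUE))
    G <- y - cst - gh * fy
    J <- diag(n) - gh * jac(t_new, y)
    dy <- tryCatch(solve(J, G), error = function(e) NULL)
    if (is.null(dy) || !all(is.finite(dy))) {
      return(list(ok = FALSE, niter = it, blowup = FALSE))
    }
    y <- y - dy
    wrms <- max(abs(dy) / (opt$reltol * pmax(abs(y), 1e-300) + opt$abstol))
    stagnated <- max(abs(dy)) <= 4 * .Machine$double.eps * max(abs(y)) # at float noise
    if (wrms < opt$newton_tol || stagnated) {
      fy <- rhs(t_new, y)
      if (!all(is.finite(fy))) {
        return(list(ok = FALSE, niter = it, blowup = TRUE))
      }
      return(list(ok = TRUE, y = y, fy = fy, niter = it))
    }
  }
  list(ok = FALSE, niter = opt$newton_max_iter, blowup = FALSE)
}

# One trapezoidal step from (t, x, f) over h. LTE from the divided
# difference of the third derivative: with f evaluated at the step ends and
# at the Hermite midpoint, x''' ~ 4 (f0 - 2 f_mid + f1) / h^2, and the
# trapezoidal truncation error is -(h^3/12) x''' ~ -(h/3) (f0 - 2 f_mid + f1).
.nk_step_tr <- function(rhs, jac, t, x, f, h, opt) {
  ns <- .nk_newton(rhs, jac, t + h, cst = x + (h / 2) * f, gh = h / 2,
                   y0 = x + h * f, opt = opt)
  if (!ns$ok) return(ns)
  y <- ns$y; fy <- ns$fy
  xm <- 0.5 * (x + y) + (h / 8) * (f - fy)
  fm <- rhs(t + h / 2, xm)
  if (!all(is.finite(fm))) return(list(ok = FALSE, niter = ns$niter, blowup = TRUE))
  lte <- -(h / 3) * (f - 2 * fm + fy)
  list(ok = TRUE, x = y, f = fy, lte = lte, niter = ns$niter + 1L)
}

# One variable-coefficient BDF2 step using history (t-h_prev, xp, fp).
# LTE by the predictor-corrector (Milne) device against the second-order
# explicit Taylor predictor.
.nk_step_bdf2 <- function(rhs, jac, t, x, f, xp, fp, h_prev, h, opt) {
  rho <- h / h_prev
  a1 <- (1 + rho)^2 / (1 + 2 * rho)
  a2 <- -rho^2 / (1 + 2 * rho)
  b <- (1 + rho) / (1 + 2 * rho)
  pred <- x + h * f + (h^2 / 2) * (f - fp) / h_prev
  ns <- .nk_newton(rhs, jac, t + h, cst = a1 * x + a2 * xp, gh = b * h,
                   y0 = pred, opt = opt)
  if (!ns$ok) return(ns)
  list(ok = TRUE, x = ns$y, f = ns$fy, lte = 0.35 * (ns$y - pred),
       niter = ns$niter)
}

# Backward-Euler seed step (BDF1) for pure gear2 startup.
.nk_step_be <- function(rhs, jac, t, x, f, h, opt) {
  ns <- .nk_newton(rhs, jac, t + h, cst = x, gh = h, y0 = x + h * f, opt = opt)
  if (!ns$ok) return(ns)
  list(ok = TRUE, x = ns$y, f = ns$fy,
       lte = 0.5 * (ns$y - (x + h * f)), niter = ns$niter)
}

.nk_resolve_jac <- function(rhs, opt) {
  j <- attr(rhs, "jacobian")
  if (!is.null(j)) return(j)
  function(t, x) {
    pracma::jacobian(function(z) rhs(t, z), x)
  }
}

.nk_integrate <- function(rhs, jac, x0, opt, species = NULL) {
  n <- length(x0)
  species <- species %||% names(x0) %||% paste0("x", seq_len(n))
  tt <- opt$total_time
  pt <- seq(0, tt, by = opt$print_step)
  if (tail(pt, 1) < tt - 1e-9 * tt) pt <- c(pt, tt) else pt[length(pt)] <- tt
  out <- matrix(NA_real_, length(pt), n,
                dimnames = list(NULL, species))
  out[1, ] <- x0
  ip <- 2L

  t <- 0; x <- as.numeric(x0)
  f <- rhs(t, x)
  if (!all(is.finite(f))) {
    stop("state blow-up: right-hand side is not finite at the initial state",
         call. = FALSE)
  }
  h <- opt$initial_step
  mode <- switch(opt$method, trapezoidal = "tr", gear2 = "gear", `tr-gear` = "tr")
  xp <- NULL; fp <- NULL; h_prev <- NA_real_
  acc <- 0L; rej <- 0L; nwt <- 0L; switches <- 0L
  ring <- 0L; gear_hold <- 0L; lte_prev <- NULL
  consec_rej <- 0L

  while (t < tt * (1 - 1e-14)) {
    h <- min(h, opt$max_step, tt - t)
    # floor at the floating-point resolution of the current time, else a
    # vanishing step can be "accepted" without advancing t at all
    h_min <- max(opt$min_step, 32 * .Machine$double.eps * t)
    if (h < h_min) {
      stop(sprintf("stiffness failure: step size underflow (h = %g s) at t = %g s",
                   h, t), call. = FALSE)
    }
    step <- if (mode == "gear") {
      if (is.null(xp)) .nk_step_be(rhs, jac, t, x, f, h, opt)
      else .nk_step_bdf2(rhs, jac, t, x, f, xp, fp, h_prev, h, opt)
    } else {
      .nk_step_tr(rhs, jac, t, x, f, h, opt)
    }
    nwt <- nwt + step$niter
    if (!step$ok) {
      if (isTRUE(step$blowup) && h <= 4 * opt$min_step) {
        stop(sprintf("state blow-up: non-finite right-hand side near t = %g s", t),
             call. = FALSE)
      }
      rej <- rej + 1L; consec_rej <- consec_rej + 1L
      h <- h / 2
      next
    }
    err <- max(abs(step$lte) / (opt$reltol * pmax(abs(x), abs(step$x)) + opt$abstol))
    if (!is.finite(err)) err <- 2 # treat as plain rejection
    if (err > 1) {
      rej <- rej + 1L; consec_rej <- consec_rej + 1L
      fac <- max(0.2, 0.9 * (.nk_lte_target / err)^(1 / 3))
      if (consec_rej >= 2L) fac <- min(fac, 0.5)
      h <- h * fac
      next
    }
    # accept: fill the print grid inside (t, t+h]
    t_new <- t + h
    while (ip <= length(pt) && pt[ip] <= t_new + 1e-12 * tt) {
      s <- (pt[ip] - t) / h
      out[ip, ] <- .nk_hermite(min(max(s, 0), 1), x, f, step$x, step$f, h)
      ip <- ip + 1L
    }
    # trapezoidal ringing detection (sign-alternating LTE on the dominant
    # component) -> temporary BDF2 fallback, SPICE TR/Gear practice
    if (opt$method == "tr-gear") {
      if (mode == "tr" && !is.null(lte_prev)) {
        i_max <- which.max(abs(step$lte))
        if (step$lte[i_max] * lte_prev[i_max] < 0 &&
            abs(step$lte[i_max]) > 0.25 * abs(lte_prev[i_max])) {
          ring <- ring + 1L
        } else ring <- 0L
        if (ring >= 3L) {
          mode <- "gear"; gear_hold <- 25L; ring <- 0L
          switches <- switches + 1L
        }
      } else if (mode == "gear") {
        gear_hold <- gear_hold - 1L
        if (gear_hold <= 0L) mode <- "tr"
      }
    }
    lte_prev <- step$lte
    xp <- x; fp <- f; h_prev <- h
    x <- step$x; f <- step$f; t <- t_new
    acc <- acc + 1L; consec_rej <- 0L
    h <- h * min(4, max(0.2, 0.9 * (.nk_lte_target / max(err, 1e-10))^(1 / 3)))
  }
  out[length(pt), ] <- x # exact endpoint state, no interpolation residue
  new_trajectory(times = pt, states = out, species = species, options = opt,
                 stats = list(accepted = acc, rejected = rej,
                              newton_iterations = nwt,
                              method_switches = switches))
}

#' Integrate a kinetic scheme, network or plain ODE system
#'
#' Native variable-step implicit integration (trapezoidal / variable-step
#' BDF2 with Newton iteration and RELTOL-driven local-truncation-error
#' control). Dispatches on a [kinetic_scheme()] (initial state and analytic
#' Jacobian derived from the scheme), an `nsm_network`, or a plain function
#' `f(t, x)`.
#'
#' @param x The system to integrate.
#' @param options A [sim_options()] object.
#' @param ... Passed to methods.
#' @return A `kin_trajectory`: print-grid times, one concentration vector
#'   per time, and step statistics.
#' @examples
#' fx <- decay_fixture(k = 1)
#' traj <- nsm_integrate(fx$scheme, sim_options(total_time = 1, print_step = 0.1))
#' traj
#' @export
nsm_integrate <- function(x, options, ...) UseMethod("nsm_integrate")

#' @rdname nsm_integrate
#' @param x0 Initial state (for the function method; defaults to the scheme's
#'   initial concentrations otherwise).
#' @export
nsm_integrate.kinetic_scheme <- function(x, options, x0 = NULL, ...) {
  rhs <- compile_rhs(x)
  x0 <- x0 %||% x$species
  .nk_integrate(rhs, attr(rhs, "jacobian"), x0, options,
                species = names(x$species))
}

#' @rdname nsm_integrate
#' @param include_resistors Whether the network method folds the continuity
#'   resistors' leak current into the dynamics (default `TRUE`: the network
#'   is integrated as built; the 1e12-ohm default makes the leak inert).
#' @export
nsm_integrate.nsm_network <- function(x, options, x0 = NULL,
                                      include_resistors = TRUE, ...) {
  rhs <- compile_rhs(x, include_resistors = include_resistors)
  x0 <- x0 %||% initial_state(x)
  .nk_integrate(rhs, attr(rhs, "jacobian"), x0, options,
                species = x$nodes$species)
}

#' @rdname nsm_integrate
#' @export
nsm_integrate.function <- function(x, options, x0, ...) {
  jac <- .nk_resolve_jac(x, options)
  .nk_integrate(x, jac, x0, options, species = names(x0))
}

#' Single implicit integration steps
#'
#' `step_trapezoidal()` solves `x1 = x + (h/2) (f(t, x) + f(t + h, x1))`;
#' `step_gear2()` solves the variable-coefficient BDF2 update using the
#' history point `x_prev` at `t - h_prev`. Both return the step result and a
#' local-truncation-error estimate (divided-difference of the third
#' derivative for the trapezoidal rule; predictor-corrector difference for
#' BDF2). These are the primitives the adaptive integrator alternates.
#'
#' @param rhs Function `f(t, x)`.
#' @param x State at time `t`.
#' @param t Current time.
#' @param h Step size (> 0).
#' @param jac Optional Jacobian function `(t, x) -> matrix`; finite
#'   differences otherwise.
#' @param reltol,abstol,newton_tol,newton_max_iter Newton/step control
#'   parameters as in [sim_options()].
#' @return A list with `x_next`, `lte` (per-component estimate) and
#'   `converged`.
#' @export
step_trapezoidal <- function(rhs, x, t, h, jac = NULL, reltol = 1e-3,
                             abstol = 1e-12, newton_tol = 1e-6,
                             newton_max_iter = 20L) {
  opt <- list(reltol = reltol, abstol = abstol, newton_tol = newton_tol,
              newton_max_iter = as.integer(newton_max_iter))
  jacf <- jac %||% .nk_resolve_jac(rhs, opt)
  f <- rhs(t, x)
  st <- .nk_step_tr(rhs, jacf, t, x, f, h, opt)
  if (!st$ok) return(list(x_next = NULL, lte = NULL, converged = FALSE))
  list(x_next = st$x, lte = st$lte, converged = TRUE)
}

#' @rdname step_trapezoidal
#' @param x_prev History state at `t - h_prev`.
#' @param h_prev Size of the previous step (defaults to `h`).
#' @export
step_gear2 <- function(rhs, x_prev, x, t, h, h_prev = h, jac = NULL,
                       reltol = 1e-3, abstol = 1e-12, newton_tol = 1e-6,
                       newton_max_iter = 20L) {
  opt <- list(reltol = reltol, abstol = abstol, newton_tol = newton_tol,
              newton_max_iter = as.integer(newton_max_iter))
  jacf <- jac %||% .nk_resolve_jac(rhs, opt)
  f <- rhs(t, x)
  fp <- rhs(t - h_prev, x_prev)
  st <- .nk_step_bdf2(rhs, jacf, t, x, f, x_prev, fp, h_prev, h, opt)
  if (!st$ok) return(list(x_next = NULL, lte = NULL, converged = FALSE))
  list(x_next = st$x, lte = st$lte, converged = TRUE)
}

#' Jacobian of a kinetic scheme or rhs function
#'
#' For a [kinetic_scheme()] (or an evaluator produced by [compile_rhs()])
#' the entries are the exact partial derivatives of the mass-action
#' polynomial; for a plain function, central finite differences.
#'
#' @param x A [kinetic_scheme()], a [compile_rhs()] evaluator, or any
#'   function `f(t, x)`.
#' @param state State vector at which to evaluate.
#' @param t Time (for time-dependent right-hand sides); default 0.
#' @return The `n x n` Jacobian matrix `d f_i / d x_j`.
#' @export
kin_jacobian <- function(x, state, t = 0) {
  if (inherits(x, "kinetic_scheme")) x <- compile_rhs(x)
  stopifnot(is.function(x))
  jf <- attr(x, "jacobian")
  if (!is.null(jf)) return(jf(t, state))
  pracma::jacobian(function(z) x(t, z), state)
}
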