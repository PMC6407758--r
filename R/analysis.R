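# Post-processing: plateau detection, algebraic steady-state-approximation
# (QSSA) solving, SSA validity reports and phase-space extraction.

#' Detect a stationary plateau in a trajectory
#'
#' The plateau is the earliest print point after which every species'
#' relative change per print step — measured against the species' own
#' trajectory maximum — stays below `rel_threshold` through the end of the
#' trajectory. Values are reported at the final time.
#'
#' @param trajectory A `kin_trajectory`.
#' @param rel_threshold Relative change per print step below which a species
#'   counts as stationary; default 1e-6.
#' @return An object of class `steady_state_result` with fields `values`,
#'   `reached`, `detection_time`, `criterion`.
#' @export
steady_state <- function(trajectory, rel_threshold = 1e-6) {
  stopifnot(inherits(trajectory, "kin_trajectory"))
  st <- trajectory$states
  K <- nrow(st)
  values <- final_state(trajectory)
  if (K < 2L) {
    return(structure(list(values = values, reached = TRUE,
                          detection_time = trajectory$times[1],
                          criterion = rel_threshold),
                     class = "steady_state_result"))
  }
  d <- abs(st[-1, , drop = FALSE] - st[-K, , drop = FALSE])
  # change measured against each species' own trajectory scale, so species
  # relaxing to zero register as stationary once their motion is negligible
  scale <- apply(abs(st), 2, max)
  rel <- sweep(d, 2, pmax(scale, 1e-300), "/")
  rel[d == 0] <- 0
  step_max <- apply(rel, 1, max) # one value per print interval
  ok <- step_max <= rel_threshold
  # earliest k with all intervals from k on stationary
  idx <- if (all(ok)) 1L else {
    last_bad <- max(which(!ok))
    if (last_bad == length(ok)) NA_integer_ else last_bad + 1L
  }
  reached <- !is.na(idx)
  structure(
    list(values = values, reached = reached,
         detection_time = if (reached) trajectory$times[idx] else NA_real_,
         criterion = rel_threshold),
    class = "steady_state_result"
  )
}

#' @export
print.steady_state_result <- function(x, ...) {
  if (x$reached) {
    cat(sprintf("Stationary plateau reached at t = %g s (relative-change criterion %g):\n",
                x$detection_time, x$criterion))
  } else {
    cat("No stationary plateau detected; values at final time:\n")
  }
  for (nm in names(x$values)) cat(sprintf("  [%s] = %.6g\n", nm, x$values[[nm]]))
  invisible(x)
}

#' Solve the steady-state approximation for intermediate species
#'
#' Sets `d[x]/dt = 0` for every species in `intermediates`, clamps the
#' remaining species at `x_fixed`, and solves the resulting algebraic
#' system by damped Newton iteration from multiple log-spaced positive
#' starts.
#'
#' @param scheme A [kinetic_scheme()].
#' @param intermediates Character vector of species forced to steady state;
#'   non-empty, strict subset of the species.
#' @param x_fixed Named values for the remaining species; defaults to the
#'   scheme's initial concentrations.
#' @param residual_tol Convergence requirement on the residual `|d[x]/dt|`
#'   of each intermediate equation, measured relative to the sum of the
#'   magnitudes of that equation's individual terms (so it is meaningful at
#'   any concentration/rate scale); default 1e-12.
#' @param n_starts Number of log-spaced multistart scales; default 10.
#' @return An object of class `ssa_result` with the all-species `values`
#'   vector, the `intermediates` set and the final `residual`.
#' @export
ssa_solve <- function(scheme, intermediates, x_fixed = NULL,
                      residual_tol = 1e-12, n_starts = 10L) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  sp <- names(scheme$species)
  if (!length(intermediates)) {
    stop("`intermediates` must be a non-empty set of species", call. = FALSE)
  }
  bad <- setdiff(intermediates, sp)
  if (length(bad)) {
    stop("unknown intermediate species: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(intermediates) >= length(sp)) {
    stop("`intermediates` must be a strict subset of the species (the rest are clamped)",
         call. = FALSE)
  }
  others <- setdiff(sp, intermediates)
  x_fixed <- x_fixed %||% scheme$species[others]
  if (!all(others %in% names(x_fixed))) {
    stop("`x_fixed` must provide values for: ", paste(others, collapse = ", "),
         call. = FALSE)
  }
  rhs <- compile_rhs(scheme)
  jac <- attr(rhs, "jacobian")
  tab <- attr(rhs, "table")
  ii <- match(intermediates, sp)
  full_x <- setNames(numeric(length(sp)), sp)
  full_x[others] <- as.numeric(x_fixed[others])
  g <- function(u) {
    full_x[ii] <- u
    rhs(0, full_x)[ii]
  }
  # residuals measured against the summed magnitude of each equation's terms,
  # so convergence is scale-free (Chapman rates live near 1e-11 mol/l/s)
  g_rel <- function(u) {
    full_x[ii] <- u
    scale <- nk_rhs(full_x, abs(tab$w), tab$target, tab$E)[ii]
    abs(rhs(0, full_x)[ii]) / pmax(scale, 1e-300)
  }
  gjac <- function(u) {
    full_x[ii] <- u
    jac(0, full_x)[ii, ii, drop = FALSE]
  }
  ref <- max(abs(full_x), 1e-12)
  scales <- 10^seq(-6, 3, length.out = n_starts)
  best <- list(rel = Inf, u = NULL)
  for (s in scales) {
    u <- rep(ref * s, length(ii))
    for (it in 1:80) {
      gv <- g(u)
      rel <- max(g_rel(u))
      if (!is.finite(rel) || rel <= residual_tol) break
      J <- gjac(u)
      du <- tryCatch(solve(J, gv), error = function(e) NULL)
      if (is.null(du) || !all(is.finite(du))) break
      lambda <- 1
      repeat { # damped update with positivity projection
        u_new <- pmax(u - lambda * du, 0)
        rel_new <- max(g_rel(u_new))
        if (is.finite(rel_new) && (rel_new < rel || lambda < 1e-6)) break
        lambda <- lambda / 2
      }
      if (max(abs(u_new - u)) == 0) { u <- u_new; break }
      u <- u_new
    }
    rel <- max(g_rel(u))
    if (is.finite(rel) && rel < best$rel) best <- list(rel = rel, u = u)
    if (best$rel <= residual_tol) break
  }
  if (best$rel > residual_tol) {
    stop(sprintf(
      "steady-state approximation did not converge after %d starts (best relative residual %.3g)",
      n_starts, best$rel), call. = FALSE)
  }
  full_x[ii] <- best$u
  structure(
    list(values = full_x, intermediates = intermediates,
         residual = max(abs(g(best$u))), relative_residual = best$rel),
    class = "ssa_result"
  )
}

#' @export
print.ssa_result <- function(x, ...) {
  cat(sprintf("Steady-state approximation (d[x]/dt = 0 for %s; residual %.3g):\n",
              paste(x$intermediates, collapse = ", "), x$residual))
  for (nm in names(x$values)) {
    tag <- if (nm %in% x$intermediates) " (intermediate)" else " (clamped)"
    cat(sprintf("  [%s] = %.6g%s\n", nm, x$values[[nm]], tag))
  }
  invisible(x)
}

#' Compare full integration against the steady-state approximation
#'
#' Integrates the scheme, extracts the stationary plateau, solves the SSA
#' with the non-intermediate species clamped at their initial
#' concentrations, and reports per-species ratios
#' (full-integration / SSA). Species whose ratio deviates from 1 by more
#' than `max_rel_dev` are flagged: a flagged intermediate means the
#' approximation fails for this mechanism.
#'
#' @param scheme A [kinetic_scheme()].
#' @param intermediates Species set forced to `d[x]/dt = 0` in the SSA.
#' @param options [sim_options()] for the full integration.
#' @param x_fixed Clamped values for the SSA (default: initial
#'   concentrations).
#' @param max_rel_dev Flag threshold on `|ratio - 1|`; default 0.1.
#' @param rel_threshold Plateau criterion passed to [steady_state()].
#' @return An object of class `ssa_comparison`: a report data frame plus the
#'   underlying results.
#' @export
compare_ssa <- function(scheme, intermediates, options, x_fixed = NULL,
                        max_rel_dev = 0.1, rel_threshold = 1e-6) {
  traj <- nsm_integrate(scheme, options)
  ss <- steady_state(traj, rel_threshold = rel_threshold)
  ssa <- ssa_solve(scheme, intermediates, x_fixed = x_fixed)
  ratio <- ifelse(ssa$values != 0, ss$values / ssa$values, NA_real_)
  report <- data.frame(
    species = names(scheme$species),
    full = as.numeric(ss$values),
    ssa = as.numeric(ssa$values),
    ratio = as.numeric(ratio),
    intermediate = names(scheme$species) %in% intermediates,
    flagged = !is.na(ratio) & abs(ratio - 1) > max_rel_dev,
    stringsAsFactors = FALSE
  )
  structure(
    list(report = report, steady_state = ss, ssa = ssa,
         max_rel_dev = max_rel_dev, plateau_reached = ss$reached),
    class = "ssa_comparison"
  )
}

#' @export
print.ssa_comparison <- function(x, ...) {
  cat("Full integration vs steady-state approximation\n")
  if (!x$plateau_reached) {
    cat("  (no strict plateau detected; full values taken at final time)\n")
  }
  print(x$report, row.names = FALSE, digits = 6)
  if (any(x$report$flagged & x$report$intermediate)) {
    cat(sprintf("Approximation FAILS (|ratio - 1| > %g on an intermediate)\n",
                x$max_rel_dev))
  } else {
    cat(sprintf("Approximation holds within %g on the intermediates\n",
                x$max_rel_dev))
  }
  invisible(x)
}

#' Extract a 3-D phase-space trajectory
#'
#' @param trajectory A `kin_trajectory`.
#' @param species Character vector of exactly three species names; the
#'   output columns follow this order.
#' @return A numeric matrix with three named columns, one row per print
#'   time (time order preserved).
#' @export
phase_space <- function(trajectory, species) {
  stopifnot(inherits(trajectory, "kin_trajectory"))
  if (length(species) != 3L) {
    stop("`species` must name exactly three species", call. = FALSE)
  }
  bad <- setdiff(species, trajectory$species)
  if (length(bad)) {
    stop("unknown species: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  trajectory$states[, species, drop = FALSE]
}
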