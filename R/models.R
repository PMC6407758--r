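# Built-in model fixtures. Each constructor returns a `kin_fixture`: the
# kinetic scheme, recommended simulation options, and notes.

.nk_fixture <- function(scheme, options, notes = "") {
  structure(list(scheme = scheme, options = options, notes = notes),
            class = "kin_fixture")
}

#' @export
print.kin_fixture <- function(x, ...) {
  print(x$scheme)
  print(x$options)
  if (nzchar(x$notes)) cat("Notes:", x$notes, "\n")
  invisible(x)
}

#' Diels-Alder cycloaddition fixture
#'
#' The reversible cycloaddition A + B <-> C (s-cis-1,3-butadiene + ethene
#' -> cyclohexene) with rate constants computed from the free-energy
#' barriers 113110.8 J/mol (forward) and 248626.4 J/mol (reverse) via the
#' Eyring equation. Initial conditions [A]0 = [B]0 = 1 mol/l, [C]0 = 0;
#' recommended horizon 1e7 s.
#'
#' @param temperature Temperature for the Eyring evaluation, K; default
#'   298.15.
#' @return A `kin_fixture`.
#' @examples
#' fx <- diels_alder_fixture()
#' constant_values(fx$scheme) # k1 >> k2
#' @export
diels_alder_fixture <- function(temperature = 298.15) {
  scheme <- kinetic_scheme(
    species = c(A = 1, B = 1, C = 0),
    constants = list(
      rate_constant("k1", barrier = 113110.8, temperature = temperature),
      rate_constant("k2", barrier = 248626.4, temperature = temperature)
    ),
    equations = list(
      rate_equation("A", list(rate_term("k1", c(A = 1, B = 1), sign = -1),
                              rate_term("k2", c(C = 1), sign = +1))),
      rate_equation("B", list(rate_term("k1", c(A = 1, B = 1), sign = -1),
                              rate_term("k2", c(C = 1), sign = +1))),
      rate_equation("C", list(rate_term("k1", c(A = 1, B = 1), sign = +1),
                              rate_term("k2", c(C = 1), sign = -1)))
    ),
    name = "Diels-Alder cycloaddition"
  )
  .nk_fixture(
    scheme,
    sim_options(total_time = 1e7, print_step = 2e4, reltol = 1e-6),
    "Barrier-derived constants; near-complete conversion, equilibrium constant k1/k2 ~ 5e23."
  )
}

#' Chapman stratospheric-ozone fixture
#'
#' Three-species encoding of the Chapman cycle (O2 photolysis, ozone
#' formation O + O2 + M -> O3 + M, ozone photolysis, odd-oxygen
#' recombination O + O3 -> 2 O2), including the stoichiometric multipliers
#' 2 k1 \[O2\] and 2 k4 \[O\]\[O3\]. The bath species M is treated as a
#' constant and folded into an effective `k2M = k2 * M`. No literature
#' parameter values are bundled: the rate constants and initial
#' concentrations are required arguments (the published stationary-ozone
#' comparison uses constants from the atmospheric-chemistry literature).
#'
#' @param k1 O2 photolysis rate, s^-1.
#' @param k2 Ozone-formation termolecular constant, l^2 mol^-2 s^-1.
#' @param k3 Ozone photolysis rate, s^-1.
#' @param k4 O + O3 recombination constant, l mol^-1 s^-1.
#' @param M Bath-gas concentration, mol/l (folded into `k2M`).
#' @param O2,O,O3 Initial concentrations, mol/l.
#' @param total_time,print_step Recommended transient options, s.
#' @return A `kin_fixture`.
#' @export
chapman_fixture <- function(k1, k2, k3, k4, M, O2, O = 0, O3 = 0,
                            total_time = 8e7, print_step = total_time / 400) {
  for (nm in c("k1", "k2", "k3", "k4", "M", "O2")) {
    v <- tryCatch(get(nm), error = function(e) NULL)
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("chapman_fixture: numeric scalar `", nm,
           "` is required (no literature defaults are bundled)", call. = FALSE)
    }
  }
  scheme <- kinetic_scheme(
    species = c(O2 = O2, O = O, O3 = O3),
    constants = c(k1 = k1, k2M = k2 * M, k3 = k3, k4 = k4),
    equations = list(
      rate_equation("O2", list(
        rate_term("k1", c(O2 = 1), sign = -1),
        rate_term("k2M", c(O = 1, O2 = 1), sign = -1),
        rate_term("k3", c(O3 = 1), sign = +1),
        rate_term("k4", c(O = 1, O3 = 1), sign = +1, coef = 2)
      )),
      rate_equation("O", list(
        rate_term("k1", c(O2 = 1), sign = +1, coef = 2),
        rate_term("k2M", c(O = 1, O2 = 1), sign = -1),
        rate_term("k3", c(O3 = 1), sign = +1),
        rate_term("k4", c(O = 1, O3 = 1), sign = -1)
      )),
      rate_equation("O3", list(
        rate_term("k2M", c(O = 1, O2 = 1), sign = +1),
        rate_term("k3", c(O3 = 1), sign = -1),
        rate_term("k4", c(O = 1, O3 = 1), sign = -1)
      ))
    ),
    name = "Chapman ozone cycle"
  )
  .nk_fixture(
    scheme,
    sim_options(total_time = total_time, print_step = print_step,
                reltol = 1e-6),
    "Open system as printed (photolysis source is not mass-closed); M folded into k2M."
  )
}

#' Olsen peroxidase-oxidase fixture
#'
#' Four-species simplified mechanism of the peroxidase-oxidase oscillator
#' (O2, NADH and the radical intermediates INT1, INT2), including the
#' autocatalytic step, the `2 k2 [INT1]^2` disproportionation, the
#' termolecular `3 k3 [O2][NADH][INT2]` branching and the reservoir exchange
#' terms. Reservoir levels are folded into effective zeroth-order
#' constants: `k6f = k6 [INT1]_0`, `k7f = k7 [O2]_0`, `k8f = k8 [NADH]_0`
#' (a folded constant of exactly zero drops its term). No literature values
#' are bundled; all parameters are required.
#'
#' @param k1,k2,k3,k4,k5,k6,k7,k8 Rate constants of the eight steps (the
#'   model's customary dimensionless units).
#' @param O2_feed,NADH_feed,INT1_feed Reservoir concentrations `[O2]_0`,
#'   `[NADH]_0`, `[INT1]_0`.
#' @param x0 Named initial state (`O2`, `NADH`, `INT1`, `INT2`).
#' @param total_time,print_step Recommended transient options (dimensionless
#'   time).
#' @return A `kin_fixture`.
#' @export
olsen_fixture <- function(k1, k2, k3, k4, k5, k6, k7, k8,
                          O2_feed, NADH_feed, INT1_feed = 1,
                          x0 = c(O2 = O2_feed, NADH = 1, INT1 = 1e-3,
                                 INT2 = 1e-3),
                          total_time = 500, print_step = 0.5) {
  ks <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k7 = k7,
          k6f = k6 * INT1_feed, k7f = k7 * O2_feed, k8f = k8 * NADH_feed)
  ks <- ks[ks > 0]
  tadd <- function(terms, kname, factors, sign, coef = 1) {
    if (!kname %in% names(ks)) return(terms) # folded constant was zero
    c(terms, list(rate_term(kname, factors, sign = sign, coef = coef)))
  }
  eq_O2 <- tadd(list(), "k3", c(O2 = 1, NADH = 1, INT2 = 1), -1)
  eq_O2 <- tadd(eq_O2, "k7f", numeric(0), +1)
  eq_O2 <- tadd(eq_O2, "k7", c(O2 = 1), -1)
  eq_N <- tadd(list(), "k1", c(NADH = 1, INT1 = 1), -1)
  eq_N <- tadd(eq_N, "k3", c(O2 = 1, NADH = 1, INT2 = 1), -1)
  eq_N <- tadd(eq_N, "k8f", numeric(0), +1)
  eq_I1 <- tadd(list(), "k1", c(NADH = 1, INT1 = 1), +1)
  eq_I1 <- tadd(eq_I1, "k2", c(INT1 = 2), -1, coef = 2)
  eq_I1 <- tadd(eq_I1, "k3", c(O2 = 1, NADH = 1, INT2 = 1), +1, coef = 3)
  eq_I1 <- tadd(eq_I1, "k4", c(INT1 = 1), -1)
  eq_I1 <- tadd(eq_I1, "k6f", numeric(0), +1)
  eq_I2 <- tadd(list(), "k2", c(INT1 = 2), +1, coef = 2)
  eq_I2 <- tadd(eq_I2, "k3", c(O2 = 1, NADH = 1, INT2 = 1), -1)
  eq_I2 <- tadd(eq_I2, "k5", c(INT2 = 1), -1)
  scheme <- kinetic_scheme(
    species = c(O2 = x0[["O2"]], NADH = x0[["NADH"]], INT1 = x0[["INT1"]],
                INT2 = x0[["INT2"]]),
    constants = ks,
    equations = list(rate_equation("O2", eq_O2), rate_equation("NADH", eq_N),
                     rate_equation("INT1", eq_I1), rate_equation("INT2", eq_I2)),
    name = "Olsen peroxidase-oxidase"
  )
  .nk_fixture(
    scheme,
    sim_options(total_time = total_time, print_step = print_step,
                reltol = 1e-6),
    "Eight-step simplified peroxidase-oxidase mechanism; reservoir feeds folded into zeroth-order constants."
  )
}

#' Damped-oscillator fixture (mechanical/electrical analogy)
#'
#' The non-forced damped oscillator `m x'' + b x' + k x = 0` written as a
#' two-variable first-order system (position `x`, velocity `v`). Supplying
#' the series-RLC parameters instead (`L`, `R`, `C`) applies the classical
#' mapping `m -> L`, `b -> R`, `k -> 1/C`, `x -> q` and produces the
#' identical system.
#'
#' @param m,b,k Mass, damping constant (>= 0) and restoring constant.
#' @param L,R,C Inductance, resistance, capacitance (alternative
#'   parameterisation; give either all of `m, k` or all of `L, C`).
#' @param x0,v0 Initial position/charge and velocity/current (>= 0 as scheme
#'   initial conditions).
#' @param total_time,print_step Recommended transient options, s.
#' @return A `kin_fixture`.
#' @examples
#' mech <- oscillator_fixture(m = 1, b = 0.5, k = 0.25)
#' elec <- oscillator_fixture(L = 1, R = 0.5, C = 4)
#' identical(canonical_terms(mech$scheme), canonical_terms(elec$scheme))
#' @export
oscillator_fixture <- function(m = NULL, b = NULL, k = NULL,
                               L = NULL, R = NULL, C = NULL,
                               x0 = 1, v0 = 0,
                               total_time = 40, print_step = 0.05) {
  if (!is.null(L) || !is.null(C)) {
    if (is.null(L) || is.null(C)) {
      stop("electrical parameterisation requires both `L` and `C`", call. = FALSE)
    }
    m <- L; b <- R %||% 0; k <- 1 / C
  }
  b <- b %||% 0
  if (is.null(m) || is.null(k)) {
    stop("supply mechanical (m, k) or electrical (L, C) parameters", call. = FALSE)
  }
  if (m <= 0 || k <= 0 || b < 0) {
    stop("parameters must satisfy m > 0 (L > 0), k > 0 (C > 0), b >= 0 (R >= 0)",
         call. = FALSE)
  }
  constants <- c(c1 = 1, km = k / m)
  v_terms <- list(rate_term("km", c(x = 1), sign = -1))
  if (b > 0) {
    constants <- c(constants, bm = b / m)
    v_terms <- c(v_terms, list(rate_term("bm", c(v = 1), sign = -1)))
  }
  scheme <- kinetic_scheme(
    species = c(x = x0, v = v0),
    constants = constants,
    equations = list(
      rate_equation("x", list(rate_term("c1", c(v = 1), sign = +1))),
      rate_equation("v", v_terms)
    ),
    name = "damped oscillator"
  )
  .nk_fixture(
    scheme,
    sim_options(total_time = total_time, print_step = print_step,
                reltol = 1e-6),
    "m x'' + b x' + k x = 0 as a first-order pair; identical under m->L, b->R, k->1/C, x->q."
  )
}

#' Exponential-decay fixture
#'
#' Single species, `d[A]/dt = -k [A]` — the netlist and closed-form
#' smoke-test system.
#'
#' @param k Decay rate constant, s^-1.
#' @param x0 Initial concentration, mol/l.
#' @param total_time,print_step Recommended transient options, s.
#' @return A `kin_fixture`.
#' @export
decay_fixture <- function(k = 1, x0 = 1, total_time = 5,
                          print_step = 0.05) {
  scheme <- kinetic_scheme(
    species = c(A = x0),
    constants = c(k = k),
    equations = list(rate_equation("A", rate_term("k", c(A = 1), sign = -1))),
    name = "exponential decay"
  )
  .nk_fixture(scheme,
              sim_options(total_time = total_time, print_step = print_step,
                          reltol = 1e-6),
              "Closed form [A](t) = [A]0 exp(-k t).")
}

#' Irreversible decay chain A -> B -> C
#'
#' @param k1,k2 Step rate constants, s^-1.
#' @param a0 Initial `[A]`, mol/l (`[B]0 = [C]0 = 0`).
#' @param total_time,print_step Recommended transient options, s.
#' @return A `kin_fixture`.
#' @export
decay_chain_fixture <- function(k1 = 1, k2 = 10, a0 = 1,
                                total_time = 5, print_step = 0.05) {
  scheme <- scheme_from_reactions(
    list(reaction(c(A = 1), c(B = 1), kf = "k1"),
         reaction(c(B = 1), c(C = 1), kf = "k2")),
    species = c(A = a0, B = 0, C = 0),
    constants = c(k1 = k1, k2 = k2),
    name = "decay chain"
  )
  .nk_fixture(scheme,
              sim_options(total_time = total_time, print_step = print_step,
                          reltol = 1e-6),
              "Closed-form bi-exponential; [B]_QSSA = k1 [A] / k2 under fast k2.")
}

#' Reversible isomerisation A <-> B
#'
#' @param kf,kr Forward/reverse rate constants, s^-1.
#' @param a0,b0 Initial concentrations, mol/l.
#' @param total_time,print_step Recommended transient options, s.
#' @return A `kin_fixture`.
#' @export
reversible_pair_fixture <- function(kf = 1, kr = 0.5, a0 = 1, b0 = 0,
                                    total_time = 10, print_step = 0.05) {
  scheme <- scheme_from_reactions(
    list(reaction(c(A = 1), c(B = 1), kf = "kf", kr = "kr")),
    species = c(A = a0, B = b0),
    constants = c(kf = kf, kr = kr),
    name = "reversible pair"
  )
  .nk_fixture(scheme,
              sim_options(total_time = total_time, print_step = print_step,
                          reltol = 1e-6),
              "Relaxes to equilibrium at rate kf + kr.")
}

#' Catalog of built-in fixtures
#'
#' @return Named list of fixture constructor functions.
#' @export
fixture_catalog <- function() {
  list(
    diels_alder = diels_alder_fixture,
    chapman = chapman_fixture,
    olsen = olsen_fixture,
    oscillator = oscillator_fixture,
    decay = decay_fixture,
    decay_chain = decay_chain_fixture,
    reversible_pair = reversible_pair_fixture
  )
}

#' Example parameter set for the Chapman fixture
#'
#' A synthetic illustrative parameter set (not a literature calibration) in
#' a regime where ozone destruction is dominated by the odd-oxygen
#' recombination step, so the full integration plateaus far above the
#' steady-state-approximation root — the situation in which testing the
#' approximation numerically matters.
#'
#' @return Named list of arguments for [chapman_fixture()].
#' @export
chapman_example_parameters <- function() {
  list(k1 = 3e-8, k2 = 1e6, k3 = 1e-10, k4 = 1e4, M = 1e-2, O2 = 1e-3)
}

#' Example chaotic parameter set for the Olsen model
#'
#' A synthetic illustrative parameter set, found by exploring the model's
#' chaotic regime, that drives the peroxidase-oxidase fixture onto a
#' strange attractor (positive largest Lyapunov exponent). It is shipped
#' for demonstrations and diagnostics only and is not a literature
#' calibration of the real reaction.
#'
#' @return Named list of arguments for [olsen_fixture()].
#' @export
olsen_example_parameters <- function() {
  list(k1 = 0.35, k2 = 250, k3 = 0.035, k4 = 20, k5 = 5.35, k6 = 1e-5,
       k7 = 0.1, k8 = 0.825, O2_feed = 8, NADH_feed = 1, INT1_feed = 1,
       x0 = c(O2 = 4, NADH = 60, INT1 = 0.01, INT2 = 0.01))
}
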