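---
title: "The Network Simulation Method for chemical kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Network Simulation Method for chemical kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netkin)
```

## The model

A chemical mechanism with species $x_1,\dots,x_n$ obeying mass-action
kinetics is a system of first-order ODEs, one per species,

$$\frac{d[x_n]}{dt} \;=\; \sum_i k_i \prod_j [x_{ij}]^{\alpha_{ij}},$$

where each signed addend is a *rate term*: a rate constant $k_i$ times
concentrations raised to small integer powers, possibly with a
stoichiometric multiplier (the $2k[X]^2$ of a disproportionation step) or
with an empty product (a zeroth-order reservoir feed whose constant level is
folded into the constant). `netkin` stores exactly this structure: a
`kinetic_scheme` is species with initial concentrations, rate constants, and
one ordered list of rate terms per species.

### The electrical analogue

The Network Simulation Method (NSM) maps this system onto an electrical
circuit in which each species is a node whose voltage *is* its concentration
(1 mol/l $\leftrightarrow$ 1 V). Three devices per node suffice:

* a **capacitor** of unit capacitance to ground, whose current
  $C\,dV/dt = d[x]/dt$ carries the time derivative;
* one **voltage-controlled current source** per rate term, injecting
  $\pm\,c\,k\prod_j V_j^{\alpha_j}$ into the node;
* a **high-value resistor** to ground, present only for circuit continuity.

Kirchhoff's current law at a node — capacitor current equals the sum of
injected source currents — is then term-for-term the species' rate
equation; for a one-step balanced reaction it expresses that the
renormalised flows (extent change per unit time) of every reactant and
product coincide. `build_network()` performs the construction,
`kcl_terms()` reads the balance back off the sources so tests can prove the
equivalence symbolically, and `export_cir()`/`parse_cir()` serialise the
circuit in a PSpice analogue-behavioural dialect (`G... VALUE={...}` cards,
`.TRAN ... UIC`, initial conditions as `IC=` on the capacitors). Since unit
capacitance makes currents equal rates, the netlist is a complete, portable
statement of the kinetics.

Because every species must carry its own balance, one capacitor, one
resistor and one equation exist per species; the number of sources equals
the number of rate terms (the reservoir-exchange addend
$k_7([{\rm O_2}]_0-[{\rm O_2}])$ of the peroxidase-oxidase model expands
into a zeroth-order feed plus a first-order sink, i.e. two sources).

### Rate constants from barriers

Rate constants can be entered directly or derived from a molar free-energy
barrier via the Eyring equation
$k = (k_B T/h)\,\exp(-\Delta G^{\ddagger}/RT)$ with transmission
coefficient 1 (`eyring_rate()`). Physical constants are CODATA 2018 exact
values, stated to full precision in the source
($k_B = 1.380649\times10^{-23}$ J/K, $h = 6.62607015\times10^{-34}$ J s,
$R = 8.31446261815324$ J/(mol K)), so barrier-derived constants are
reproducible bit-for-bit. For multimolecular terms the implied
standard-state concentration is 1 mol/l, so the s$^{-1}$-scale value is
used as-is against mol/l concentrations. The Diels-Alder fixture never
hard-codes its rate constants: they are computed from the two barriers
(113110.8 and 248626.4 J/mol) at the requested temperature, with 298.15 K
as the package default since the original description leaves the
temperature unstated.

## The native integrator

The solver reproduces the numerical contract of a SPICE transient analysis:
an implicit, A-stable, second-order pair — the trapezoidal rule and the
two-step backward differentiation formula (BDF2, the "Gear" method of
second order) in its variable-coefficient form — with variable step size
driven by a local-truncation-error (LTE) test against `RELTOL`.

* **Trapezoidal step.** $x_{n+1} = x_n + \frac h2(f_n + f_{n+1})$, solved
  by Newton iteration on the analytic mass-action Jacobian (exact partial
  derivatives of the polynomial rate law; finite differences are used only
  for arbitrary user functions). The LTE $-\frac{h^3}{12}x'''$ is estimated
  from a divided difference of the derivative using an extra evaluation at
  the cubic-Hermite midpoint of the step:
  $\widehat{\rm LTE} = -\frac h3 (f_n - 2f_{mid} + f_{n+1})$.
* **BDF2 step.** With step ratio $\rho = h_n/h_{n-1}$,
  $x_{n+1} = \frac{(1+\rho)^2}{1+2\rho}x_n - \frac{\rho^2}{1+2\rho}x_{n-1}
  + \frac{(1+\rho)h}{1+2\rho} f_{n+1}$; the LTE is taken from the
  predictor-corrector difference against the explicit second-order Taylor
  predictor (Milne device). Pure BDF2 runs seed their history with one
  backward-Euler step.
* **Error control.** A step is accepted when
  $\max_i |{\rm LTE}_i| / ({\rm RELTOL}\,|x_i| + {\rm ABSTOL}) \le 1$, with
  ABSTOL defaulting to $10^{-12}$ mol/l as an absolute floor near zero
  concentrations. The next step is sized by the standard third-root rule
  towards a target ratio of 0.3 rather than the acceptance boundary
  (safety 0.9, growth capped at 4, two consecutive rejections halve $h$):
  sizing to the boundary itself lets the *accumulated* error drift towards
  $N_{\rm steps}\cdot$RELTOL, while the 0.3 target keeps global errors
  within a few RELTOL on the dissipative problems the package addresses.
  Oscillatory systems accumulate phase error linearly in the horizon, so
  for very tight tolerances over many periods the global error saturates
  near $10^{-5}$ relative regardless of RELTOL — visible in the damped
  oscillator tests, and inherent to any second-order method under per-step
  control.
* **TR/Gear policy (`method = "tr-gear"`, the default).** Trapezoidal
  integration with a temporary switch to BDF2 when trapezoidal ringing is
  detected (the LTE of the dominant component alternating sign over three
  consecutive accepted steps), mirroring circuit-simulator practice; the
  original description names the method pair but not the switching rule, so
  the rule here is a documented choice validated by the oracle tests rather
  than by step-for-step imitation. Pure `"trapezoidal"` and `"gear2"` modes
  are selectable for testing.
* **Output.** `Total time` and `Time step` (the print step) define the
  output grid only; values are obtained by cubic Hermite interpolation on
  the accepted mesh, so printing never constrains the adaptive step.
  `NUMDGT` formats text output and never touches arithmetic. No
  non-negativity clamping is applied: an undershoot below zero is reported,
  not silently corrected, so tolerance problems stay visible.
* **Failure modes.** Newton non-convergence rejects the step and retries at
  half the size; a step that underflows `min_step` (or the floating-point
  resolution of the current time) raises a stiffness-failure error carrying
  the failing time; non-finite right-hand sides raise a blow-up error.

Both methods are A-stable, so stiffness — rate constants spread over many
orders of magnitude, the motivating regime for the electrical analogy —
costs implicit steps proportional to the *dynamics*, not to the fastest
rate: a $10^6$ rate-ratio scheme integrates in a few thousand accepted
steps where an explicit method at its stability limit would need millions.

The mass-action right-hand side, its analytic Jacobian and the fixed-step
RK4 reference integrator run in compiled code on a flattened term table;
the adaptive algorithm itself is R. `integrate_rk4()` exists purely as the
brute-force oracle against which the native integrator is validated
(agreement to $10^{-4}$ relative on randomly generated schemes at
RELTOL $10^{-6}$, with $10^6$ fixed steps on the oracle side).

## Analysis tools

**Steady states.** `steady_state()` detects a plateau as the earliest print
point after which every species' change per print step, relative to that
species' own trajectory maximum, stays below a threshold (default
$10^{-6}$); measuring against the trajectory maximum lets species that
relax to zero register as stationary. **`ssa_solve()`** imposes
$d[x]/dt = 0$ on a chosen intermediate set with the remaining species
clamped (by default at their initial concentrations) and solves the
algebraic system by damped Newton iteration with positivity projection and
ten log-spaced starts. Convergence is judged on the residual *relative to
the summed magnitudes of each equation's terms* — an absolute criterion is
meaningless across the $10^{-11}$ mol/l s$^{-1}$ scales of the ozone cycle
and the $O(1)$ scales of the enzyme model. **`compare_ssa()`** runs both
pipelines and reports per-species full/SSA ratios, flagging deviations
(default 10%): for a fast-slow decay chain the ratio approaches 1 as the
timescale separation grows, while mechanisms without separation — or the
ozone cycle in recombination-dominated regimes — are flagged as SSA
failures.

**Chaos diagnostics.** `phase_space()` extracts ordered coordinate triples;
`lyapunov_max()` estimates the largest Lyapunov exponent by the Benettin
two-trajectory method: a companion displaced by $\delta_0$
($10^{-8}\,\max(\lVert x_0\rVert, 1)$ by default) is renormalised back to
$\delta_0$ at fixed intervals and the log stretches are averaged, with the
first half of the run discarded as transient. On linear systems the
estimate matches the dominant eigenvalue to a few percent. On a chaotic
attractor the *finite-time* estimate fluctuates intrinsically, and any
change in the arithmetic of the reference orbit (such as restarting the
adaptive solver at different times) is amplified to an O(1) orbit change
within a few Lyapunov times, contaminating run-to-run comparisons. The
`chunk` argument therefore decouples integration chunking from the
renormalisation interval: runs compared across renormalisation intervals
share one chunk length, follow a bit-identical reference orbit, and the
tests' ±20% stability requirement under halving of the interval then
measures the estimator itself (observed sensitivity: ~1e-4 relative on an
800-time-unit horizon in the shipped example regime).

## Built-in models

* `diels_alder_fixture()` — the reversible cycloaddition A + B ⇌ C with
  barrier-derived constants; equilibrium constant $k_1/k_2 \approx 5\times
  10^{23}$, so conversion is essentially complete. The approach to
  equilibrium of a bimolecular step is algebraic ($\sim 1/k_1 t$), so the
  equilibrium-gap check integrates to $10^{14}$ s, far beyond the
  $10^7$-s display horizon.
* `chapman_fixture()` — the three-species ozone cycle, with the bath
  species M folded into an effective `k2M` and the printed stoichiometric
  multipliers kept ($2k_1[{\rm O_2}]$, $2k_4[{\rm O}][{\rm O_3}]$). The
  printed system conserves total oxygen atoms $2[{\rm O_2}] + [{\rm O}] +
  3[{\rm O_3}]$, which the tests verify by a null-space check. No
  literature rate constants are bundled — they are required arguments, and
  reproducing published stationary-ozone values requires the constants
  from the cited atmospheric-chemistry sources. `chapman_example_parameters()`
  is a clearly-labelled synthetic regime for exercising the machinery.
* `olsen_fixture()` — the eight-step simplified peroxidase-oxidase
  mechanism over O$_2$, NADH and two radical intermediates, with reservoir
  feeds folded into zeroth-order constants (`k6f`, `k7f`, `k8f`; a folded
  constant of exactly zero drops its term). `olsen_example_parameters()`
  is a synthetic parameter set located by exploring the model's chaotic
  regime (period-doubling cascade in the NADH-recruitment constant); it is
  shipped for diagnostics and demonstrations, not as a calibration of the
  real enzyme reaction.
* `oscillator_fixture()` — the damped oscillator $m\ddot x + b\dot x + kx =
  0$ as a first-order pair, constructible from mechanical $(m, b, k)$ or
  series-RLC $(L, R, C)$ parameters under the classical mapping $m \to L$,
  $b \to R$, $k \to 1/C$, $x \to q$; both parameterisations build the
  identical scheme object.
* `decay_fixture()`, `decay_chain_fixture()`, `reversible_pair_fixture()` —
  closed-form systems for the solver's ground-truth suite.
* `random_scheme()` — reproducible random mass-action schemes assembled
  from uni-/bimolecular reaction templates (exponents 1 and 2), so
  trajectories from non-negative states stay non-negative; the `closed`
  variant uses only molecule-count-preserving templates, making the
  all-ones vector a conserved left null vector, and wide
  `rate_scale_range`s pin the extreme constants to the range endpoints to
  guarantee stiffness.

### What the synthetic generators do and do not show

The random generator emulates the *structure* of mass-action networks
(polynomial right-hand sides, conservation, stiffness) under exactly known
ground truth, which is what validates the integrator and the network
construction. It does not emulate measurement noise, uncertain or
temperature-dependent rate constants, non-polynomial rate laws
(Michaelis-Menten forms must be pre-expanded), or transport coupling — so
green tests certify the numerics, not the fit of any particular published
mechanism to data. Likewise the Chapman and Olsen example parameter sets
are synthetic: they reproduce qualitative regimes (SSA failure; chaos), not
literature values.

## Numerical choices and limitations

* Tolerances: `reltol` in $(0, 0.1]$, default $10^{-3}$; `abstol`
  $10^{-12}$ mol/l; Newton tolerance $10^{-2}$ of the step tolerance, at
  most 8 iterations per step inside the integrator.
* Startup: `initial_step` defaults to $10^{-6}\times$ print step;
  `max_step` to a tenth of the horizon; `min_step` is additionally floored
  at the floating-point resolution of the current time.
* The continuity resistor defaults to $10^{15}\,\Omega$: its leak current
  integrates to roughly $T/R$ in concentration units along conserved
  directions, so over a $10^7$-s horizon a $10^{12}\,\Omega$ resistor
  would already perturb the fourth significant digit at $10^{-6}$
  resolution. Tests verify the default perturbs the Diels-Alder solution
  by less than $10^{-6}$ relative.
* Problem sizes in the test-suite were chosen to exercise each property at
  statistically meaningful but desk-scale sizes: 20 random schemes for the
  oracle comparison, $10^6$ RK4 oracle steps, a 1600-time-unit chaos
  horizon, $10^{14}$ s for the equilibrium gap.
* Non-goals: higher-order BDF, DAEs, event detection, SBML import, and
  running an external SPICE engine (the netlist export is complete, and an
  external engine can consume it, but the native integrator replaces it).

## Reading and writing schemes

The plain-text scheme format is versioned (`# netkin scheme v1`) with
`[species]`, `[constants]` (direct values or `barrier:<J/mol>@<K>`) and
`[equations]` sections; equations are written exactly as the rate law
reads, e.g.

```
d[INT1]/dt = k1*NADH*INT1 - 2*k2*INT1^2 + 3*k3*O2*NADH*INT2 - k4*INT1 + k6f
```

`read_scheme(write_scheme(s))` is the identity on valid schemes, and every
parse error carries its line number. The command-line interface
(`exec/netkin`, or `netkin_main()` from R) chains the workflow — scheme
file, options, simulation, CSV/netlist export, SSA report, chaos
diagnostics — with a YAML config file overridable by flags.
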