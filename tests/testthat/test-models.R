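# Fixture fidelity: the built-in models encode their published equation
# structures term-for-term, and the random generator behaves reproducibly.

test_that("the cycloaddition fixture encodes d[A]/dt = -k1[A][B] + k2[C] and mirrors", {
  fx <- diels_alder_fixture()
  expected <- list(
    A = sort(c("-1*k1*A^1*B^1", "+1*k2*C^1")),
    B = sort(c("-1*k1*A^1*B^1", "+1*k2*C^1")),
    C = sort(c("+1*k1*A^1*B^1", "-1*k2*C^1"))
  )
  expect_identical(canonical_terms(fx$scheme), expected)
  k <- constant_values(fx$scheme)
  expect_gt(k[["k1"]], k[["k2"]]) # lower barrier, faster step
  expect_equal(unname(fx$scheme$species), c(1, 1, 0))
})

test_that("[A](t) = [B](t) for the symmetric cycloaddition initial conditions", {
  fx <- diels_alder_fixture()
  tr <- run_scheme(fx$scheme, 1e7, 1e5, reltol = 1e-8)
  expect_equal(tr$states[, "A"], tr$states[, "B"], tolerance = 1e-12)
})

test_that("the Chapman fixture encodes the printed three-equation cycle with its 2x multipliers", {
  p <- chapman_example_parameters()
  fx <- do.call(chapman_fixture, p)
  expected <- list(
    O2 = sort(c("-1*k1*O2^1", "-1*k2M*O^1*O2^1", "+1*k3*O3^1",
                "+2*k4*O^1*O3^1")),
    O = sort(c("+2*k1*O2^1", "-1*k2M*O^1*O2^1", "+1*k3*O3^1",
               "-1*k4*O^1*O3^1")),
    O3 = sort(c("+1*k2M*O^1*O2^1", "-1*k3*O3^1", "-1*k4*O^1*O3^1"))
  )
  expect_identical(canonical_terms(fx$scheme), expected)
  expect_equal(constant_values(fx$scheme)[["k2M"]], p$k2 * p$M)
})

test_that("without destruction steps the Chapman oxygen-atom pool grows monotonically", {
  p <- chapman_example_parameters()
  # k3 = k4 = 0 is outside the positive-constant domain, so drop the terms by
  # building the production-only subsystem from the same structure
  s <- kinetic_scheme(
    species = c(O2 = p$O2, O = 0),
    constants = c(k1 = p$k1, k2M = p$k2 * p$M),
    equations = list(
      rate_equation("O2", list(rate_term("k1", c(O2 = 1), sign = -1),
                               rate_term("k2M", c(O = 1, O2 = 1), sign = -1))),
      rate_equation("O", list(rate_term("k1", c(O2 = 1), sign = +1, coef = 2),
                              rate_term("k2M", c(O = 1, O2 = 1), sign = -1)))
    ))
  tr <- run_scheme(s, 1e6, 1e4, reltol = 1e-8)
  expect_true(all(diff(tr$states[, "O2"]) <= 0))
})

test_that("the Chapman cycle conserves total oxygen atoms 2[O2] + [O] + 3[O3]", {
  fx <- do.call(chapman_fixture, chapman_example_parameters())
  # the printed cycle is atom-closed: (2, 1, 3) is a left null vector
  rhs <- compile_rhs(fx$scheme)
  for (i in 1:10) {
    x <- runif(3, 0, 1e-3)
    expect_lt(abs(sum(c(2, 1, 3) * rhs(0, x))), 1e-15) # float cancellation only
  }
  tr <- run_scheme(fx$scheme, 1e7, 1e5, reltol = 1e-8)
  atoms <- tr$states %*% c(2, 1, 3)
  expect_lt(max(abs(atoms - atoms[1])) / atoms[1], 1e-8)
})

test_that("the peroxidase-oxidase fixture encodes the eight-step structure with 2x and 3x multipliers", {
  p <- olsen_example_parameters()
  fx <- do.call(olsen_fixture, p)
  expected <- list(
    O2 = sort(c("-1*k3*INT2^1*NADH^1*O2^1", "+1*k7f", "-1*k7*O2^1")),
    NADH = sort(c("-1*k1*INT1^1*NADH^1", "-1*k3*INT2^1*NADH^1*O2^1",
                  "+1*k8f")),
    INT1 = sort(c("+1*k1*INT1^1*NADH^1", "-2*k2*INT1^2",
                  "+3*k3*INT2^1*NADH^1*O2^1", "-1*k4*INT1^1", "+1*k6f")),
    INT2 = sort(c("+2*k2*INT1^2", "-1*k3*INT2^1*NADH^1*O2^1",
                  "-1*k5*INT2^1"))
  )
  expect_identical(canonical_terms(fx$scheme), expected)
  kv <- constant_values(fx$scheme)
  expect_equal(kv[["k7f"]], p$k7 * p$O2_feed)
  expect_equal(kv[["k8f"]], p$k8 * p$NADH_feed)
})

test_that("degenerate peroxidase-oxidase limits behave as closed forms dictate", {
  # oxygen-exchange only: [O2] relaxes exponentially to the reservoir level
  fx <- olsen_fixture(k1 = 0, k2 = 0, k3 = 0, k4 = 0, k5 = 0, k6 = 0,
                      k7 = 0.5, k8 = 0, O2_feed = 8, NADH_feed = 1,
                      x0 = c(O2 = 2, NADH = 1, INT1 = 0.5, INT2 = 0.5))
  tr <- run_scheme(fx$scheme, 10, 0.1, reltol = 1e-8)
  exact <- 8 + (2 - 8) * exp(-0.5 * tr$times)
  expect_lt(max(abs(tr$states[, "O2"] - exact)) / 8, 1e-6)
  # untouched species stay constant
  expect_true(all(tr$states[, "NADH"] == 1))
  expect_true(all(tr$states[, "INT1"] == 0.5))
})

test_that("mechanical and electrical oscillator parameterisations are the same system", {
  mech <- oscillator_fixture(m = 1, b = 0.5, k = 0.25)
  elec <- oscillator_fixture(L = 1, R = 0.5, C = 4) # k = 1/C = 0.25
  expect_identical(canonical_terms(mech$scheme), canonical_terms(elec$scheme))
  expect_equal(constant_values(mech$scheme), constant_values(elec$scheme))
  t1 <- run_scheme(mech$scheme, 40, 0.2)
  t2 <- run_scheme(elec$scheme, 40, 0.2)
  expect_identical(t1$states, t2$states)
  expect_error(oscillator_fixture(m = -1, b = 0, k = 1), "m > 0")
})

test_that("the undamped oscillator conserves energy to solver tolerance", {
  fx <- oscillator_fixture(m = 1, b = 0, k = 4)
  tr <- run_scheme(fx$scheme, 20, 0.05, reltol = 1e-8)
  E <- 0.5 * tr$states[, "v"]^2 + 0.5 * 4 * tr$states[, "x"]^2
  expect_lt(max(abs(E - E[1])) / E[1], 1e-5)
})

test_that("the underdamped oscillator matches its closed form", {
  fx <- oscillator_fixture(m = 1, b = 0.5, k = 4)
  tr <- run_scheme(fx$scheme, 40, 0.05, reltol = 1e-6)
  exact <- underdamped_exact(tr$times, m = 1, b = 0.5, k = 4)
  expect_lt(sup_rel_error(tr$states, exact), 1e-4)
})

test_that("random schemes are reproducible, closed ones conserve, wide ranges are stiff", {
  a <- random_scheme(4, 10, rng_seed = 42)
  b <- random_scheme(4, 10, rng_seed = 42)
  expect_identical(canonical_terms(a), canonical_terms(b))
  expect_equal(a$species, b$species)
  expect_equal(constant_values(a), constant_values(b))
  cl <- random_scheme(5, 12, rng_seed = 9, closed = TRUE)
  W <- left_null_space(attr(cl, "stoichiometry"))
  expect_gt(ncol(W), 0L)
  # all-ones is in the left null space for count-preserving templates
  expect_lt(max(abs(rep(1, 5) %*% attr(cl, "stoichiometry"))), 1e-12)
  st <- random_scheme(4, 10, rate_scale_range = c(1, 1e6), rng_seed = 3)
  kv <- constant_values(st)
  expect_gte(max(kv) / min(kv), 1e5)
  # the generator must not disturb the global RNG stream
  set.seed(1); r1 <- runif(1)
  set.seed(1); invisible(random_scheme(3, 6, rng_seed = 8)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("the fixture catalog entries all build valid schemes", {
  cat <- fixture_catalog()
  expect_named(cat, c("diels_alder", "chapman", "olsen", "oscillator",
                      "decay", "decay_chain", "reversible_pair"))
  fx <- list(cat$diels_alder(), do.call(cat$chapman, chapman_example_parameters()),
             do.call(cat$olsen, olsen_example_parameters()), cat$oscillator(m = 1, b = 1, k = 1),
             cat$decay(), cat$decay_chain(), cat$reversible_pair())
  for (f in fx) {
    expect_s3_class(f$scheme, "kinetic_scheme")
    expect_s3_class(f$options, "sim_options")
  }
})
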