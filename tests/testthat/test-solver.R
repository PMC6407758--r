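# Native variable-step trapezoidal/BDF2 integrator.

test_that("exponential decay matches the closed form within 10 reltol across tolerances", {
  fx <- decay_fixture(k = 1)
  for (rt in c(1e-3, 1e-4, 1e-6)) {
    tr <- run_scheme(fx$scheme, 1, 0.1, reltol = rt)
    exact <- matrix(exp(-tr$times), ncol = 1)
    expect_lt(sup_rel_error(tr$states, exact), 10 * rt)
  }
})

test_that("a trapezoidal step on a linear rhs equals the Pade update exactly", {
  for (z in c(0.1, 1, 10, 100, 1000)) {
    s <- step_trapezoidal(function(t, x) -x, x = 1, t = 0, h = z,
                          newton_tol = 1e-13)
    expect_equal(s$x_next, (1 - z / 2) / (1 + z / 2), tolerance = 1e-12)
  }
})

test_that("both implicit methods are A-stable on the linear test equation", {
  # trapezoidal amplification |(1 - z/2)/(1 + z/2)| <= 1 for all z > 0
  for (z in 10^seq(-1, 3, length.out = 9)) {
    s <- step_trapezoidal(function(t, x) -x, x = 1, t = 0, h = z,
                          newton_tol = 1e-13)
    expect_lte(abs(s$x_next), 1)
  }
  # BDF2 recurrence contracts over many steps for any z > 0
  for (z in c(0.5, 5, 50, 500)) {
    xp <- 1; x <- 1
    for (i in 1:100) {
      s <- step_gear2(function(t, x) -x, xp, x, t = 0, h = z, h_prev = z,
                      newton_tol = 1e-13)
      xp <- x; x <- s$x_next
    }
    expect_lt(abs(x), 1e-10)
  }
})

test_that("observed convergence order is 2 for both methods on a smooth nonlinear problem", {
  rhs <- function(t, x) x * (1 - x) # logistic, closed form known
  exact <- function(t, x0 = 0.1) 1 / (1 + exp(-t) * (1 / x0 - 1))
  hs <- 2^-(2:6)
  err_tr <- err_g2 <- numeric(0)
  for (h in hs) {
    n <- round(4 / h)
    x <- 0.1; t <- 0
    for (i in seq_len(n)) {
      s <- step_trapezoidal(rhs, x, t, h, newton_tol = 1e-12)
      x <- s$x_next; t <- t + h
    }
    err_tr <- c(err_tr, abs(x - exact(4)))
    xp <- exact(-h); x <- 0.1; t <- 0
    for (i in seq_len(n)) {
      s <- step_gear2(rhs, xp, x, t, h, newton_tol = 1e-12)
      xp <- x; x <- s$x_next; t <- t + h
    }
    err_g2 <- c(err_g2, abs(x - exact(4)))
  }
  slope_tr <- unname(coef(lm(log(err_tr) ~ log(hs)))[2])
  slope_g2 <- unname(coef(lm(log(err_g2) ~ log(hs)))[2])
  expect_lt(abs(slope_tr - 2), 0.2)
  expect_lt(abs(slope_g2 - 2), 0.2)
})

test_that("the analytic Jacobian matches examples and finite differences", {
  s <- decay_fixture(k = 0.7)$scheme
  expect_equal(kin_jacobian(s, 1), matrix(-0.7, 1, 1))
  da <- diels_alder_fixture()$scheme
  k <- constant_values(da)
  J <- kin_jacobian(da, c(1, 1, 0))
  expect_equal(J[1, 1], -k[["k1"]]) # d(d[A]/dt)/d[A] at [B] = 1
  expect_equal(J[1, 3], k[["k2"]])
  set.seed(5)
  for (seed in 1:5) {
    rs <- random_scheme(4, 8, rng_seed = seed)
    rhs <- compile_rhs(rs)
    x <- runif(4, 0.1, 1.5)
    Ja <- kin_jacobian(rs, x)
    Jf <- pracma::jacobian(function(z) rhs(0, z), x) # independent FD oracle
    expect_lt(max(abs(Ja - Jf)), 1e-6)
  }
})

test_that("halving reltol monotonically reduces the error against a tight reference", {
  fixtures <- list(reversible_pair_fixture(), decay_fixture())
  for (fx in fixtures) {
    tt <- fx$options$total_time; ps <- fx$options$print_step
    ref <- run_scheme(fx$scheme, tt, ps, reltol = 1e-9)
    errs <- vapply(c(1e-2, 1e-3, 1e-4), function(rt) {
      sup_rel_error(run_scheme(fx$scheme, tt, ps, reltol = rt)$states,
                    ref$states)
    }, numeric(1))
    expect_true(all(diff(errs) < 0))
  }
})

test_that("the implicit solver crosses a 1e6 rate-scale separation in few accepted steps", {
  s <- random_scheme(4, 10, rate_scale_range = c(1, 1e6), rng_seed = 7,
                     closed = TRUE)
  tr <- run_scheme(s, 10, 0.1, reltol = 1e-6)
  expect_lt(tr$stats$accepted, 1e4)
  # an explicit method at its stability-limited step would need > 1e6 steps
  lam_max <- max(abs(Re(eigen(kin_jacobian(s, s$species))$values)))
  expect_gt(10 / (2.8 / lam_max), 1e6)
})

test_that("linear conservation laws hold along trajectories of closed schemes", {
  for (seed in c(2, 4, 6)) {
    s <- random_scheme(4, 10, rng_seed = seed, closed = TRUE)
    W <- left_null_space(attr(s, "stoichiometry"))
    expect_gt(ncol(W), 0L)
    rt <- 1e-6
    tr <- run_scheme(s, 5, 0.05, reltol = rt)
    q <- tr$states %*% W
    drift <- max(abs(sweep(q, 2, q[1, ], "-"))) / max(abs(q[1, ]), 1e-12)
    expect_lt(drift, 10 * rt)
  }
})

test_that("pure gear2 mode integrates accurately from a backward-Euler seed", {
  tr <- nsm_integrate(decay_fixture()$scheme,
                      sim_options(1, 0.1, reltol = 1e-6, method = "gear2"))
  expect_lt(abs(final_state(tr)[["A"]] - exp(-1)), 1e-4)
})

test_that("print grid interpolation covers [0, total_time] exactly", {
  tr <- run_scheme(decay_fixture()$scheme, 1, 0.3, reltol = 1e-6)
  expect_equal(tr$times[1], 0)
  expect_equal(tail(tr$times, 1), 1)
  expect_false(anyNA(tr$states))
})

test_that("non-finite dynamics raise a state blow-up error", {
  rhs <- function(t, x) if (t > 0.5) rep(NaN, length(x)) else -x
  expect_error(
    nsm_integrate(rhs, sim_options(1, 0.1), x0 = 1),
    "blow-up|stiffness failure")
  # finite-time blow-up: dx/dt = x^2 from 1 escapes at t = 1
  expect_error(
    nsm_integrate(function(t, x) x^2, sim_options(2, 0.1), x0 = 1),
    "blow-up|stiffness failure")
})

test_that("the native integrator agrees with an established stiff solver on the cycloaddition", {
  fx <- diels_alder_fixture()
  tr <- run_scheme(fx$scheme, 1e7, 1e5, reltol = 1e-8)
  rhs <- compile_rhs(fx$scheme)
  ref <- deSolve::lsoda(
    y = fx$scheme$species, times = tr$times,
    func = function(t, y, p) list(rhs(t, y)),
    rtol = 1e-10, atol = 1e-14)
  expect_lt(sup_rel_error(tr$states, ref[, -1]), 1e-6)
})

test_that("option validation enforces the documented invariants", {
  expect_error(sim_options(0, 0.1), "total_time")
  expect_error(sim_options(1, 2), "print_step")
  expect_error(sim_options(1, 0.1, reltol = 0.5), "reltol")
  expect_error(sim_options(1, 0.1, min_step = 1, initial_step = 0.5),
               "min_step")
})
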