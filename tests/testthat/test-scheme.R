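# Scheme data model: Eyring rates, reactions, validation.

test_that("Eyring rates reproduce the frequency factor and the cycloaddition barriers", {
  # zero barrier: exponential factor is 1, so k = k_B T / h
  expect_equal(eyring_rate(0, 298.15), 6.2124e12, tolerance = 1e-4)
  # the two printed free-energy barriers of the cycloaddition profile,
  # evaluated independently from k = (k_B T / h) exp(-dG/(R T))
  kB <- 1.380649e-23; h <- 6.62607015e-34; R <- 8.31446261815324
  direct <- function(dG, T) kB * T / h * exp(-dG / (R * T))
  expect_equal(eyring_rate(113110.8, 298.15), direct(113110.8, 298.15),
               tolerance = 1e-12)
  expect_equal(eyring_rate(113110.8, 298.15), 9.4865e-8, tolerance = 1e-4)
  expect_equal(eyring_rate(248626.4, 298.15), 1.7211e-31, tolerance = 1e-4)
})

test_that("Eyring rate is monotone in barrier and temperature and rejects bad input", {
  barriers <- seq(0, 3e5, length.out = 40)
  for (T in c(100, 298.15, 1000)) {
    k <- eyring_rate(barriers, T)
    expect_true(all(diff(k) < 0))
  }
  temps <- seq(150, 1200, length.out = 40)
  k <- vapply(temps, function(T) eyring_rate(5e4, T), numeric(1))
  expect_true(all(diff(k) > 0))
  expect_error(eyring_rate(1e4, 0), "temperature")
  expect_error(eyring_rate(1e4, -5), "temperature")
  expect_error(eyring_rate(Inf, 300), "finite")
  expect_message(eyring_rate(-1e3, 300), "negative")
})

test_that("barrier-derived rate constants satisfy the Eyring identity", {
  rc <- rate_constant("kf", barrier = 113110.8, temperature = 298.15)
  expect_identical(rc$origin, "barrier")
  expect_equal(rc$value, eyring_rate(113110.8, 298.15), tolerance = 1e-12)
  expect_error(rate_constant("kf", barrier = 1e4), "temperature")
  expect_error(rate_constant("kf", value = -1), "positive")
  expect_error(rate_constant("bad name", value = 1), "invalid")
})

test_that("expand_reaction produces the mass-action equations of a reversible step", {
  rx <- reaction(c(A = 1, B = 1), c(C = 1), kf = "k1", kr = "k2")
  eqs <- expand_reaction(rx)
  scheme <- kinetic_scheme(c(A = 1, B = 1, C = 0), c(k1 = 2, k2 = 3),
                           unname(eqs))
  # d[A]/dt = -k1[A][B] + k2[C]; d[C]/dt = +k1[A][B] - k2[C]
  x <- c(A = 0.7, B = 0.4, C = 0.2)
  rhs <- oracle_rhs(scheme, x)
  expect_equal(rhs[["A"]], -2 * 0.7 * 0.4 + 3 * 0.2)
  expect_equal(rhs[["B"]], rhs[["A"]])
  expect_equal(rhs[["C"]], -rhs[["A"]])
})

test_that("expand_reaction handles irreversible and stoichiometric cases", {
  eqs <- expand_reaction(reaction(c(A = 1), c(B = 1), kf = "k"))
  expect_length(eqs$A$terms, 1L)
  expect_equal(eqs$A$terms[[1]]$sign, -1)
  expect_equal(eqs$B$terms[[1]]$sign, +1)
  # 2X -> Y: d[X]/dt = -2k[X]^2, d[Y]/dt = +k[X]^2
  eqs2 <- expand_reaction(reaction(c(X = 2), c(Y = 1), kf = "k"))
  tX <- eqs2$X$terms[[1]]
  expect_equal(tX$coef, 2)
  expect_equal(unname(tX$factors["X"]), 2)
  expect_equal(eqs2$Y$terms[[1]]$coef, 1)
})

test_that("one-step expansion conserves stoichiometry: rhs proportional to (-a, +b)", {
  set.seed(11)
  for (i in 1:20) {
    nr <- sample(1:2, 1); np <- sample(1:2, 1)
    sp <- paste0("S", 1:(nr + np))
    a <- setNames(sample(1:2, nr, replace = TRUE), sp[1:nr])
    b <- setNames(sample(1:2, np, replace = TRUE), sp[nr + 1:np])
    rx <- reaction(a, b, kf = "k")
    scheme <- kinetic_scheme(setNames(runif(nr + np, 0.1, 1), sp),
                             c(k = runif(1, 0.5, 2)),
                             unname(expand_reaction(rx)))
    x <- setNames(runif(nr + np, 0.1, 1), sp)
    rhs <- oracle_rhs(scheme, x)
    expected_dir <- c(-a, b)[sp]
    rate <- rhs / expected_dir
    expect_equal(max(rate) / min(rate), 1, tolerance = 1e-12)
  }
})

test_that("scheme validation rejects inconsistent definitions", {
  eq <- function(s) rate_equation(s, rate_term("k", setNames(1, s), sign = -1))
  expect_error(kinetic_scheme(c(A = 1, A = 2), c(k = 1), list(eq("A"))),
               "duplicate species")
  expect_error(kinetic_scheme(c(A = -1), c(k = 1), list(eq("A"))),
               ">= 0")
  expect_error(kinetic_scheme(c(A = 1), c(A = 1), list(eq("A"))),
               "shared")
  expect_error(kinetic_scheme(c(A = 1), c(k = 1), list(eq("A"), eq("A"))),
               "more than one equation")
  expect_error(kinetic_scheme(c(A = 1, B = 1), c(k = 1), list(eq("A"))),
               "missing equation.*B")
  expect_error(kinetic_scheme(c(A = 1), c(k = 1), list(eq("B"))),
               "unknown species")
  expect_error(
    kinetic_scheme(c(A = 1), c(k = 1),
                   list(rate_equation("A", rate_term("nope", c(A = 1))))),
    "unknown rate constant 'nope'")
  expect_error(
    kinetic_scheme(c(A = 1), c(k = 1),
                   list(rate_equation("A", rate_term("k", c(B = 1))))),
    "unknown species 'B'")
})
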