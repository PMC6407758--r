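# NSM network construction, KCL equivalence, rhs compilation and the SPICE
# netlist round trip.

test_that("the cycloaddition network has one capacitor/resistor per species and one source per term", {
  s <- diels_alder_fixture()$scheme
  net <- build_network(s)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$capacitors), 3L)
  expect_equal(nrow(net$resistors), 3L)
  expect_length(net$sources, 6L) # 2 addends x 3 equations
  expect_true(all(net$capacitors$capacitance == 1))
  expect_equal(net$capacitors$ic, unname(s$species))
})

test_that("the peroxidase-oxidase network carries one source per rate term (14, counted from the term list)", {
  s <- do.call(olsen_fixture, olsen_example_parameters())$scheme
  expect_equal(n_terms(s), 14L) # 3 + 3 + 5 + 3 expanded mass-action addends
  net <- build_network(s)
  expect_equal(nrow(net$nodes), 4L)
  expect_length(net$sources, n_terms(s))
})

test_that("Kirchhoff's current law at every node reproduces the rate equations term-for-term", {
  fixtures <- list(
    diels_alder_fixture()$scheme,
    do.call(olsen_fixture, olsen_example_parameters())$scheme,
    do.call(chapman_fixture, chapman_example_parameters())$scheme,
    oscillator_fixture(m = 1, b = 0.5, k = 4)$scheme,
    decay_fixture()$scheme,
    decay_chain_fixture()$scheme,
    reversible_pair_fixture()$scheme
  )
  for (s in fixtures) {
    expect_identical(kcl_terms(build_network(s)), canonical_terms(s))
  }
  for (seed in 1:5) {
    s <- random_scheme(4, 10, rng_seed = seed)
    expect_identical(kcl_terms(build_network(s)), canonical_terms(s))
  }
})

test_that("compiled rhs agrees with term-by-term evaluation at random states", {
  set.seed(99)
  for (seed in 1:5) {
    s <- random_scheme(sample(2:5, 1), sample(4:12, 1), rng_seed = seed)
    rhs <- compile_rhs(s)
    n <- length(s$species)
    for (i in 1:20) {
      x <- runif(n, 0, 2)
      a <- rhs(0, x)
      b <- oracle_rhs(s, x)
      expect_equal(a, unname(b), tolerance = 1e-14)
    }
  }
})

test_that("rhs vanishes at the all-zero state when no zeroth-order term exists", {
  s <- random_scheme(4, 10, rng_seed = 3)
  expect_equal(compile_rhs(s)(0, rep(0, 4)), rep(0, 4))
})

test_that("a single-species decay scheme exports exactly one C, one G, one R card", {
  s <- decay_fixture(k = 0.5)$scheme
  cir <- export_cir(s, sim_options(total_time = 10, print_step = 0.1))
  lines <- strsplit(cir, "\n")[[1]]
  expect_length(grep("^C_", lines), 1L)
  expect_length(grep("^G_", lines), 1L)
  expect_length(grep("^R_", lines), 1L)
  expect_length(grep("^\\.TRAN ", lines), 1L)
  expect_identical(tail(lines, 1), ".END")
})

test_that("netlist export is deterministic and round-trips through parse_cir", {
  fixtures <- list(diels_alder_fixture()$scheme,
                   do.call(olsen_fixture, olsen_example_parameters())$scheme,
                   decay_chain_fixture()$scheme)
  opt <- sim_options(total_time = 100, print_step = 1, reltol = 1e-4,
                     numdgt = 8L)
  for (s in fixtures) {
    net <- build_network(s)
    cir <- export_cir(net, opt)
    expect_identical(cir, export_cir(net, opt)) # byte-identical
    net2 <- parse_cir(cir)
    expect_equal(nrow(net2$nodes), length(s$species))
    expect_length(net2$sources, n_terms(s))
    expect_identical(net2$nodes$species, names(s$species))
    # reconstructed model encodes the same dynamics
    r1 <- compile_rhs(s)
    r2 <- compile_rhs(net2)
    for (i in 1:10) {
      x <- runif(length(s$species), 0, 1.5)
      expect_equal(r2(0, x), r1(0, x), tolerance = 1e-12)
    }
    # options cards round-trip
    expect_equal(net2$options$reltol, opt$reltol)
    expect_equal(net2$options$total_time, opt$total_time)
    expect_equal(net2$options$numdgt, opt$numdgt)
    expect_equal(setNames(net2$capacitors$ic, net2$nodes$species),
                 s$species)
  }
})

test_that("parse_cir rejects empty netlists and unsupported elements with line numbers", {
  expect_error(parse_cir(""), "no capacitor")
  expect_error(parse_cir("* title only\n.END\n"), "no capacitor")
  bad <- "* t\nC_A N_A 0 1 IC=1\nL1 N_A 0 1e-3\n.END\n"
  expect_error(parse_cir(bad), "line 3: unsupported element")
  bad2 <- "* t\nC_A N_A 0 1 IC=1\n.AC DEC 10 1 1e6\n.END\n"
  expect_error(parse_cir(bad2), "line 3: unsupported control card")
})

test_that("the continuity resistor does not perturb the chemistry", {
  fx <- diels_alder_fixture()
  net <- build_network(fx$scheme)
  opt <- sim_options(1e7, 1e5, reltol = 1e-9)
  bare <- nsm_integrate(net, opt, include_resistors = FALSE)
  leaky <- nsm_integrate(net, opt, include_resistors = TRUE)
  expect_lt(sup_rel_error(leaky$states, bare$states), 1e-6)
})

test_that("mangled-name collisions are rejected", {
  s <- kinetic_scheme(
    c(a = 1, A = 1), c(k = 1),
    list(rate_equation("a", rate_term("k", c(a = 1), sign = -1)),
         rate_equation("A", rate_term("k", c(A = 1), sign = -1))))
  expect_error(build_network(s), "collide")
})
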