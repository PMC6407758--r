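# The NSM equivalent electrical network. One node per species whose voltage
# is the concentration (1 mol/l == 1 V); a unit capacitor per node so the
# capacitor current equals d[x]/dt; one voltage-controlled current source per
# rate term injecting sign*coef*k*prod(V^alpha); and one high-value resistor
# per node to ground for continuity. Kirchhoff's current law at each node is
# then exactly the species' rate equation.

# Continuity resistor: "high value", inert w.r.t. the kinetics. The leak
# current integrates to ~ T/R in concentration units along conserved
# directions, so a 1e7-s horizon needs R >> 1e13 ohm to stay below 1e-6.
.nk_default_resistance <- 1e15

#' Build the NSM network model of a kinetic scheme
#'
#' @param scheme A [kinetic_scheme()].
#' @param resistance Continuity resistor value per node, ohm.
#' @return An object of class `nsm_network` with components `nodes`
#'   (species/node table), `capacitors` (unit capacitance, initial-condition
#'   voltage), `sources` (one per rate term, carrying the term structure),
#'   and `resistors`.
#' @examples
#' build_network(decay_fixture()$scheme)
#' @export
build_network <- function(scheme, resistance = .nk_default_resistance) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  sp <- names(scheme$species)
  node <- paste0("N_", toupper(sp))
  if (anyDuplicated(node)) {
    stop("species names collide after netlist mangling (upper-casing): ",
         paste(sp[duplicated(node) | duplicated(node, fromLast = TRUE)],
               collapse = ", "), call. = FALSE)
  }
  nodes <- data.frame(species = sp, node = node, stringsAsFactors = FALSE)
  capacitors <- data.frame(
    name = paste0("C_", toupper(sp)), node = node, capacitance = 1,
    ic = as.numeric(scheme$species), stringsAsFactors = FALSE
  )
  kval <- constant_values(scheme)
  sources <- list()
  for (i in seq_along(sp)) {
    eq <- scheme$equations[[sp[i]]]
    for (j in seq_along(eq$terms)) {
      term <- eq$terms[[j]]
      sources[[length(sources) + 1L]] <- list(
        name = sprintf("G_%s_%d", toupper(sp[i]), j),
        node = node[i], species = sp[i],
        sign = term$sign, coef = term$coef, constant = term$constant,
        value = unname(kval[[term$constant]]), factors = term$factors
      )
    }
  }
  resistors <- data.frame(
    name = paste0("R_", toupper(sp)), node = node,
    resistance = resistance, stringsAsFactors = FALSE
  )
  structure(
    list(nodes = nodes, capacitors = capacitors, sources = sources,
         resistors = resistors, scheme_name = scheme$name,
         options = NULL),
    class = "nsm_network"
  )
}

#' @export
print.nsm_network <- function(x, ...) {
  cat(sprintf(
    "NSM network%s: %d nodes, %d capacitors, %d current sources, %d resistors\n",
    if (is.null(x$scheme_name)) "" else paste0(" '", x$scheme_name, "'"),
    nrow(x$nodes), nrow(x$capacitors), length(x$sources), nrow(x$resistors)))
  invisible(x)
}

#' Kirchhoff-current-law balance of a network, per species
#'
#' Reassembles, from the current sources alone, the canonical term multiset
#' that the network injects into each node. By construction of the analogy
#' this must equal [canonical_terms()] of the originating scheme
#' (capacitor current = sum of source currents at every node).
#'
#' @param network An `nsm_network`.
#' @return Named list (per species) of sorted term-signature strings.
#' @export
kcl_terms <- function(network) {
  stopifnot(inherits(network, "nsm_network"))
  out <- setNames(vector("list", nrow(network$nodes)), network$nodes$species)
  for (s in network$sources) {
    sig <- paste0(ifelse(s$sign < 0, "-", "+"),
                  format(s$coef, digits = 15), "*", s$constant,
                  if (length(s$factors)) {
                    paste0("*", paste0(names(s$factors), "^",
                                       format(s$factors, digits = 15),
                                       collapse = "*"))
                  } else "")
    out[[s$species]] <- c(out[[s$species]], sig)
  }
  lapply(out, function(v) sort(v %||% character(0)))
}

# ---- right-hand-side compilation -------------------------------------------

# Flatten terms into the C-level table: w (signed multiplier), target
# (0-based species index), E (terms x species exponent matrix).
.nk_term_table <- function(terms_by_species, species_names, kval = NULL) {
  n <- length(species_names)
  m <- sum(vapply(terms_by_species, length, integer(1)))
  w <- numeric(m)
  target <- integer(m)
  E <- matrix(0, nrow = m, ncol = n, dimnames = list(NULL, species_names))
  t <- 0L
  for (i in seq_along(species_names)) {
    for (term in terms_by_species[[i]]) {
      t <- t + 1L
      kv <- if (is.null(term$value)) kval[[term$constant]] else term$value
      w[t] <- term$sign * term$coef * kv
      target[t] <- i - 1L
      if (length(term$factors)) {
        E[t, names(term$factors)] <- term$factors
      }
    }
  }
  list(w = w, target = target, E = E, species = species_names)
}

.nk_rhs_from_table <- function(tab) {
  force(tab)
  f <- function(t, x) nk_rhs(x, tab$w, tab$target, tab$E)
  attr(f, "jacobian") <- function(t, x) nk_jac(x, tab$w, tab$target, tab$E)
  attr(f, "table") <- tab
  attr(f, "species") <- tab$species
  f
}

#' Compile the mass-action right-hand side of a scheme or network
#'
#' Returns a pure evaluator `f(t, x)` of the signed sum of mass-action terms
#' (the state vector `x` is ordered as the species list). The evaluator
#' carries an analytic Jacobian in its `"jacobian"` attribute, exact for the
#' polynomial rate law.
#'
#' @param x A [kinetic_scheme()] or an `nsm_network`.
#' @param ... Passed to methods.
#' @return A function `f(t, x) -> dx/dt` with attributes `"jacobian"` and
#'   `"species"`.
#' @export
compile_rhs <- function(x, ...) UseMethod("compile_rhs")

#' @rdname compile_rhs
#' @export
compile_rhs.kinetic_scheme <- function(x, ...) {
  tab <- .nk_term_table(lapply(x$equations, `[[`, "terms"), names(x$species),
                        constant_values(x))
  .nk_rhs_from_table(tab)
}

#' @rdname compile_rhs
#' @param include_resistors For the network method: when `TRUE` the leak
#'   current of the continuity resistors (`-V/R` per node) is included in the
#'   compiled derivative; with the default 1e12-ohm resistors this
#'   perturbation is far below solver tolerances.
#' @export
compile_rhs.nsm_network <- function(x, include_resistors = FALSE, ...) {
  sp <- x$nodes$species
  terms_by_species <- setNames(vector("list", length(sp)), sp)
  for (s in x$sources) {
    terms_by_species[[s$species]] <- c(
      terms_by_species[[s$species]],
      list(list(sign = s$sign, coef = s$coef, constant = s$constant,
                value = s$value, factors = s$factors)))
  }
  if (include_resistors) {
    for (i in seq_along(sp)) {
      g <- 1 / x$resistors$resistance[i]
      if (is.finite(g) && g > 0) {
        terms_by_species[[sp[i]]] <- c(
          terms_by_species[[sp[i]]],
          list(list(sign = -1, coef = 1, constant = "Gleak", value = g,
                    factors = setNames(1, sp[i]))))
      }
    }
  }
  tab <- .nk_term_table(terms_by_species, sp)
  .nk_rhs_from_table(tab)
}

#' Initial state of a scheme or network
#'
#' @param x A [kinetic_scheme()] or `nsm_network`.
#' @return Named numeric vector of initial concentrations (node voltages).
#' @export
initial_state <- function(x) {
  if (inherits(x, "kinetic_scheme")) return(x$species)
  if (inherits(x, "nsm_network")) {
    return(setNames(x$capacitors$ic, x$nodes$species))
  }
  stop("`x` must be a kinetic_scheme or nsm_network", call. = FALSE)
}
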