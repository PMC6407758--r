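# Data model for kinetic schemes: species with initial concentrations, rate
# constants (direct or barrier-derived), and one signed sum of mass-action
# terms per species.

.nk_name_re <- "^[A-Za-z][A-Za-z0-9_]*$"

.nk_check_name <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(sprintf("%s name must be a non-empty string", what), call. = FALSE)
  }
  if (!grepl(.nk_name_re, x)) {
    stop(sprintf(
      "%s name '%s' is invalid: use a letter followed by letters, digits or '_' (no whitespace or netlist-reserved characters)",
      what, x), call. = FALSE)
  }
  x
}

#' Define a rate constant
#'
#' A rate constant is either given directly (`value`) or derived from a
#' free-energy barrier at a stated temperature via [eyring_rate()]. Units are
#' implied by the rate term the constant multiplies (s^-1 for unimolecular
#' terms, l mol^-1 s^-1 for bimolecular terms, ...).
#'
#' @param name Identifier (letter followed by letters/digits/underscores).
#' @param value Positive rate constant value. Ignored when `barrier` is given.
#' @param barrier Free-energy barrier, J/mol. If supplied, the value is
#'   computed with the Eyring equation and `temperature` is required.
#' @param temperature Absolute temperature in K (required with `barrier`).
#' @return An object of class `nk_rate_constant`.
#' @examples
#' rate_constant("k1", barrier = 113110.8, temperature = 298.15)
#' rate_constant("kf", value = 2.5e-3)
#' @export
rate_constant <- function(name, value = NULL, barrier = NULL,
                          temperature = NULL) {
  .nk_check_name(name, "rate constant")
  if (!is.null(barrier)) {
    if (is.null(temperature)) {
      stop("a barrier-derived rate constant requires `temperature`",
           call. = FALSE)
    }
    value <- eyring_rate(barrier, temperature)
    origin <- "barrier"
  } else {
    if (is.null(value)) stop("supply `value` or `barrier`", call. = FALSE)
    origin <- "direct"
    barrier <- NA_real_
    temperature <- NA_real_
  }
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value <= 0) {
    stop(sprintf("rate constant '%s' must have a positive finite value", name),
         call. = FALSE)
  }
  structure(
    list(name = name, value = as.numeric(value), origin = origin,
         barrier = as.numeric(barrier), temperature = as.numeric(temperature)),
    class = "nk_rate_constant"
  )
}

#' @export
print.nk_rate_constant <- function(x, ...) {
  if (x$origin == "barrier") {
    cat(sprintf("%s = %.6g  (Eyring: %.6g J/mol at %.6g K)\n",
                x$name, x$value, x$barrier, x$temperature))
  } else {
    cat(sprintf("%s = %.6g\n", x$name, x$value))
  }
  invisible(x)
}

#' Define one mass-action rate term
#'
#' One addend `sign * coef * k * prod_j [x_j]^alpha_j` of a species' rate
#' equation. `factors` may be empty for zeroth-order terms (constant feeds
#' whose reservoir concentration has been folded into the constant).
#'
#' @param constant Name of the rate constant the term references.
#' @param factors Named numeric vector of positive exponents; names are
#'   species. Empty for zeroth-order terms.
#' @param sign `+1` (production) or `-1` (consumption).
#' @param coef Positive stoichiometric multiplier (e.g. the 2 in
#'   `2 k [X]^2`). Defaults to 1.
#' @return An object of class `nk_term`.
#' @export
rate_term <- function(constant, factors = numeric(0), sign = 1, coef = 1) {
  .nk_check_name(constant, "rate constant")
  if (!sign %in% c(-1, 1)) stop("`sign` must be +1 or -1", call. = FALSE)
  if (!is.numeric(coef) || length(coef) != 1L || !is.finite(coef) || coef <= 0) {
    stop("`coef` must be a positive number", call. = FALSE)
  }
  factors <- unlist(factors)
  if (length(factors)) {
    if (is.null(names(factors)) || any(!nzchar(names(factors)))) {
      stop("`factors` must be a named vector of exponents", call. = FALSE)
    }
    if (anyDuplicated(names(factors))) {
      stop("duplicate species in `factors`", call. = FALSE)
    }
    if (any(!is.finite(factors)) || any(factors <= 0)) {
      stop("factor exponents must be positive", call. = FALSE)
    }
    factors <- factors[order(names(factors))]
  } else {
    factors <- setNames(numeric(0), character(0))
  }
  structure(list(sign = as.numeric(sign), coef = as.numeric(coef),
                 constant = constant, factors = factors),
            class = "nk_term")
}

#' Define the rate equation of one species
#'
#' @param species Species name (the left-hand side `d[species]/dt`).
#' @param terms List of [rate_term()] objects; may be empty (constant
#'   species).
#' @return An object of class `nk_equation`.
#' @export
rate_equation <- function(species, terms = list()) {
  .nk_check_name(species, "species")
  if (inherits(terms, "nk_term")) terms <- list(terms)
  if (!all(vapply(terms, inherits, logical(1), "nk_term"))) {
    stop("`terms` must be a list of rate_term() objects", call. = FALSE)
  }
  structure(list(species = species, terms = terms), class = "nk_equation")
}

.nk_format_term <- function(term, lead = FALSE) {
  sgn <- if (term$sign < 0) "-" else if (lead) "" else "+"
  coef <- if (term$coef != 1) paste0(format(term$coef, digits = 15), "*") else ""
  fac <- if (length(term$factors)) {
    paste0("*", paste0(names(term$factors),
                       ifelse(term$factors != 1,
                              paste0("^", format(term$factors, digits = 15)), "")),
           collapse = "")
  } else ""
  paste0(sgn, coef, term$constant, fac)
}

.nk_format_equation <- function(eq) {
  if (!length(eq$terms)) return(sprintf("d[%s]/dt = 0", eq$species))
  parts <- vapply(seq_along(eq$terms), function(i) {
    .nk_format_term(eq$terms[[i]], lead = i == 1L)
  }, character(1))
  sprintf("d[%s]/dt = %s", eq$species, paste(parts, collapse = " "))
}

#' @export
print.nk_equation <- function(x, ...) {
  cat(.nk_format_equation(x), "\n")
  invisible(x)
}

#' Assemble and validate a kinetic scheme
#'
#' A kinetic scheme holds the species list with initial concentrations
#' (mol/l), the rate constants, and exactly one mass-action rate equation
#' per species. All cross-references are validated; species and constant
#' names must be unique and disjoint.
#'
#' @param species Named numeric vector: initial concentration (mol/l, >= 0)
#'   per species name.
#' @param constants List of [rate_constant()] objects, or a named numeric
#'   vector of direct values.
#' @param equations List of [rate_equation()] objects, one per species (any
#'   order).
#' @param name Optional free-form scheme name.
#' @return An object of class `kinetic_scheme`.
#' @examples
#' s <- kinetic_scheme(
#'   species = c(A = 1, B = 0),
#'   constants = c(k = 0.5),
#'   equations = list(
#'     rate_equation("A", rate_term("k", c(A = 1), sign = -1)),
#'     rate_equation("B", rate_term("k", c(A = 1), sign = +1))
#'   ),
#'   name = "decay"
#' )
#' print(s)
#' @export
kinetic_scheme <- function(species, constants, equations, name = NULL) {
  if (!is.numeric(species) || is.null(names(species)) || !length(species)) {
    stop("`species` must be a named numeric vector of initial concentrations",
         call. = FALSE)
  }
  for (nm in names(species)) .nk_check_name(nm, "species")
  if (anyDuplicated(names(species))) {
    stop("duplicate species name: ",
         paste(unique(names(species)[duplicated(names(species))]),
               collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(species)) || any(species < 0)) {
    stop("initial concentrations must be finite and >= 0", call. = FALSE)
  }
  if (is.numeric(constants)) {
    constants <- lapply(names(constants), function(nm) {
      rate_constant(nm, value = constants[[nm]])
    })
  }
  if (!all(vapply(constants, inherits, logical(1), "nk_rate_constant"))) {
    stop("`constants` must be rate_constant() objects or a named numeric vector",
         call. = FALSE)
  }
  knames <- vapply(constants, `[[`, character(1), "name")
  if (anyDuplicated(knames)) {
    stop("duplicate rate constant name: ",
         paste(unique(knames[duplicated(knames)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(knames %in% names(species))) {
    stop("names shared between species and rate constants: ",
         paste(intersect(knames, names(species)), collapse = ", "),
         call. = FALSE)
  }
  names(constants) <- knames
  if (inherits(equations, "nk_equation")) equations <- list(equations)
  if (!all(vapply(equations, inherits, logical(1), "nk_equation"))) {
    stop("`equations` must be a list of rate_equation() objects", call. = FALSE)
  }
  eq_species <- vapply(equations, `[[`, character(1), "species")
  if (anyDuplicated(eq_species)) {
    stop("more than one equation for species: ",
         paste(unique(eq_species[duplicated(eq_species)]), collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(eq_species, names(species))
  if (length(unknown)) {
    stop("equation given for unknown species: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing_eq <- setdiff(names(species), eq_species)
  if (length(missing_eq)) {
    stop("missing equation for species: ",
         paste(missing_eq, collapse = ", "), call. = FALSE)
  }
  equations <- equations[match(names(species), eq_species)]
  names(equations) <- names(species)
  for (eq in equations) {
    for (term in eq$terms) {
      if (!term$constant %in% knames) {
        stop(sprintf("equation for '%s' references unknown rate constant '%s'",
                     eq$species, term$constant), call. = FALSE)
      }
      bad <- setdiff(names(term$factors), names(species))
      if (length(bad)) {
        stop(sprintf("equation for '%s' references unknown species '%s'",
                     eq$species, paste(bad, collapse = "', '")), call. = FALSE)
      }
    }
  }
  structure(
    list(species = species, constants = constants, equations = equations,
         name = name),
    class = "kinetic_scheme"
  )
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("Kinetic scheme%s: %d species, %d rate constants, %d terms\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              length(x$species), length(x$constants), n_terms(x)))
  cat("Initial concentrations (mol/l):\n")
  for (nm in names(x$species)) cat(sprintf("  [%s]0 = %g\n", nm, x$species[[nm]]))
  cat("Rate constants:\n")
  for (k in x$constants) {
    cat("  "); print(k)
  }
  cat("Equations:\n")
  for (eq in x$equations) cat(" ", .nk_format_equation(eq), "\n")
  invisible(x)
}

#' Number of rate terms in a scheme
#'
#' @param scheme A [kinetic_scheme()].
#' @return Integer: total number of mass-action addends across all equations.
#' @export
n_terms <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  sum(vapply(scheme$equations, function(eq) length(eq$terms), integer(1)))
}

#' Rate constant values of a scheme
#'
#' @param scheme A [kinetic_scheme()].
#' @return Named numeric vector of rate-constant values.
#' @export
constant_values <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  vapply(scheme$constants, `[[`, numeric(1), "value")
}

# Canonical multiset of term signatures per species. Signature carries the
# signed multiplier, constant name and sorted factor list; used to compare a
# scheme's equations with the KCL balance of its network term-for-term.
.nk_canonical_terms <- function(equations) {
  lapply(equations, function(eq) {
    sigs <- vapply(eq$terms, function(term) {
      paste0(ifelse(term$sign < 0, "-", "+"),
             format(term$coef, digits = 15), "*", term$constant,
             if (length(term$factors)) {
               paste0("*", paste0(names(term$factors), "^",
                                  format(term$factors, digits = 15),
                                  collapse = "*"))
             } else "")
    }, character(1))
    sort(sigs)
  })
}

#' Canonical term signatures of a kinetic scheme
#'
#' Returns, per species, the sorted multiset of term signatures
#' (`sign coef * constant * factors`). Two schemes are term-for-term equal
#' iff their canonical terms are identical; this is the symbolic form used
#' to check Kirchhoff's-current-law equivalence of the network model.
#'
#' @param scheme A [kinetic_scheme()].
#' @return Named list (per species) of sorted character vectors.
#' @export
canonical_terms <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  .nk_canonical_terms(scheme$equations)
}
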