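# One-step balanced reactions and their expansion into mass-action rate
# equations. For sum(a_i R_i) <-> sum(b_j P_j) every species of the step
# carries the same renormalised flow (extent per unit time), so the ODE
# right-hand sides are the single scalar rate scaled by -a_i / +b_j.

#' Define a one-step balanced reaction
#'
#' @param reactants Named integer vector of stoichiometric coefficients
#'   `a_i` (positive).
#' @param products Named integer vector of coefficients `b_j` (positive).
#'   Reactant and product sets must be disjoint.
#' @param kf Name of the forward rate constant.
#' @param kr Name of the reverse rate constant, or `NULL` for an
#'   irreversible step.
#' @return An object of class `nk_reaction`.
#' @examples
#' reaction(c(A = 1, B = 1), c(C = 1), kf = "k1", kr = "k2")
#' @export
reaction <- function(reactants, products, kf, kr = NULL) {
  check_side <- function(x, what) {
    x <- unlist(x)
    if (!length(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
      stop(sprintf("`%s` must be a named coefficient vector", what),
           call. = FALSE)
    }
    for (nm in names(x)) .nk_check_name(nm, "species")
    if (anyDuplicated(names(x))) {
      stop(sprintf("duplicate species in `%s`", what), call. = FALSE)
    }
    if (any(x != round(x)) || any(x < 1)) {
      stop(sprintf("`%s` coefficients must be positive integers", what),
           call. = FALSE)
    }
    x
  }
  reactants <- check_side(reactants, "reactants")
  products <- check_side(products, "products")
  overlap <- intersect(names(reactants), names(products))
  if (length(overlap)) {
    stop("reactant and product sets must be disjoint; shared: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  .nk_check_name(kf, "rate constant")
  if (!is.null(kr)) .nk_check_name(kr, "rate constant")
  structure(list(reactants = reactants, products = products, kf = kf, kr = kr),
            class = "nk_reaction")
}

#' @export
print.nk_reaction <- function(x, ...) {
  side <- function(v) paste(ifelse(v > 1, paste0(v, " "), ""), names(v),
                            sep = "", collapse = " + ")
  arrow <- if (is.null(x$kr)) sprintf("--%s-->", x$kf) else
    sprintf("<--%s/%s-->", x$kr, x$kf)
  cat(side(x$reactants), arrow, side(x$products), "\n")
  invisible(x)
}

#' Expand a reaction into mass-action rate equations
#'
#' Applies the mass-action law to a one-step reaction: for reactant `R_i`
#' with coefficient `a_i`, `d[R_i]/dt = -a_i kf prod([R]^a) + a_i kr
#' prod([P]^b)`, and symmetrically for products. Reverse terms are omitted
#' for irreversible steps.
#'
#' @param x An [reaction()] object.
#' @return Named list of [rate_equation()] objects, one per involved
#'   species.
#' @examples
#' expand_reaction(reaction(c(A = 1, B = 1), c(C = 1), kf = "k1", kr = "k2"))
#' @export
expand_reaction <- function(x) {
  stopifnot(inherits(x, "nk_reaction"))
  fwd_factors <- as.numeric(x$reactants)
  names(fwd_factors) <- names(x$reactants)
  rev_factors <- as.numeric(x$products)
  names(rev_factors) <- names(x$products)
  eqs <- list()
  for (nm in names(x$reactants)) {
    a <- x$reactants[[nm]]
    terms <- list(rate_term(x$kf, fwd_factors, sign = -1, coef = a))
    if (!is.null(x$kr)) {
      terms <- c(terms, list(rate_term(x$kr, rev_factors, sign = +1, coef = a)))
    }
    eqs[[nm]] <- rate_equation(nm, terms)
  }
  for (nm in names(x$products)) {
    b <- x$products[[nm]]
    terms <- list(rate_term(x$kf, fwd_factors, sign = +1, coef = b))
    if (!is.null(x$kr)) {
      terms <- c(terms, list(rate_term(x$kr, rev_factors, sign = -1, coef = b)))
    }
    eqs[[nm]] <- rate_equation(nm, terms)
  }
  eqs
}

#' Build a kinetic scheme from a set of reactions
#'
#' Expands each reaction by [expand_reaction()] and merges the resulting
#' terms per species. Species not taking part in any reaction get an empty
#' (constant) equation.
#'
#' @param reactions List of [reaction()] objects.
#' @param species Named numeric vector of initial concentrations covering at
#'   least every species appearing in `reactions`.
#' @param constants Rate constants (as for [kinetic_scheme()]).
#' @param name Optional scheme name.
#' @return A [kinetic_scheme()].
#' @export
scheme_from_reactions <- function(reactions, species, constants, name = NULL) {
  if (inherits(reactions, "nk_reaction")) reactions <- list(reactions)
  term_bag <- setNames(vector("list", length(species)), names(species))
  for (rx in reactions) {
    eqs <- expand_reaction(rx)
    for (nm in names(eqs)) {
      if (!nm %in% names(species)) {
        stop(sprintf("reaction references species '%s' missing from `species`",
                     nm), call. = FALSE)
      }
      term_bag[[nm]] <- c(term_bag[[nm]], eqs[[nm]]$terms)
    }
  }
  equations <- lapply(names(species), function(nm) {
    rate_equation(nm, term_bag[[nm]] %||% list())
  })
  kinetic_scheme(species, constants, equations, name = name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
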