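# Synthetic random mass-action schemes for property tests: built from
# randomly drawn one-step reactions (mass-action exponents 1 or 2), so
# trajectories from non-negative initial states stay non-negative and, in
# the closed variant, total concentration is conserved (left null vector of
# the stoichiometry = all-ones).

.nk_with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a random mass-action kinetic scheme
#'
#' Reactions are drawn from a pool of uni- and bimolecular templates until
#' at least `n_terms` rate terms have accumulated; rate constants are
#' log-uniform over `rate_scale_range` (a wide range generates stiffness:
#' the two extreme constants are pinned to the range endpoints). With
#' `closed = TRUE` only templates preserving the total number of molecules
#' are used, so the all-ones vector is a conserved left null vector of the
#' stoichiometry.
#'
#' @param n_species Number of species (>= 2 so reactions exist).
#' @param n_terms Minimum total number of rate terms.
#' @param rate_scale_range Length-2 positive range for the log-uniform rate
#'   constants.
#' @param rng_seed Integer seed; the same seed reproduces the same scheme.
#' @param closed Restrict to molecule-count-preserving reactions.
#' @return A [kinetic_scheme()] with attributes `"stoichiometry"` (species
#'   x reactions matrix) and `"reactions"`.
#' @export
random_scheme <- function(n_species, n_terms = 2 * n_species,
                          rate_scale_range = c(0.1, 10), rng_seed = 1L,
                          closed = FALSE) {
  stopifnot(n_species >= 1, n_terms >= 1, length(rate_scale_range) == 2,
            all(rate_scale_range > 0))
  .nk_with_seed(rng_seed, {
    sp <- paste0("S", seq_len(n_species))
    pick <- function(n) sample(sp, n)
    # each template: (arity needed, closed?, generator of reactant/product sides)
    templates <- list(
      list(2L, TRUE, function() { s <- pick(2); list(setNames(1, s[1]), setNames(1, s[2])) }),
      list(2L, TRUE, function() { s <- pick(2); list(setNames(2, s[1]), setNames(2, s[2])) }),
      list(3L, TRUE, function() { s <- pick(3); list(setNames(2, s[1]), setNames(c(1, 1), s[2:3])) }),
      list(4L, TRUE, function() { s <- pick(4); list(setNames(c(1, 1), s[1:2]), setNames(c(1, 1), s[3:4])) }),
      list(3L, FALSE, function() { s <- pick(3); list(setNames(c(1, 1), s[1:2]), setNames(1, s[3])) }),
      list(3L, FALSE, function() { s <- pick(3); list(setNames(1, s[1]), setNames(c(1, 1), s[2:3])) }),
      list(2L, FALSE, function() { s <- pick(2); list(setNames(2, s[1]), setNames(1, s[2])) })
    )
    if (closed) templates <- Filter(function(tp) tp[[2]], templates)
    templates <- Filter(function(tp) tp[[1]] <= n_species, templates)
    if (!length(templates)) {
      stop("n_species too small to draw any reaction (need >= 2)", call. = FALSE)
    }
    reactions <- list()
    total_terms <- 0L
    while (total_terms < n_terms && length(reactions) < 1000L) {
      tp <- templates[[sample(seq_along(templates), 1L)]]
      sides <- tp[[3]]()
      rx <- reaction(sides[[1]], sides[[2]],
                     kf = sprintf("k%d", length(reactions) + 1L))
      reactions[[length(reactions) + 1L]] <- rx
      total_terms <- total_terms + length(rx$reactants) + length(rx$products)
    }
    lo <- log(rate_scale_range[1]); hi <- log(rate_scale_range[2])
    kv <- exp(stats::runif(length(reactions), lo, hi))
    if (length(kv) >= 2 && rate_scale_range[2] > rate_scale_range[1]) {
      kv[1] <- rate_scale_range[1] # pin the extremes: stiffness by construction
      kv[2] <- rate_scale_range[2]
    }
    constants <- setNames(kv, sprintf("k%d", seq_along(reactions)))
    species0 <- setNames(stats::runif(n_species, 0.2, 2), sp)
    scheme <- scheme_from_reactions(reactions, species0, constants,
                                    name = sprintf("random scheme (seed %d)",
                                                   rng_seed))
    N <- matrix(0, n_species, length(reactions),
                dimnames = list(sp, names(constants)))
    for (j in seq_along(reactions)) {
      rx <- reactions[[j]]
      N[names(rx$reactants), j] <- N[names(rx$reactants), j] - rx$reactants
      N[names(rx$products), j] <- N[names(rx$products), j] + rx$products
    }
    attr(scheme, "stoichiometry") <- N
    attr(scheme, "reactions") <- reactions
    scheme
  })
}
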