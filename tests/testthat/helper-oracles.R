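# Independent oracles used across the suite. These deliberately avoid the
# package's compiled evaluation path.

# Pure-R term-by-term evaluation of a scheme's right-hand side.
oracle_rhs <- function(scheme, x) {
  kv <- constant_values(scheme)
  sp <- names(scheme$species)
  names(x) <- sp
  vapply(sp, function(nm) {
    s <- 0
    for (term in scheme$equations[[nm]]$terms) {
      p <- term$sign * term$coef * kv[[term$constant]]
      for (j in seq_along(term$factors)) {
        p <- p * x[[names(term$factors)[j]]]^term$factors[[j]]
      }
      s <- s + p
    }
    s
  }, numeric(1))
}

# Error relative to each species' own trajectory magnitude (sup norm).
sup_rel_error <- function(states, ref_states) {
  num <- abs(states - ref_states)
  den <- apply(abs(ref_states), 2, max)
  den[den == 0] <- 1
  max(sweep(num, 2, den, "/"))
}

# Basis of the left null space of a stoichiometry matrix, via SVD.
left_null_space <- function(N, tol = 1e-10) {
  sv <- svd(N, nu = nrow(N))
  r <- sum(sv$d > tol * max(sv$d, 1))
  if (r == nrow(N)) return(matrix(0, nrow(N), 0))
  sv$u[, seq.int(r + 1, nrow(N)), drop = FALSE]
}

# Closed forms
decay_chain_exact <- function(t, k1, k2, a0 = 1) {
  A <- a0 * exp(-k1 * t)
  B <- a0 * k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t))
  cbind(A = A, B = B, C = a0 - A - B)
}

reversible_pair_exact <- function(t, kf, kr, a0 = 1, b0 = 0) {
  tot <- a0 + b0
  Aeq <- tot * kr / (kf + kr)
  A <- Aeq + (a0 - Aeq) * exp(-(kf + kr) * t)
  cbind(A = A, B = tot - A)
}

underdamped_exact <- function(t, m, b, k, x0 = 1, v0 = 0) {
  g <- b / (2 * m)
  w <- sqrt(k / m - g^2)
  x <- exp(-g * t) * (x0 * cos(w * t) + ((v0 + g * x0) / w) * sin(w * t))
  v <- exp(-g * t) * (v0 * cos(w * t) -
                        (x0 * (g^2 + w^2) + g * v0) / w * sin(w * t))
  cbind(x = x, v = v)
}

run_scheme <- function(scheme, total_time, print_step, reltol = 1e-6, ...) {
  nsm_integrate(scheme, sim_options(total_time = total_time,
                                    print_step = print_step,
                                    reltol = reltol, ...))
}
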