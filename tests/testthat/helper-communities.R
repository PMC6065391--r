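# Shared generators and oracles. All randomness is driven by the caller's
# seed (tests set a seed before using these).

# Random feasible competitive system: uniform C (condition-capped), uniform
# densities, rates by inverse design so the densities are the equilibrium.
random_competitive_system <- function(N_R, N_S = N_R, epsilon = 0.5,
                                      cond_max = 1e6) {
  repeat {
    C <- matrix(stats::runif(N_R * N_S), N_R, N_S)
    if (kappa(C, exact = TRUE) < cond_max) break
  }
  R_star <- stats::runif(N_R, 0.1, 1)
  S_star <- stats::runif(N_S, 0.1, 1)
  rt <- rates_from_densities(C, R_star, S_star, epsilon)
  list(comm = community(C, rho = rt$rho, mu = rt$mu, epsilon = epsilon),
       R_star = R_star, S_star = S_star)
}

# Central finite-difference Jacobian of the crossfeeding RHS: the
# independent oracle for the analytic block assembly.
fd_jacobian <- function(comm, R, S, h = 1e-6) {
  x0 <- c(R, S)
  n <- length(x0)
  f <- function(x) {
    d <- crossfeeding_rhs(comm, x[seq_along(R)], x[-seq_along(R)])
    c(d$dR, d$dS)
  }
  J <- matrix(0, n, n)
  for (k in seq_len(n)) {
    e <- numeric(n); e[k] <- h
    J[, k] <- (f(x0 + e) - f(x0 - e)) / (2 * h)
  }
  J
}

# Multiset comparison for complex spectra: sort on rounded keys so machine
# noise in ties cannot scramble the pairing.
sort_spectrum <- function(z, digits = 8) {
  z <- as.complex(z)
  z[order(round(Re(z), digits), round(Im(z), digits))]
}

# Equal-angle Gram matrix: unit diagonal, common off-diagonal cosine a.
equal_angle_gram <- function(a, n) {
  G <- matrix(a, n, n)
  diag(G) <- 1
  G
}
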