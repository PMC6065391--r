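test_that("identity community has the unit equilibrium", {
  comm <- community(diag(3), rho = rep(1, 3), mu = rep(1, 3), epsilon = 1)
  eq <- competitive_equilibrium(comm)
  expect_equal(eq$R_star, rep(1, 3))
  expect_equal(eq$S_star, rep(1, 3))
  expect_true(eq$feasible)
  expect_lt(eq$residual, 1e-12)
})

test_that("a triangular system reproduces the direct linear-solve oracle", {
  C <- matrix(c(1, 0, 0.5, 0.5), 2)  # columns (1,0), (0.5,0.5)
  comm <- community(C, rho = c(1, 1), mu = c(1, 1), epsilon = 1)
  eq <- competitive_equilibrium(comm)
  # independent oracle: solve the two linear systems from the definitions
  R_oracle <- solve(t(C)) %*% c(1, 1)
  S_oracle <- solve(diag(as.numeric(R_oracle)) %*% C) %*% c(1, 1)
  expect_equal(eq$R_star, as.numeric(R_oracle))
  expect_equal(eq$S_star, as.numeric(S_oracle))
  expect_equal(eq$R_star, c(1, 1))     # (C^T)^{-1} mu with this C
  expect_equal(eq$S_star, c(0, 2))     # boundary: one consumer at zero
  expect_false(eq$feasible)
})

test_that("inverse design then forward solve is the identity (round trip)", {
  set.seed(21)
  for (rep in 1:100) {
    N <- sample(2:30, 1)
    # moderate condition numbers so the 1e-8 tolerance reflects the
    # round-trip identity, not amplification through the two solves
    sys <- random_competitive_system(N, cond_max = 1e4)
    eq <- competitive_equilibrium(sys$comm)
    expect_equal(eq$R_star, sys$R_star, tolerance = 1e-8)
    expect_equal(eq$S_star, sys$S_star, tolerance = 1e-8)
    expect_true(eq$feasible)
  }
})

test_that("with no production any positive densities give positive rates", {
  set.seed(22)
  for (rep in 1:50) {
    N <- sample(2:20, 1)
    C <- matrix(runif(N * N), N)
    rt <- rates_from_densities(C, runif(N, 1e-3, 10), runif(N, 1e-3, 10),
                               epsilon = runif(1, 0.05, 2))
    expect_true(all(rt$mu > 0))
    expect_true(all(rt$rho > 0))
    expect_true(rt$feasible_rates)
  }
})

test_that("crossfeeding equilibrium reduces to competition when P = 0", {
  set.seed(23)
  sys <- random_competitive_system(5)
  eq1 <- competitive_equilibrium(sys$comm)
  eq2 <- crossfeeding_equilibrium(sys$comm)
  expect_equal(eq1$R_star, eq2$R_star)
  expect_equal(eq1$S_star, eq2$S_star)
})

test_that("crossfeeding equilibrium is self-consistent on random feasible systems", {
  set.seed(24)
  for (rep in 1:20) {
    N <- 4
    C <- matrix(runif(N * N, 0.2, 1), N)
    P <- matrix(runif(N * N, 0, 0.05), N)
    R_star <- runif(N, 0.5, 1); S_star <- runif(N, 0.5, 1)
    rt <- rates_from_densities(C, R_star, S_star, epsilon = 1, P = P)
    if (!rt$feasible_rates) next
    comm <- community(C, rho = rt$rho, mu = rt$mu, epsilon = 1, P = P)
    eq <- crossfeeding_equilibrium(comm)
    expect_equal(eq$R_star, R_star, tolerance = 1e-8)
    expect_equal(eq$S_star, S_star, tolerance = 1e-8)
    d <- crossfeeding_rhs(comm, eq$R_star, eq$S_star)
    expect_lt(max(abs(c(d$dR, d$dS))), 1e-10)
  }
})

test_that("specialist rate design matches hand arithmetic and round-trips", {
  sc <- specialist_community(c = 1, s = 1, r = 1,
                             P = matrix(c(0, 0.4, 0.4, 0), 2), epsilon = 1)
  rt <- specialist_rates(sc)
  expect_equal(rt$mu, c(0.6, 0.6))
  expect_equal(rt$rho, c(0.6, 0.6))
  eq <- crossfeeding_equilibrium(as_community(sc))
  expect_equal(eq$R_star, rep(1, 2), tolerance = 1e-12)
  expect_equal(eq$S_star, rep(1, 2), tolerance = 1e-12)
})

test_that("infeasible target densities with production warn, not silently pass", {
  P <- matrix(c(0, 2, 2, 0), 2)  # production outweighs consumption income
  expect_warning(
    rt <- rates_from_densities(diag(2), c(1, 1), c(1, 1), epsilon = 1, P = P),
    "not all positive")
  expect_false(rt$feasible_rates)
})

test_that("specialist feasibility constraints flag the right rows/columns", {
  # P = 0: both constraints hold for any positive parameters
  sc0 <- specialist_community(c = 2, s = 0.3, r = 0.7,
                              P = matrix(0, 3, 3), epsilon = 0.4)
  expect_true(specialist_feasibility(sc0)$ok)
  # entry 1.2 pushes row 1 over the influx bound and column 2 over the
  # mortality bound (both use c r = c r epsilon = 1 here)
  P <- matrix(0, 2, 2); P[1, 2] <- 1.2
  fz <- specialist_feasibility(specialist_community(1, 1, 1, P, 1))
  expect_equal(fz$violating_resources, 1L)
  expect_equal(fz$violating_consumers, 2L)
  # epsilon = 0.5: column sums 0.6 > 0.5 fail (A), row sums 0.6 < 1 pass (B)
  P2 <- matrix(c(0, 0.6, 0.6, 0), 2)
  fz2 <- specialist_feasibility(specialist_community(1, 1, 1, P2, 0.5))
  expect_false(any(fz2$consumer_ok))
  expect_true(all(fz2$resource_ok))
})

test_that("singular or ill-conditioned consumption matrices are refused", {
  C <- matrix(1, 3, 3)
  expect_error(
    competitive_equilibrium(community(C, rep(1, 3), rep(1, 3), 1)),
    "condition number")
  expect_error(rates_from_densities(diag(2), c(1, -1), c(1, 1), 1),
               "positive")
})
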