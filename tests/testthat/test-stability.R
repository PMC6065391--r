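test_that("the one-species Jacobian matches direct substitution", {
  comm <- community(matrix(1), rho = 1, mu = 1, epsilon = 1)
  J <- community_jacobian(comm, R = 1, S = 1)
  expect_equal(unname(J), matrix(c(-1, 1, -1, 0), 2))
})

test_that("analytic Jacobian matches finite differences, with production and leaching", {
  set.seed(31)
  for (rep in 1:8) {
    N <- 5
    comm <- community(matrix(runif(N * N), N), rho = runif(N, 0.5, 1),
                      mu = runif(N, 0.5, 1), epsilon = runif(1, 0.2, 1),
                      P = matrix(runif(N * N, 0, 0.2), N),
                      eta = runif(N, 0, 0.3))
    R <- runif(N, 0.2, 1); S <- runif(N, 0.2, 1)
    J <- community_jacobian(comm, R, S)
    Jfd <- fd_jacobian(comm, R, S)
    expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-5)
  }
})

test_that("the specialist Jacobian has the closed block form", {
  set.seed(32)
  N <- 4; c0 <- 1.5; s0 <- 0.4; r0 <- 0.8; eps <- 0.7
  P <- matrix(runif(N * N, 0, 0.1), N)
  sc <- specialist_community(c0, s0, r0, P, eps)
  J <- community_jacobian(as_community(sc), rep(r0, N), rep(s0, N))
  expected <- rbind(cbind(diag(-c0 * s0, N), P - diag(c0 * r0, N)),
                    cbind(diag(eps * c0 * s0, N), matrix(0, N, N)))
  expect_equal(unname(J), expected, tolerance = 1e-12)
})

test_that("spectra report sorted eigenvalues and a tolerance-aware verdict", {
  sp <- jacobian_spectrum(matrix(c(-1, 1, -1, 0), 2))
  expect_equal(sort_spectrum(sp$eigenvalues),
               sort_spectrum(c(complex(real = -0.5, imaginary = -sqrt(3) / 2),
                               complex(real = -0.5, imaginary = sqrt(3) / 2))))
  expect_equal(sp$max_real, -0.5)
  expect_true(sp$stable)
  sp2 <- jacobian_spectrum(diag(c(-1, -2)))
  expect_equal(Re(sp2$eigenvalues), c(-1, -2))  # descending real part
  sp3 <- jacobian_spectrum(diag(c(-1, 1e-12)))
  expect_false(sp3$stable)
  expect_true(sp3$marginal)
})

test_that("random feasible competitive systems are always locally stable", {
  set.seed(33)
  for (rep in 1:25) {
    N <- sample(2:30, 1)
    sys <- random_competitive_system(N)
    sp <- jacobian_spectrum(
      community_jacobian(sys$comm, sys$R_star, sys$S_star))
    expect_lt(sp$max_real, 0)
  }
})

test_that("specialist lambda mapping reproduces the full Jacobian spectrum", {
  # P = 0 collapses every gamma to 0: lambda = -1/2 +/- (sqrt(3)/2) i
  sc0 <- specialist_community(c = 1, s = 1, r = 1, P = matrix(0, 3, 3),
                              epsilon = 1)
  gl0 <- specialist_lambdas(sc0)
  expect_equal(sort(unique(round(Re(gl0$lambdas), 10))), -0.5)
  expect_equal(sort(unique(round(abs(Im(gl0$lambdas)), 10))), sqrt(3) / 2)
  # random symmetric P within the Gershgorin bound: stable, and the union
  # over gamma equals the full-Jacobian eigen oracle
  set.seed(34)
  for (rep in 1:10) {
    N <- 6
    P <- matrix(runif(N * N, 0, 0.25 / N), N); P <- (P + t(P)) / 2
    sc <- specialist_community(c = 1, s = runif(1, 0.2, 1),
                               r = runif(1, 0.5, 1), P = P,
                               epsilon = runif(1, 0.3, 1.5))
    gl <- specialist_lambdas(sc)
    expect_true(all(Re(gl$lambdas) < 0))
    J <- community_jacobian(as_community(sc), rep(sc$r, N), rep(sc$s, N))
    full <- eigen(J, only.values = TRUE)$values
    expect_lt(max(Mod(sort_spectrum(gl$lambdas) - sort_spectrum(full))), 1e-8)
  }
})

test_that("a production eigenvalue equal to cr gives a marginal zero root", {
  sc <- specialist_community(c = 1, s = 1, r = 0.5, P = diag(0.5, 3),
                             epsilon = 1)
  gl <- specialist_lambdas(sc)   # gamma = cr = 0.5 exactly, thrice
  expect_equal(max(Re(gl$lambdas)), 0)
})

test_that("the per-gamma condition is equivalent to both roots being stable", {
  # real gamma below/above cr
  sc <- specialist_community(c = 1, s = 1, r = 1, P = matrix(0, 2, 2),
                             epsilon = 1)
  expect_true(gamma_condition(0.5 + 0i, sc))
  expect_false(gamma_condition(1.5 + 0i, sc))
  set.seed(35)
  for (rep in 1:1000) {
    sc <- specialist_community(c = runif(1, 0.2, 2), s = runif(1, 0.1, 1),
                               r = runif(1, 0.1, 1),
                               P = matrix(0, 2, 2),
                               epsilon = runif(1, 0.2, 3))
    gam <- complex(real = runif(1, -1, 2), imaginary = runif(1, -1, 1))
    cs <- sc$c * sc$s; cr <- sc$c * sc$r
    disc <- sqrt(as.complex(cs^2 - 4 * sc$epsilon * cs * (cr - gam)))
    roots <- c(-cs + disc, -cs - disc) / 2
    expect_identical(gamma_condition(gam, sc), all(Re(roots) < 0))
  }
})

test_that("the sufficient production bound behaves as sufficient, not necessary", {
  # P = 0: passes iff cr > cs/(4 epsilon)
  sc_pass <- specialist_community(1, 1, 1, matrix(0, 2, 2), epsilon = 1)
  expect_true(production_bound(sc_pass)$sufficient)   # 1 > 0.25
  sc_fail <- specialist_community(1, 1, 0.2, matrix(0, 2, 2), epsilon = 1)
  expect_false(production_bound(sc_fail)$sufficient)  # 0.2 < 0.25
  # hand arithmetic: 0.4^2 = 0.16 < 1 * (1 - 0 - 0.25) = 0.75
  sc <- specialist_community(1, 1, 1, matrix(c(0, 0.4, 0.4, 0), 2), 1)
  bd <- production_bound(sc)
  expect_equal(bd$lhs, c(0.16, 0.16))
  expect_equal(bd$rhs, c(0.75, 0.75))
  expect_true(bd$sufficient)
  # a system that fails the bound yet is stable (bound only sufficient)
  set.seed(3)
  P <- matrix(runif(36, 0, 0.3), 6)
  sc2 <- specialist_community(c = 1, s = 0.1, r = 1, P = P, epsilon = 2)
  expect_true(specialist_feasibility(sc2)$ok)
  expect_false(production_bound(sc2)$sufficient)
  expect_true(all(Re(specialist_lambdas(sc2)$lambdas) < 0))
})

test_that("Gershgorin reciprocity criterion requires symmetry and row sums below cr", {
  sc0 <- specialist_community(1, 1, 1, matrix(0, 3, 3), 1)
  expect_true(gershgorin_symmetric_check(sc0))
  P <- matrix(c(0, 0.55, 0.55, 0), 2)  # row sums 0.55 < cr = 1
  expect_true(gershgorin_symmetric_check(specialist_community(1, 1, 1, P, 1)))
  Pbig <- matrix(c(0.55, 0.55, 0.55, 0.55), 2)  # row sums 1.1 > 1
  expect_false(gershgorin_symmetric_check(specialist_community(1, 1, 1, Pbig, 1)))
  Pasym <- matrix(c(0, 0.3, 0.1, 0), 2)
  expect_error(
    gershgorin_symmetric_check(specialist_community(1, 1, 1, Pasym, 1)),
    "not symmetric")
})

test_that("symmetric production within the Gershgorin bound is always stable", {
  set.seed(36)
  for (rep in 1:50) {
    N <- sample(3:12, 1)
    P <- matrix(runif(N * N, 0, 1.8 / N), N); P <- (P + t(P)) / 2
    sc <- specialist_community(c = 1, s = runif(1, 0.1, 1), r = 1, P = P,
                               epsilon = runif(1, 0.2, 2))
    if (!isTRUE(tryCatch(gershgorin_symmetric_check(sc),
                         error = function(e) FALSE))) next
    if (!specialist_feasibility(sc)$ok) next
    J <- community_jacobian(as_community(sc), rep(1, N), rep(sc$s, N))
    expect_lt(jacobian_spectrum(J)$max_real, 0)
  }
})

test_that("invasion fitness is zero for residents and predicts invasion dynamics", {
  set.seed(37)
  sys <- random_competitive_system(3)
  eq <- competitive_equilibrium(sys$comm)
  for (j in 1:3)
    expect_equal(invasion_fitness(sys$comm, eq$R_star, j), 0,
                 tolerance = 1e-12)
  # residents 1-2 at equilibrium on three resources; invader is consumer 3
  Cm <- matrix(runif(6, 0.2, 1), 3, 2)
  R_star <- runif(3, 0.5, 1); Sm <- runif(2, 0.5, 1)
  rt <- rates_from_densities(Cm, R_star, Sm, epsilon = 1)
  c3 <- runif(3, 0.2, 1)
  base_mu3 <- sum(c3 * R_star)   # epsilon (C^T R*)_3 with epsilon = 1
  for (fac in c(1.1, 0.9)) {
    C <- cbind(Cm, c3)
    comm <- community(C, rho = rt$rho, mu = c(rt$mu, fac * base_mu3),
                      epsilon = 1)
    fit <- invasion_fitness(comm, R_star, 3)
    if (fac > 1) expect_lt(fit, 0) else expect_gt(fit, 0)
    # Jacobian at the boundary equilibrium carries the fitness on its
    # bottom-right diagonal
    J <- community_jacobian(comm, R_star, c(Sm, 0))
    expect_equal(J[6, 6], fit)
    # simulation oracle: a rare invader decays or grows with sign(fit)
    tr <- simulate_community(comm, R_star, c(Sm, 1e-3),
                             times = seq(0, 5, length.out = 21))
    s3 <- tr$S[, 3]
    if (fac > 1) expect_lt(s3[21], 1e-3) else expect_gt(s3[21], 1e-3)
  }
})

test_that("rank condition reports rank deficits and rectangular shapes", {
  expect_true(rank_condition(diag(3))$holds)
  C <- cbind(c(1, 2, 3), c(1, 2, 3), c(0, 1, 0))
  rc <- rank_condition(C)
  expect_equal(rc$rank, 2)
  expect_false(rc$holds)
  set.seed(38)
  expect_true(rank_condition(matrix(runif(12), 4, 3))$holds)
})

test_that("the Hermitian certificate is positive definite on stable systems", {
  expect_true(hermitian_certificate(diag(1), 1, 1, 1, 0 + 0i))
  set.seed(39)
  for (rep in 1:30) {
    N <- sample(2:10, 1)
    sys <- random_competitive_system(N)
    lam <- complex(real = runif(1, 0, 10), imaginary = runif(1, -5, 5))
    expect_true(hermitian_certificate(sys$comm$C, sys$R_star, sys$S_star,
                                      sys$comm$epsilon, lam))
  }
  # duplicate-column C breaks invertibility and with it the certificate
  C <- matrix(runif(16), 4); C[, 2] <- C[, 1]
  expect_false(hermitian_certificate(C, runif(4, 0.5, 1), runif(4, 0.5, 1),
                                     1, 0.5 + 0i))
  # negative real part is outside the certificate's domain
  expect_error(hermitian_certificate(diag(1), 1, 1, 1, -1 + 0i), "Re")
  # lambda colliding with the resource-block spectrum is a precondition error
  expect_error(
    hermitian_certificate(diag(2), c(1, 1), c(1e-13, 1e-13), 1, 0 + 0i),
    "collides")
})
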