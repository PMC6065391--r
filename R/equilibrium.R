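## Forward equilibrium solving and inverse rate design.

cond_limit <- 1e12  # condition number beyond which C is treated as singular

check_square_invertible <- function(C, what = "C") {
  if (nrow(C) != ncol(C))
    stop("forward equilibrium solving requires a square ", what,
         " (got ", nrow(C), " x ", ncol(C), ")")
  kap <- kappa(C, exact = TRUE)
  if (!is.finite(kap) || kap > cond_limit)
    stop(what, " is singular or ill-conditioned (condition number ",
         format(kap, digits = 3), " > ", format(cond_limit), ")")
  invisible(kap)
}

new_equilibrium <- function(R_star, S_star, residual, comm) {
  structure(
    list(R_star = as.numeric(R_star), S_star = as.numeric(S_star),
         feasible = all(R_star > 0) && all(S_star > 0),
         residual = residual, community = comm),
    class = "community_equilibrium"
  )
}

#' Equilibrium of the competitive consumer-resource model
#'
#' Solves the interior equilibrium in closed form:
#' \deqn{R^* = (C^T)^{-1} \mu / \epsilon, \quad
#'       S^* = [\mathrm{diag}(R^*) C]^{-1} \rho.}
#' Requires a square, well-conditioned `C` and `P = 0`. The equilibrium is
#' feasible when all entries of both vectors are strictly positive.
#'
#' @param comm a [community()] object with all-zero production matrix.
#' @return An object of class `"community_equilibrium"` with fields
#'   `R_star`, `S_star`, `feasible` and `residual` (max |RHS| at the
#'   solution).
#' @examples
#' comm <- community(diag(3), rho = rep(1, 3), mu = rep(1, 3), epsilon = 1)
#' competitive_equilibrium(comm)
#' @export
competitive_equilibrium <- function(comm) {
  stopifnot(inherits(comm, "community"))
  if (any(comm$P > 0))
    stop("community has nonzero production; use crossfeeding_equilibrium()")
  check_square_invertible(comm$C)
  R_star <- solve(t(comm$C), comm$mu / comm$epsilon)
  if (any(R_star == 0))
    stop("degenerate equilibrium: some R*_i is exactly zero, S* undefined")
  S_star <- solve(as.numeric(R_star) * comm$C, comm$rho)
  d <- competition_rhs(comm, R_star, S_star)
  new_equilibrium(R_star, S_star, max(abs(c(d$dR, d$dS))), comm)
}

#' Equilibrium of the crossfeeding consumer-producer-resource model
#'
#' Closed-form interior equilibrium with production:
#' \deqn{R^* = (C^T)^{-1} (P^T 1 + \mu)/\epsilon, \quad
#'       S^* = [\mathrm{diag}(R^*) C - P]^{-1} \rho.}
#' Reduces to [competitive_equilibrium()] when `P = 0`.
#'
#' @param comm a [community()] object (square `C`).
#' @return A `"community_equilibrium"`; `residual` is measured under the
#'   crossfeeding dynamics.
#' @export
crossfeeding_equilibrium <- function(comm) {
  stopifnot(inherits(comm, "community"))
  check_square_invertible(comm$C)
  R_star <- solve(t(comm$C), (unname(colSums(comm$P)) + comm$mu) / comm$epsilon)
  if (any(R_star == 0))
    stop("degenerate equilibrium: some R*_i is exactly zero, S* undefined")
  A <- as.numeric(R_star) * comm$C - comm$P
  kap <- kappa(A, exact = TRUE)
  if (!is.finite(kap) || kap > cond_limit)
    stop("[diag(R*) C - P] is singular or ill-conditioned (condition number ",
         format(kap, digits = 3), ")")
  S_star <- solve(A, comm$rho)
  d <- crossfeeding_rhs(comm, R_star, S_star)
  new_equilibrium(R_star, S_star, max(abs(c(d$dR, d$dS))), comm)
}

#' @export
print.community_equilibrium <- function(x, ...) {
  cat(sprintf("community equilibrium (%s, residual %.2e)\n",
              if (x$feasible) "feasible" else "INFEASIBLE", x$residual))
  cat("  R*: ", paste(sprintf("%.4g", x$R_star), collapse = " "), "\n")
  cat("  S*: ", paste(sprintf("%.4g", x$S_star), collapse = " "), "\n")
  invisible(x)
}

#' Design influx and mortality rates for target equilibrium densities
#'
#' Inverse problem: given a consumption matrix and any strictly positive
#' target densities, returns rates that make those densities an interior
#' equilibrium:
#' \deqn{\mu = \epsilon C^T R^* - P^T 1, \quad
#'       \rho = \mathrm{diag}(R^*) C S^* - P S^*.}
#' With `P = 0`, both rate vectors are guaranteed strictly positive for any
#' positive densities and any nonnegative `C` with no zero row/column in the
#' relevant products — every feasible point can be an equilibrium. With
#' `P != 0` positivity is checked and reported via a warning, not
#' guaranteed. Rectangular `C` (`N_R >= N_S`) is supported.
#'
#' @param C nonnegative consumption matrix (`N_R x N_S`).
#' @param R_star,S_star strictly positive target densities.
#' @param epsilon positive conversion efficiency.
#' @param P optional nonnegative production matrix (default zero).
#' @return A list with `rho`, `mu` and logical `feasible_rates` (both vectors
#'   strictly positive).
#' @examples
#' rates_from_densities(diag(2), R_star = c(1, 1), S_star = c(1, 1), epsilon = 1)
#' @export
rates_from_densities <- function(C, R_star, S_star, epsilon, P = NULL) {
  C <- as.matrix(C)
  if (any(R_star <= 0) || any(S_star <= 0))
    stop("target densities must be strictly positive")
  if (length(R_star) != nrow(C) || length(S_star) != ncol(C))
    stop("density lengths must match dim(C)")
  if (is.null(P)) P <- matrix(0, nrow(C), ncol(C))
  P <- as.matrix(P)
  if (!identical(dim(P), dim(C))) stop("'P' must have the same shape as 'C'")
  mu <- epsilon * as.vector(crossprod(C, R_star)) - colSums(P)
  rho <- as.vector((as.numeric(R_star) * C) %*% S_star) -
    as.vector(P %*% S_star)
  feasible <- all(mu > 0) && all(rho > 0)
  if (!feasible)
    warning("designed rates are not all positive: the requested densities ",
            "are not attainable as a feasible equilibrium at this P")
  list(rho = rho, mu = mu, feasible_rates = feasible)
}

#' Build a community whose equilibrium sits at given densities
#'
#' Convenience wrapper around [rates_from_densities()] returning a full
#' [community()] object.
#'
#' @inheritParams rates_from_densities
#' @param eta optional leaching vector; when nonzero, the influx is raised by
#'   `eta * R_star` so the target densities remain the equilibrium.
#' @return A `"community"` whose interior equilibrium is `(R_star, S_star)`.
#' @export
design_community <- function(C, R_star, S_star, epsilon, P = NULL, eta = NULL) {
  r <- rates_from_densities(C, R_star, S_star, epsilon, P)
  rho <- r$rho
  if (!is.null(eta)) rho <- rho + eta * R_star
  community(C = C, rho = rho, mu = r$mu, epsilon = epsilon, P = P, eta = eta)
}
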