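#' Right-hand side of the competitive consumer-resource dynamics
#'
#' Evaluates the time derivatives of resource densities and consumer
#' abundances under pure competition for substitutable abiotic resources
#' (the production matrix is ignored):
#' \deqn{dR_i/dt = \rho_i - \eta_i R_i - R_i \sum_j C_{ij} S_j}
#' \deqn{dS_i/dt = \epsilon S_i \sum_j C^T_{ij} R_j - \mu_i S_i}
#'
#' @param comm a [community()] object.
#' @param R resource density vector (length `N_R`).
#' @param S consumer abundance vector (length `N_S`).
#' @return A list with components `dR` and `dS`.
#' @examples
#' comm <- community(C = matrix(1), rho = 1, mu = 1, epsilon = 1)
#' competition_rhs(comm, R = 1, S = 1)  # equilibrium: both zero
#' @export
competition_rhs <- function(comm, R, S) {
  check_state(comm, R, S)
  dR <- comm$rho - comm$eta * R - R * as.vector(comm$C %*% S)
  dS <- comm$epsilon * S * as.vector(crossprod(comm$C, R)) - comm$mu * S
  list(dR = dR, dS = dS)
}

#' Right-hand side of the crossfeeding consumer-producer-resource dynamics
#'
#' As [competition_rhs()], plus production of resources by consumers at rates
#' `P` and the corresponding biomass cost to each consumer (the column sum of
#' `P`), which carries no efficiency factor and no resource dependence:
#' \deqn{dR_i/dt = \rho_i - \eta_i R_i - R_i \sum_j C_{ij} S_j + \sum_j P_{ij} S_j}
#' \deqn{dS_i/dt = \epsilon S_i \sum_j C^T_{ij} R_j - S_i \sum_j P^T_{ij} - \mu_i S_i}
#' With `P = 0` this reduces exactly to [competition_rhs()].
#'
#' @inheritParams competition_rhs
#' @return A list with components `dR` and `dS`.
#' @export
crossfeeding_rhs <- function(comm, R, S) {
  check_state(comm, R, S)
  dR <- comm$rho - comm$eta * R - R * as.vector(comm$C %*% S) +
    as.vector(comm$P %*% S)
  dS <- comm$epsilon * S * as.vector(crossprod(comm$C, R)) -
    S * unname(colSums(comm$P)) - comm$mu * S
  list(dR = dR, dS = dS)
}

#' Simulate community dynamics
#'
#' Integrates the chosen dynamics with a stiff-capable adaptive solver
#' (`deSolve::ode`, method `"lsoda"`). Small negative excursions (magnitude
#' below `neg_tol`) produced by the integrator are clamped to zero and
#' counted; larger negativity aborts with the last valid state attached to
#' the error condition.
#'
#' @inheritParams competition_rhs
#' @param R0,S0 nonnegative initial resource densities and consumer
#'   abundances.
#' @param times strictly increasing numeric vector of output times.
#' @param dynamics `"crossfeeding"` (default; exact superset of competition)
#'   or `"competition"` (ignores `P`).
#' @param neg_tol clamping threshold for negative values (default `1e-12`).
#' @param ... further arguments passed to [deSolve::ode()] (e.g. `rtol`,
#'   `atol`).
#' @return An object of class `"community_trajectory"`: a list with `times`,
#'   `R` (matrix, rows = times), `S` (matrix), the community, and the number
#'   of clamped values in attribute `"n_clamped"`.
#' @examples
#' comm <- community(C = diag(2), rho = c(1, 1), mu = c(1, 1), epsilon = 1)
#' tr <- simulate_community(comm, R0 = c(1, 1), S0 = c(1, 1), times = 0:10)
#' tail(as.data.frame(tr))
#' @export
simulate_community <- function(comm, R0, S0, times,
                               dynamics = c("crossfeeding", "competition"),
                               neg_tol = 1e-12, ...) {
  dynamics <- match.arg(dynamics)
  check_state(comm, R0, S0)
  if (any(R0 < 0) || any(S0 < 0)) stop("initial state must be nonnegative")
  times <- as.numeric(times)
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("'times' must be strictly increasing with at least two points")
  rhs_fun <- if (dynamics == "competition") competition_rhs else crossfeeding_rhs
  n_R <- comm$N_R
  deriv <- function(t, y, parms) {
    d <- rhs_fun(comm, y[seq_len(n_R)], y[-seq_len(n_R)])
    list(c(d$dR, d$dS))
  }
  dots <- list(...)
  if (is.null(dots$rtol)) dots$rtol <- 1e-10
  if (is.null(dots$atol)) dots$atol <- 1e-12
  sol <- try(do.call(deSolve::ode,
                     c(list(y = c(R0, S0), times = times, func = deriv,
                            parms = NULL, method = "lsoda"), dots)),
             silent = TRUE)
  if (inherits(sol, "try-error"))
    stop("integration failed: ", attr(sol, "condition")$message)
  if (nrow(sol) < length(times)) {
    last <- sol[nrow(sol), ]
    cond <- simpleError(sprintf(
      "integrator stopped early at t = %g (stiffness or blow-up)", last[1]))
    cond$last_state <- last
    stop(cond)
  }
  y <- sol[, -1, drop = FALSE]
  neg <- y < 0
  if (any(neg)) {
    worst <- min(y)
    if (worst < -neg_tol) {
      cond <- simpleError(sprintf(
        "trajectory went negative beyond tolerance (min value %.3e)", worst))
      cond$last_state <- sol[which(apply(neg, 1, any))[1], ]
      stop(cond)
    }
    y[neg] <- 0
  }
  out <- list(times = times,
              R = y[, seq_len(n_R), drop = FALSE],
              S = y[, -seq_len(n_R), drop = FALSE],
              community = comm, dynamics = dynamics)
  colnames(out$R) <- rownames(comm$C)
  colnames(out$S) <- colnames(comm$C)
  attr(out, "n_clamped") <- sum(neg)
  class(out) <- "community_trajectory"
  out
}

#' @export
print.community_trajectory <- function(x, ...) {
  cat(sprintf("community trajectory: %d time points on [%g, %g] (%s dynamics)\n",
              length(x$times), min(x$times), max(x$times), x$dynamics))
  fin <- c(x$R[nrow(x$R), ], x$S[nrow(x$S), ])
  cat("  final state: ", paste(sprintf("%.4g", fin), collapse = " "), "\n")
  invisible(x)
}

#' Tidy data frame of a trajectory
#'
#' @param x a `"community_trajectory"`.
#' @param ... unused.
#' @return A data frame with columns `time`, `variable`, `value` (long
#'   format, matching the CSV layout of [write_trajectory_csv()]).
#' @export
as.data.frame.community_trajectory <- function(x, ...) {
  vars <- c(colnames(x$R), colnames(x$S))
  data.frame(
    time = rep(x$times, times = length(vars)),
    variable = rep(vars, each = length(x$times)),
    value = c(x$R, x$S),
    stringsAsFactors = FALSE
  )
}

#' @export
plot.community_trajectory <- function(x, ...) {
  y <- cbind(x$R, x$S)
  graphics::matplot(x$times, y, type = "l", lty = 1,
                    col = c(rep("steelblue", ncol(x$R)),
                            rep("firebrick", ncol(x$S))),
                    xlab = "time", ylab = "density / abundance", ...)
  graphics::legend("topright", c("resources", "consumers"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}
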