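#' Define a consumer-producer-resource community
#'
#' A community is parameterized by a consumption matrix `C` (rows index
#' resources, columns index consumers), an optional production matrix `P` of
#' the same shape (crossfeeding: resource i produced by consumer j), a
#' resource influx vector `rho`, a consumer mortality vector `mu`, a scalar
#' conversion efficiency `epsilon`, and an optional resource leaching vector
#' `eta`.
#'
#' The community dynamics are
#' \deqn{dR_i/dt = \rho_i - \eta_i R_i - R_i \sum_j C_{ij} S_j + \sum_j P_{ij} S_j}
#' \deqn{dS_i/dt = \epsilon S_i \sum_j C^T_{ij} R_j - S_i \sum_j P^T_{ij} - \mu_i S_i}
#' With `P = 0` this is pure competition for substitutable abiotic resources;
#' a nonzero `P` adds production of resources by consumers, at a biomass cost
#' that is independent of resource levels.
#'
#' @param C numeric matrix of nonnegative consumption rates, `N_R x N_S`
#'   (rows = resources, columns = consumers).
#' @param rho positive resource influx vector of length `N_R`.
#' @param mu positive consumer mortality vector of length `N_S`.
#' @param epsilon positive scalar conversion efficiency.
#' @param P optional nonnegative production matrix, same shape as `C`;
#'   defaults to all zeros (no crossfeeding).
#' @param eta optional nonnegative resource leaching vector of length `N_R`;
#'   defaults to all zeros.
#' @return An object of class `"community"`: a list with elements `C`, `P`,
#'   `rho`, `mu`, `epsilon`, `eta`, `N_R`, `N_S`.
#' @examples
#' comm <- community(C = diag(2), rho = c(1, 1), mu = c(1, 1), epsilon = 1)
#' comm
#' @export
community <- function(C, rho, mu, epsilon, P = NULL, eta = NULL) {
  C <- as.matrix(C)
  if (!is.numeric(C) || anyNA(C)) stop("'C' must be a numeric matrix with no NA")
  if (any(C < 0)) stop("'C' must be entrywise nonnegative")
  N_R <- nrow(C)
  N_S <- ncol(C)
  if (is.null(P)) {
    P <- matrix(0, N_R, N_S)
  } else {
    P <- as.matrix(P)
    if (!identical(dim(P), dim(C)))
      stop("'P' must have the same shape as 'C' (", N_R, " x ", N_S, ")")
    if (any(P < 0)) stop("'P' must be entrywise nonnegative")
  }
  rho <- as.numeric(rho)
  mu <- as.numeric(mu)
  if (length(rho) != N_R) stop("'rho' must have length N_R = ", N_R)
  if (length(mu) != N_S) stop("'mu' must have length N_S = ", N_S)
  if (any(rho <= 0)) stop("'rho' must be entrywise positive")
  if (any(mu <= 0)) stop("'mu' must be entrywise positive")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("'epsilon' must be a positive scalar")
  if (is.null(eta)) {
    eta <- numeric(N_R)
  } else {
    eta <- as.numeric(eta)
    if (length(eta) == 1L) eta <- rep(eta, N_R)
    if (length(eta) != N_R) stop("'eta' must have length N_R = ", N_R)
    if (any(eta < 0)) stop("'eta' must be entrywise nonnegative")
  }
  if (is.null(rownames(C))) rownames(C) <- paste0("R", seq_len(N_R))
  if (is.null(colnames(C))) colnames(C) <- paste0("S", seq_len(N_S))
  dimnames(P) <- dimnames(C)
  structure(
    list(C = C, P = P, rho = rho, mu = mu, epsilon = as.numeric(epsilon),
         eta = eta, N_R = N_R, N_S = N_S),
    class = "community"
  )
}

#' @export
print.community <- function(x, ...) {
  kind <- if (any(x$P > 0)) "consumer-producer-resource" else "consumer-resource"
  cat(sprintf("%s community: %d resources, %d consumers\n", kind, x$N_R, x$N_S))
  cat(sprintf("  epsilon = %g;  leaching %s\n", x$epsilon,
              if (any(x$eta > 0)) "active" else "off"))
  cat(sprintf("  consumption rates in [%.3g, %.3g]", min(x$C), max(x$C)))
  if (any(x$P > 0))
    cat(sprintf(";  production rates in [%.3g, %.3g]", min(x$P), max(x$P)))
  cat("\n")
  invisible(x)
}

#' @export
summary.community <- function(object, ...) {
  eq <- tryCatch(
    if (any(object$P > 0)) crossfeeding_equilibrium(object)
    else competitive_equilibrium(object),
    error = function(e) e
  )
  out <- list(community = object, equilibrium = eq,
              rank = rank_condition(object$C))
  class(out) <- "summary.community"
  out
}

#' @export
print.summary.community <- function(x, ...) {
  print(x$community)
  rk <- x$rank
  cat(sprintf("  rank(C) = %d (N_S = %d): rank condition %s\n",
              rk$rank, rk$N_S, if (rk$holds) "holds" else "FAILS"))
  if (inherits(x$equilibrium, "error")) {
    cat("  equilibrium: not solvable (", conditionMessage(x$equilibrium), ")\n")
  } else {
    print(x$equilibrium)
  }
  invisible(x)
}

## internal shape checks shared by the RHS / Jacobian code
check_state <- function(comm, R, S) {
  if (length(R) != comm$N_R)
    stop("state 'R' has length ", length(R), " but community has N_R = ", comm$N_R)
  if (length(S) != comm$N_S)
    stop("state 'S' has length ", length(S), " but community has N_S = ", comm$N_S)
  invisible(TRUE)
}
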