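#' Specialist community with uniform densities
#'
#' The tractable crossfeeding case: `C = c I` (every consumer specializes on
#' one resource) with equilibrium densities tuned to be uniform,
#' `R* = r 1`, `S* = s 1`. This leaves the production matrix `P` completely
#' free, so it is close to the most general case of purely mutualistic
#' interspecific interaction, and it admits a closed-form eigenvalue mapping
#' (see [specialist_lambdas()]).
#'
#' @param c positive scalar specialist consumption rate.
#' @param s positive scalar equilibrium consumer abundance.
#' @param r positive scalar equilibrium resource density.
#' @param P nonnegative square production matrix.
#' @param epsilon positive conversion efficiency.
#' @return An object of class `"specialist_community"`.
#' @examples
#' sc <- specialist_community(c = 1, s = 1, r = 1,
#'                            P = matrix(c(0, .4, .4, 0), 2), epsilon = 1)
#' specialist_feasibility(sc)
#' @export
specialist_community <- function(c, s, r, P, epsilon) {
  if (any(c(c, s, r, epsilon) <= 0))
    stop("'c', 's', 'r' and 'epsilon' must be positive scalars")
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stop("'P' must be square")
  if (any(P < 0)) stop("'P' must be entrywise nonnegative")
  structure(list(c = c, s = s, r = r, P = P, epsilon = epsilon, N = nrow(P)),
            class = "specialist_community")
}

#' @export
print.specialist_community <- function(x, ...) {
  cat(sprintf("specialist community: N = %d, c = %g, r = %g, s = %g, epsilon = %g\n",
              x$N, x$c, x$r, x$s, x$epsilon))
  fz <- specialist_feasibility(x)
  cat(sprintf("  feasibility constraints: %s\n",
              if (fz$ok) "satisfied" else "VIOLATED"))
  invisible(x)
}

#' Influx and mortality rates realizing a uniform specialist equilibrium
#'
#' Closed-form inverse design for the specialist case:
#' \deqn{\mu = c r \epsilon 1 - P^T 1, \quad \rho = s [c r I - P] 1.}
#'
#' @param comm a [specialist_community()].
#' @return A list with `rho`, `mu` and `feasible_rates`.
#' @export
specialist_rates <- function(comm) {
  stopifnot(inherits(comm, "specialist_community"))
  mu <- comm$c * comm$r * comm$epsilon - unname(colSums(comm$P))
  rho <- comm$s * (comm$c * comm$r - rowSums(comm$P))
  list(rho = rho, mu = mu, feasible_rates = all(mu > 0) && all(rho > 0))
}

#' Promote a specialist community to a full community object
#'
#' Builds the `C = c I` community with rates from [specialist_rates()]; its
#' interior equilibrium is `R* = r 1`, `S* = s 1`.
#'
#' @param comm a [specialist_community()] satisfying both feasibility
#'   constraints (positive rates).
#' @return A [community()] object.
#' @export
as_community <- function(comm) {
  stopifnot(inherits(comm, "specialist_community"))
  rt <- specialist_rates(comm)
  if (!rt$feasible_rates)
    stop("specialist community violates the feasibility constraints; ",
         "rates would not be positive (see specialist_feasibility())")
  community(C = diag(comm$c, comm$N), rho = rt$rho, mu = rt$mu,
            epsilon = comm$epsilon, P = comm$P)
}

#' Feasibility constraints for the uniform specialist equilibrium
#'
#' Positive mortality rates require `c r epsilon > sum_j P^T_ij` (column sum
#' of `P` for each consumer i) and positive influx rates require
#' `c r > sum_j P_ij` (row sum of `P` for each resource i). Unlike the pure
#' competition case, not every positive `(r, s)` is attainable once `P != 0`.
#'
#' @param comm a [specialist_community()].
#' @return A list with logical vectors `consumer_ok` (constraint on column
#'   sums) and `resource_ok` (constraint on row sums), the violating indices,
#'   and overall flag `ok`.
#' @export
specialist_feasibility <- function(comm) {
  stopifnot(inherits(comm, "specialist_community"))
  cr <- comm$c * comm$r
  consumer_ok <- cr * comm$epsilon > colSums(comm$P)
  resource_ok <- cr > rowSums(comm$P)
  list(consumer_ok = consumer_ok,
       resource_ok = resource_ok,
       violating_consumers = which(!consumer_ok),
       violating_resources = which(!resource_ok),
       ok = all(consumer_ok) && all(resource_ok))
}

#' Closed-form Jacobian eigenvalues of the specialist system
#'
#' For the uniform specialist equilibrium the `2N` Jacobian eigenvalues come
#' in pairs indexed by the eigenvalues `gamma` of the production matrix `P`:
#' \deqn{\lambda = -cs/2 \pm (1/2)\sqrt{(cs)^2 - 4 \epsilon c s (c r - \gamma)}}
#' (complex square root, both branches always returned). The union over all
#' `gamma` reproduces the full Jacobian spectrum.
#'
#' @param comm a [specialist_community()].
#' @return An object of class `"gamma_diagnostics"`: a list with `gammas`
#'   (complex eigenvalues of `P`), `lambda_plus`, `lambda_minus`,
#'   `stable_per_gamma` (both roots have negative real part), and `lambdas`
#'   (all `2N` roots).
#' @export
specialist_lambdas <- function(comm) {
  stopifnot(inherits(comm, "specialist_community"))
  gam <- eigen(comm$P, only.values = TRUE)$values
  gam <- as.complex(gam)
  cs <- comm$c * comm$s
  cr <- comm$c * comm$r
  disc <- sqrt(as.complex(cs^2 - 4 * comm$epsilon * cs * (cr - gam)))
  lp <- (-cs + disc) / 2
  lm <- (-cs - disc) / 2
  structure(
    list(gammas = gam, lambda_plus = lp, lambda_minus = lm,
         stable_per_gamma = Re(lp) < 0 & Re(lm) < 0,
         lambdas = c(lp, lm), comm = comm),
    class = "gamma_diagnostics"
  )
}

#' @export
print.gamma_diagnostics <- function(x, ...) {
  cat(sprintf("specialist eigenvalue mapping: %d gamma values -> %d lambda roots\n",
              length(x$gammas), length(x$lambdas)))
  cat(sprintf("  max Re(lambda) = %.6g; stable for %d/%d gamma\n",
              max(Re(x$lambdas)), sum(x$stable_per_gamma), length(x$gammas)))
  invisible(x)
}

#' Per-eigenvalue stability condition for the specialist system
#'
#' The necessary-and-sufficient condition for both mapped Jacobian roots of
#' a production eigenvalue `gamma` to have negative real part:
#' \deqn{\epsilon (\mathrm{Im}\,\gamma)^2 < c s (c r - \mathrm{Re}\,\gamma).}
#'
#' @param gamma complex (or real) eigenvalue(s) of `P`; vectorized.
#' @param comm a [specialist_community()].
#' @return Logical vector, `TRUE` where the condition holds.
#' @export
gamma_condition <- function(gamma, comm) {
  stopifnot(inherits(comm, "specialist_community"))
  comm$epsilon * Im(as.complex(gamma))^2 <
    comm$c * comm$s * (comm$c * comm$r - Re(gamma))
}

#' Sufficient production bound for specialist stability
#'
#' Row-wise sufficient (not necessary) condition guaranteeing local
#' stability of the uniform specialist equilibrium:
#' \deqn{\Big(\sum_{j \ne i} P_{ij}\Big)^2 <
#'   \frac{c s}{\epsilon}\Big(c r - P_{ii} - \frac{c s}{4 \epsilon}\Big)
#'   \quad \forall i.}
#' When the bound fails the system may still be stable; check the spectrum.
#'
#' @param comm a [specialist_community()].
#' @return A list with per-row `lhs`, `rhs`, logical `ok` per row, and
#'   overall `sufficient` flag.
#' @export
production_bound <- function(comm) {
  stopifnot(inherits(comm, "specialist_community"))
  cs <- comm$c * comm$s
  cr <- comm$c * comm$r
  off <- rowSums(comm$P) - diag(comm$P)
  lhs <- off^2
  rhs <- (cs / comm$epsilon) * (cr - diag(comm$P) - cs / (4 * comm$epsilon))
  ok <- lhs < rhs
  list(lhs = lhs, rhs = rhs, ok = ok, sufficient = all(ok))
}

#' Gershgorin reciprocity criterion for symmetric production
#'
#' For a symmetric (reciprocal) production matrix all `gamma` are real, and
#' Gershgorin's theorem bounds them by the row sums: the equilibrium is
#' locally stable whenever `c r > sum_j P_ij` for every row — the same
#' condition that makes the equilibrium feasible. Feasibility and
#' reciprocity together imply local stability.
#'
#' @param comm a [specialist_community()] whose `P` is symmetric; asymmetric
#'   input is a precondition error reporting the largest asymmetric entry.
#' @param sym_tol symmetry tolerance (default `1e-12`).
#' @return `TRUE` iff the row-sum criterion holds for every row.
#' @export
gershgorin_symmetric_check <- function(comm, sym_tol = 1e-12) {
  stopifnot(inherits(comm, "specialist_community"))
  asym <- max(abs(comm$P - t(comm$P)))
  if (asym > sym_tol)
    stop("production matrix is not symmetric: max |P - t(P)| entry = ",
         format(asym, digits = 6))
  all(comm$c * comm$r > rowSums(comm$P))
}
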