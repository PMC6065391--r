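#' Community Jacobian at a state
#'
#' Assembles the `(N_R + N_S) x (N_R + N_S)` Jacobian of the crossfeeding
#' dynamics in block form:
#' \describe{
#'   \item{top-left}{`-diag(C S) - diag(eta)`}
#'   \item{top-right}{`P - diag(R) C`}
#'   \item{bottom-left}{`epsilon diag(S) C^T`}
#'   \item{bottom-right}{`diag(epsilon C^T R - P^T 1 - mu)`}
#' }
#' Because the per-consumer growth rate is linear in `S_i` only, these
#' blocks are exact at any state, not just at equilibrium. At an interior
#' equilibrium the bottom-right block vanishes; for an extirpated consumer
#' `j` (with `S_j = 0`) its diagonal entry is the invasion fitness
#' `[epsilon C^T R* - mu]_j`. Rectangular `C` (unequal resource and consumer
#' numbers) is supported.
#'
#' @param comm a [community()] object.
#' @param R,S state vectors (typically an equilibrium `R_star`, `S_star`).
#' @return A numeric matrix of dimension `(N_R + N_S)` squared, resources
#'   first.
#' @examples
#' comm <- community(matrix(1), rho = 1, mu = 1, epsilon = 1)
#' community_jacobian(comm, R = 1, S = 1)  # [[-1, -1], [1, 0]]
#' @export
community_jacobian <- function(comm, R, S) {
  stopifnot(inherits(comm, "community"))
  check_state(comm, R, S)
  top_left <- diag(-as.vector(comm$C %*% S) - comm$eta, comm$N_R)
  top_right <- comm$P - as.numeric(R) * comm$C
  bottom_left <- comm$epsilon * as.numeric(S) * t(comm$C)
  growth <- comm$epsilon * as.vector(crossprod(comm$C, R)) -
    unname(colSums(comm$P)) - comm$mu
  bottom_right <- diag(growth, comm$N_S)
  rbind(cbind(top_left, top_right), cbind(bottom_left, bottom_right))
}

#' Eigenvalue spectrum and stability verdict of a Jacobian
#'
#' All eigenvalues of the (real) Jacobian, sorted by descending real part
#' (ties by ascending imaginary part). The equilibrium is locally stable
#' when every eigenvalue has negative real part; a tolerance band around
#' zero is reported as marginal rather than forced into either verdict,
#' because these spectra typically carry a dense band of real eigenvalues
#' near zero.
#'
#' @param J square real matrix (e.g. from [community_jacobian()]).
#' @param tol marginality tolerance on the real part (default `1e-10`).
#' @return An object of class `"community_spectrum"`: `eigenvalues`
#'   (complex), `max_real`, `stable` (`max_real < -tol`), `marginal`
#'   (`|max_real| <= tol`), `n_marginal` (eigenvalues within the band).
#' @examples
#' jacobian_spectrum(matrix(c(-1, 1, -1, 0), 2))  # max Re = -0.5, stable
#' @export
jacobian_spectrum <- function(J, tol = 1e-10) {
  J <- as.matrix(J)
  if (nrow(J) != ncol(J)) stop("'J' must be square")
  ev <- eigen(J, only.values = TRUE)$values
  ev <- as.complex(ev)
  ev <- ev[order(-Re(ev), Im(ev))]
  max_real <- max(Re(ev))
  structure(
    list(eigenvalues = ev, max_real = max_real,
         stable = max_real < -tol,
         marginal = abs(max_real) <= tol,
         n_marginal = sum(abs(Re(ev)) <= tol), tol = tol),
    class = "community_spectrum"
  )
}

#' @export
print.community_spectrum <- function(x, ...) {
  verdict <- if (x$stable) "stable" else if (x$marginal) "marginal" else "UNSTABLE"
  cat(sprintf("spectrum: %d eigenvalues, max Re = %.6g -> %s",
              length(x$eigenvalues), x$max_real, verdict))
  if (x$n_marginal > 0)
    cat(sprintf(" (%d within +/-%g of the imaginary axis)", x$n_marginal, x$tol))
  cat("\n")
  invisible(x)
}

#' Invasion fitness of a consumer at a resource equilibrium
#'
#' The per-capita growth rate `[epsilon C^T R* - mu]_j` of consumer `j` when
#' rare. Exactly zero for residents at an interior equilibrium; negative
#' means the equilibrium with `S*_j = 0` is uninvasible by species `j` (and,
#' given the resident rank condition, stable); nonnegative means `j` can
#' invade (or is marginal).
#'
#' @param comm a [community()] object.
#' @param R_star positive resource density vector.
#' @param j consumer index.
#' @return Scalar invasion growth rate.
#' @export
invasion_fitness <- function(comm, R_star, j) {
  stopifnot(inherits(comm, "community"))
  if (length(R_star) != comm$N_R) stop("'R_star' must have length N_R")
  if (!is.numeric(j) || length(j) != 1L || j < 1 || j > comm$N_S)
    stop("consumer index 'j' out of range 1..", comm$N_S)
  (comm$epsilon * as.vector(crossprod(comm$C, R_star)) -
     unname(colSums(comm$P)) - comm$mu)[j]
}

#' Rank condition on the consumption matrix
#'
#' The feasibility-implies-stability guarantee requires
#' `rank(C) = N_S <= N_R`: at least as many resources as consumers, with
#' sufficiently unique consumer preferences.
#'
#' @param C consumption matrix.
#' @return A list with `rank`, `N_R`, `N_S` and logical `holds`.
#' @export
rank_condition <- function(C) {
  C <- as.matrix(C)
  rk <- qr(C)$rank
  list(rank = rk, N_R = nrow(C), N_S = ncol(C), holds = rk == ncol(C))
}

#' Positive-definiteness certificate underlying the stability theorem
#'
#' The local-stability proof for competitive communities reduces the
#' eigenvalue problem, for any candidate eigenvalue `lambda` with
#' nonnegative real part, to the matrix
#' \deqn{\sqrt{D_1}\, C^T D_2\, C \sqrt{D_1}, \quad
#'   D_1 = \epsilon\,\mathrm{diag}(S^*), \quad
#'   D_2 = [-\mathrm{diag}(C S^*) - \lambda I]^{-1}(-\mathrm{diag}(R^*)),}
#' whose Hermitian part must be positive definite — which rules out such a
#' `lambda` and certifies stability. This function evaluates that
#' certificate at a given `lambda`, operationalizing the proof as a
#' checkable predicate. It must return `TRUE` for every `Re(lambda) >= 0`
#' whenever `C` has full column rank and the densities are positive.
#'
#' @param C consumption matrix (`N_R x N_S`, full column rank for the
#'   certificate to hold).
#' @param R_star,S_star positive equilibrium densities.
#' @param epsilon positive conversion efficiency.
#' @param lambda complex scalar with `Re(lambda) >= 0`; must not collide
#'   with an eigenvalue `-(C S*)_i` of the top-left block.
#' @param pd_tol relative tolerance for positive definiteness.
#' @return `TRUE` if the Hermitian part is positive definite.
#' @export
hermitian_certificate <- function(C, R_star, S_star, epsilon, lambda,
                                  pd_tol = 1e-10) {
  C <- as.matrix(C)
  if (Re(lambda) < 0) stop("certificate applies to Re(lambda) >= 0 only")
  CS <- as.vector(C %*% S_star)
  if (any(abs(lambda + CS) < 1e-12))
    stop("lambda collides with an eigenvalue of -diag(C S*)")
  d2 <- R_star / (CS + lambda)          # diagonal of D2 (complex)
  s1 <- sqrt(epsilon * S_star)          # sqrt of diagonal D1
  M <- (s1 * t(C)) %*% (d2 * C)
  M <- t(t(M) * s1)                     # sqrt(D1) C^T D2 C sqrt(D1)
  H <- (M + Conj(t(M))) / 2
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  min(Re(ev)) > pd_tol * max(abs(Re(ev)), 1e-300)
}
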