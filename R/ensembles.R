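#' Configuration for community ensembles
#'
#' Describes how to generate a fixed preference (and optionally production)
#' matrix plus repeated random draws of equilibrium densities, from which
#' pooled Jacobian spectra are computed.
#'
#' Structures: `specialist_random` (strong diagonal, weak i.i.d. uniform
#' off-diagonal preferences), `generalist_random` (off-diagonal scale above
#' the diagonal), `specialist_ordered` / `generalist_ordered` (off-diagonal
#' preference falls off as a Gaussian kernel of the circular distance to the
#' consumer's favorite resource) and `diagonal` (pure specialists,
#' `C = diag_strength * I`, the setting for production/crossfeeding runs).
#'
#' @param N system size (resources = consumers), `>= 2`.
#' @param structure one of `"specialist_random"`, `"generalist_random"`,
#'   `"specialist_ordered"`, `"generalist_ordered"`, `"diagonal"`.
#' @param diag_strength diagonal (favorite-resource) consumption rate.
#' @param offdiag_scale off-diagonal amplitude; defaults to
#'   `0.2 * diag_strength` for specialist structures and
#'   `2 * diag_strength` for generalist ones.
#' @param kernel_width width (in resource positions) of the ordered
#'   preference kernel.
#' @param n_draws number of random density draws.
#' @param density_low,density_high bounds of the uniform density draw,
#'   `0 < low < high`; bounded away from zero by default to keep
#'   `diag(R*)` well conditioned.
#' @param epsilon conversion efficiency used when building communities.
#' @param production `"none"`, `"random"` (i.i.d. uniform entries) or
#'   `"random_symmetric"` (symmetrized before use).
#' @param production_scale upper bound of the uniform production entries.
#' @param seed integer seed; all generation is deterministic given the
#'   config.
#' @return An object of class `"ensemble_config"`.
#' @export
ensemble_config <- function(N, structure = "specialist_random",
                            diag_strength = 1, offdiag_scale = NULL,
                            kernel_width = 1, n_draws = 50,
                            density_low = 0.1, density_high = 1,
                            epsilon = 1, production = "none",
                            production_scale = 0.1, seed = 1L) {
  structure_names <- c("specialist_random", "generalist_random",
                       "specialist_ordered", "generalist_ordered", "diagonal")
  if (!structure %in% structure_names)
    stop("unknown structure '", structure, "'; must be one of: ",
         paste(structure_names, collapse = ", "))
  if (N < 2) stop("'N' must be at least 2")
  if (n_draws < 1) stop("'n_draws' must be at least 1")
  if (!(density_low > 0 && density_low < density_high))
    stop("need 0 < density_low < density_high")
  if (is.null(offdiag_scale))
    offdiag_scale <- if (grepl("^generalist", structure))
      2 * diag_strength else 0.2 * diag_strength
  if (offdiag_scale < 0 || production_scale < 0)
    stop("scales must be nonnegative")
  production <- match.arg(production, c("none", "random", "random_symmetric"))
  structure(
    list(N = as.integer(N), structure = structure,
         diag_strength = diag_strength, offdiag_scale = offdiag_scale,
         kernel_width = kernel_width, n_draws = as.integer(n_draws),
         density_low = density_low, density_high = density_high,
         epsilon = epsilon, production = production,
         production_scale = production_scale, seed = as.integer(seed)),
    class = "ensemble_config"
  )
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a consumption matrix from an ensemble configuration
#'
#' Deterministic given the config seed. Random structures draw i.i.d.
#' uniform off-diagonal entries; ordered structures place off-diagonal
#' entry `(i, j) = offdiag_scale * exp(-d(i,j)^2 / (2 kernel_width^2))`
#' with `d` the circular distance between resource `i` and consumer `j`'s
#' favorite resource (resource `j`). Rank-deficient / ill-conditioned draws
#' (condition number above `1e8`) are rejected and redrawn; the number of
#' rejections is recorded in attribute `"n_rejected"`.
#'
#' @param config an [ensemble_config()].
#' @return An `N x N` consumption matrix.
#' @export
make_consumption_matrix <- function(config) {
  stopifnot(inherits(config, "ensemble_config"))
  N <- config$N
  build <- function() {
    if (config$structure == "diagonal")
      return(diag(config$diag_strength, N))
    if (config$structure %in% c("specialist_random", "generalist_random")) {
      C <- matrix(stats::runif(N * N, 0, config$offdiag_scale), N, N)
      diag(C) <- config$diag_strength
      return(C)
    }
    # ordered: circular distance kernel around the favorite resource
    d <- abs(outer(seq_len(N), seq_len(N), "-"))
    d <- pmin(d, N - d)
    C <- config$offdiag_scale * exp(-d^2 / (2 * config$kernel_width^2))
    diag(C) <- config$diag_strength
    C
  }
  with_seed(config$seed, {
    rejected <- 0L
    repeat {
      C <- build()
      if (kappa(C, exact = TRUE) < 1e8) break
      rejected <- rejected + 1L
      if (rejected >= 100L)
        stop("could not draw a well-conditioned consumption matrix in 100 tries")
    }
    attr(C, "n_rejected") <- rejected
    C
  })
}

#' Generate a production matrix satisfying the specialist feasibility
#' constraints
#'
#' Entries are i.i.d. `U(0, production_scale)` (symmetrized as
#' `(P + t(P))/2` for `"random_symmetric"`). If the result violates the
#' feasibility constraints for the given specialist parameters
#' (`c r epsilon >` column sums and `c r >` row sums), the whole matrix is
#' rescaled by a single scalar (preserving symmetry and relative structure)
#' to sit just inside them; with `rescale = FALSE` a violation is an error
#' reporting the maximum admissible scale.
#'
#' @param config an [ensemble_config()] with `production != "none"`.
#' @param comm a [specialist_community()] supplying `c`, `r` and `epsilon`
#'   (its own `P` is ignored); constraints are enforced against these.
#' @param rescale rescale into feasibility (default) or error out.
#' @param margin safety factor applied when rescaling (default 0.95).
#' @return An `N x N` production matrix (zero matrix for
#'   `production = "none"`), with any applied scale factor in attribute
#'   `"scale_applied"`.
#' @export
make_production_matrix <- function(config, comm, rescale = TRUE, margin = 0.95) {
  stopifnot(inherits(config, "ensemble_config"))
  N <- config$N
  if (config$production == "none") return(matrix(0, N, N))
  stopifnot(inherits(comm, "specialist_community"))
  P <- with_seed(config$seed + 1L, {
    P <- matrix(stats::runif(N * N, 0, config$production_scale), N, N)
    if (config$production == "random_symmetric") P <- (P + t(P)) / 2
    P
  })
  cr <- comm$c * comm$r
  worst <- max(max(rowSums(P)) / cr, max(colSums(P)) / (cr * comm$epsilon))
  scale_applied <- 1
  if (worst >= 1) {
    if (!rescale)
      stop("production scale violates the feasibility constraints; ",
           "maximum admissible scale is ",
           format(config$production_scale * margin / worst, digits = 4))
    scale_applied <- margin / worst
    P <- P * scale_applied
  }
  attr(P, "scale_applied") <- scale_applied
  P
}

#' Pooled Jacobian spectrum over random density draws
#'
#' Reproduces the ensemble procedure behind the eigenvalue-density figures:
#' a fixed preference matrix (and production matrix, if any), repeated
#' uniform draws of equilibrium densities, inverse rate design so each draw
#' is an interior equilibrium, and the pooled eigenvalues of all the
#' resulting Jacobians.
#'
#' For `production = "none"`, full density vectors `R*`, `S*` are drawn
#' uniformly per draw. With production, scalar specialist densities `r`,
#' `s` are drawn (rejecting draws violating the feasibility constraints,
#' so every retained draw has positive rates).
#'
#' @param config an [ensemble_config()].
#' @return An object of class `"pooled_spectrum"`: `eigenvalues`
#'   (complex, `n_draws * 2N`), `max_reals` per draw, `fraction_unstable`
#'   (share of draws with `max Re > tol`), the consumption and production
#'   matrices used, and the config.
#' @param tol stability tolerance on the real part (default `1e-10`).
#' @export
pooled_spectrum <- function(config, tol = 1e-10) {
  stopifnot(inherits(config, "ensemble_config"))
  N <- config$N
  C <- make_consumption_matrix(config)
  with_prod <- config$production != "none"
  P <- if (with_prod) {
    # scale against the most permissive density so some draws are feasible
    ref <- specialist_community(c = config$diag_strength, s = 1,
                                r = config$density_high,
                                P = matrix(0, N, N),
                                epsilon = config$epsilon)
    make_production_matrix(config, ref)
  } else {
    matrix(0, N, N)
  }
  n_rejected <- 0L
  eigs <- vector("list", config$n_draws)
  max_reals <- numeric(config$n_draws)
  with_seed(config$seed + 2L, {
    for (k in seq_len(config$n_draws)) {
      if (with_prod) {
        sc <- NULL
        for (try in seq_len(10000L)) {
          r <- stats::runif(1, config$density_low, config$density_high)
          s <- stats::runif(1, config$density_low, config$density_high)
          cand <- specialist_community(c = config$diag_strength, s = s, r = r,
                                       P = P, epsilon = config$epsilon)
          if (specialist_feasibility(cand)$ok) { sc <- cand; break }
          n_rejected <- n_rejected + 1L
        }
        if (is.null(sc))
          stop("no feasible density draw found; production scale too large ",
               "for the density bounds")
        comm <- as_community(sc)
        J <- community_jacobian(comm, rep(sc$r, N), rep(sc$s, N))
      } else {
        R_star <- stats::runif(N, config$density_low, config$density_high)
        S_star <- stats::runif(N, config$density_low, config$density_high)
        rt <- rates_from_densities(C, R_star, S_star, config$epsilon)
        comm <- community(C, rho = rt$rho, mu = rt$mu,
                          epsilon = config$epsilon)
        J <- community_jacobian(comm, R_star, S_star)
      }
      ev <- eigen(J, only.values = TRUE)$values
      eigs[[k]] <- as.complex(ev)
      max_reals[k] <- max(Re(ev))
    }
  })
  structure(
    list(eigenvalues = unlist(eigs), max_reals = max_reals,
         n_draws = config$n_draws,
         fraction_unstable = mean(max_reals > tol),
         C = C, P = P, config = config, n_rejected_draws = n_rejected),
    class = "pooled_spectrum"
  )
}

#' @export
print.pooled_spectrum <- function(x, ...) {
  cat(sprintf("pooled spectrum: %d draws, N = %d (%s%s)\n",
              x$n_draws, x$config$N, x$config$structure,
              if (x$config$production != "none")
                paste0(", production ", x$config$production) else ""))
  cat(sprintf("  %d eigenvalues; max Re overall = %.6g; fraction of unstable draws = %.3f\n",
              length(x$eigenvalues), max(Re(x$eigenvalues)),
              x$fraction_unstable))
  near_zero <- mean(abs(Re(x$eigenvalues)) < 0.05 * max(abs(Re(x$eigenvalues))))
  cat(sprintf("  share of eigenvalues with near-zero real part: %.3f\n", near_zero))
  invisible(x)
}

#' @export
plot.pooled_spectrum <- function(x, ...) {
  ev <- x$eigenvalues
  graphics::smoothScatter(Re(ev), Im(ev), xlab = "Re(lambda)",
                          ylab = "Im(lambda)", ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}
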