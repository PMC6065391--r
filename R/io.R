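## CSV / YAML / JSON interchange for parameter sets and results.
##
## Matrices travel as headered CSV: first column = resource labels, header
## row = consumer labels. Full parameter sets travel as a YAML (or JSON)
## document carrying epsilon/rho/mu/eta inline and matrices either inline
## (list of rows) or as relative CSV file references.

#' Write / read a labeled matrix as CSV
#'
#' First column holds resource labels, the header row consumer labels.
#'
#' @param M numeric matrix (rows = resources, columns = consumers).
#' @param path file path.
#' @return `read_matrix_csv` returns the matrix with dimnames;
#'   `write_matrix_csv` returns `path` invisibly.
#' @export
write_matrix_csv <- function(M, path) {
  M <- as.matrix(M)
  if (is.null(rownames(M))) rownames(M) <- paste0("R", seq_len(nrow(M)))
  if (is.null(colnames(M))) colnames(M) <- paste0("S", seq_len(ncol(M)))
  df <- data.frame(resource = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  storage.mode(M) <- "double"
  M
}

#' Write / read a community as a YAML or JSON document
#'
#' The document stores `epsilon`, `rho`, `mu`, `eta` and the matrices `C`
#' and `P` either inline (as lists of rows) or, when `matrix_files = TRUE`
#' on write, as sibling CSV files referenced by relative path (`C_file`,
#' `P_file`). Format is chosen from the file extension (`.yml`/`.yaml` or
#' `.json`).
#'
#' @param comm a [community()] object.
#' @param path document path.
#' @param matrix_files write matrices as sibling CSV files instead of
#'   inline rows.
#' @return `read_community` returns a `"community"`; `write_community`
#'   returns `path` invisibly.
#' @export
write_community <- function(comm, path, matrix_files = FALSE) {
  stopifnot(inherits(comm, "community"))
  doc <- list(epsilon = comm$epsilon, rho = as.numeric(comm$rho),
              mu = as.numeric(comm$mu), eta = as.numeric(comm$eta))
  if (matrix_files) {
    base <- sub("\\.[^.]+$", "", basename(path))
    c_file <- paste0(base, "_C.csv")
    p_file <- paste0(base, "_P.csv")
    write_matrix_csv(comm$C, file.path(dirname(path), c_file))
    doc$C_file <- c_file
    if (any(comm$P > 0)) {
      write_matrix_csv(comm$P, file.path(dirname(path), p_file))
      doc$P_file <- p_file
    }
  } else {
    doc$C <- apply(unname(comm$C), 1, as.numeric, simplify = FALSE)
    if (any(comm$P > 0))
      doc$P <- apply(unname(comm$P), 1, as.numeric, simplify = FALSE)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(doc, path, precision = 15L)
  }
  invisible(path)
}

#' @rdname write_community
#' @export
read_community <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  get_mat <- function(inline, file_ref) {
    if (!is.null(inline)) {
      if (is.list(inline)) inline <- do.call(rbind, lapply(inline, as.numeric))
      return(as.matrix(inline))
    }
    if (!is.null(file_ref))
      return(read_matrix_csv(file.path(dirname(path), file_ref)))
    NULL
  }
  C <- get_mat(doc[["C"]], doc[["C_file"]])  # exact names: avoid $ partial match
  if (is.null(C)) stop("document has neither 'C' nor 'C_file'")
  P <- get_mat(doc[["P"]], doc[["P_file"]])
  community(C = C, rho = as.numeric(doc$rho), mu = as.numeric(doc$mu),
            epsilon = as.numeric(doc$epsilon), P = P,
            eta = if (!is.null(doc$eta)) as.numeric(doc$eta))
}

#' Write a trajectory as tidy CSV
#'
#' Long format with columns `time`, `variable`, `value`.
#'
#' @param traj a `"community_trajectory"`.
#' @param path file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "community_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a spectrum as CSV and/or JSON summary
#'
#' `write_spectrum_csv` writes one row per eigenvalue (`re`, `im` columns);
#' `write_spectrum_json` writes a summary with `max_real`, `stable` and the
#' marginal count.
#'
#' @param spec a `"community_spectrum"` (from [jacobian_spectrum()]).
#' @param path file path.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "community_spectrum"))
  utils::write.csv(
    data.frame(re = Re(spec$eigenvalues), im = Im(spec$eigenvalues)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
write_spectrum_json <- function(spec, path) {
  stopifnot(inherits(spec, "community_spectrum"))
  jsonlite::write_json(
    list(max_real = spec$max_real, stable = spec$stable,
         marginal = spec$marginal, n_marginal = spec$n_marginal,
         n_eigenvalues = length(spec$eigenvalues)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
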