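#' Pearson correlation matrix of a regional time-series matrix
#'
#' @param timeseries Numeric matrix, timepoints x regions (T >= 3). Column
#'   names, if present, are carried through.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(timeseries) {
  timeseries <- as.matrix(timeseries)
  if (!is.numeric(timeseries)) stop("time series must be numeric")
  if (anyNA(timeseries) || any(!is.finite(timeseries)))
    stop("time series contains missing or non-finite values")
  if (nrow(timeseries) < 3L)
    stop("need at least 3 timepoints to estimate correlations")
  sds <- apply(timeseries, 2L, stats::sd)
  if (any(sds == 0)) {
    k <- which(sds == 0)[1L]
    nm <- if (!is.null(colnames(timeseries))) colnames(timeseries)[k] else k
    stop("region '", nm, "' has zero variance")
  }
  r <- stats::cor(timeseries)
  # enforce exact symmetry against floating-point asymmetry
  (r + t(r)) / 2
}

#' Fisher z-transform of a correlation matrix
#'
#' Applies the variance-stabilizing transform z = arctanh(r) to every
#' off-diagonal entry. The diagonal is stored as zero and excluded from all
#' downstream edge operations. Correlations are clipped to |r| <= 1 - 1e-7
#' beforehand so collinear (degenerate) inputs yield finite z.
#'
#' @param r_matrix Symmetric correlation matrix.
#' @return Matrix of Fisher-z values, zero diagonal.
#' @export
fisher_z <- function(r_matrix) {
  r_matrix <- as.matrix(r_matrix)
  if (nrow(r_matrix) != ncol(r_matrix)) stop("correlation matrix must be square")
  r <- pmin(pmax(r_matrix, -1 + 1e-7), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  z
}

#' Flatten a connectivity matrix to its canonical edge vector
#'
#' Extracts the upper triangle in the row-major order of [edge_pairs()],
#' giving one value per unordered region pair.
#'
#' @param matrix Symmetric N x N connectivity matrix.
#' @return Numeric vector of length `N (N - 1) / 2`.
#' @seealso [devectorize()]
#' @export
vectorize <- function(matrix) {
  matrix <- as.matrix(matrix)
  n <- nrow(matrix)
  if (ncol(matrix) != n) stop("connectivity matrix must be square")
  p <- edge_pairs(n)
  matrix[p]
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize()]: places each edge value at (i, j) and (j, i),
#' with a zero diagonal.
#'
#' @param values Edge vector in canonical order.
#' @param n_regions Number of regions; must satisfy
#'   `length(values) == n_regions (n_regions - 1) / 2`.
#' @return Symmetric N x N matrix, zero diagonal.
#' @export
devectorize <- function(values, n_regions) {
  if (length(values) != n_edges(n_regions))
    stop("edge vector length ", length(values), " does not match ",
         n_regions, " regions (expected ", n_edges(n_regions), ")")
  m <- matrix(0, n_regions, n_regions)
  p <- edge_pairs(n_regions)
  m[p] <- values
  m[p[, c(2L, 1L)]] <- values
  m
}

#' Subjects-by-edges Fisher-z strength matrix for a cohort
#'
#' Runs the standard connectivity chain (Pearson correlation, Fisher z,
#' vectorize) for every subject and stacks the edge vectors.
#'
#' @param cohort A list of subject records as produced by
#'   [generate_cohort()], a list of timepoints x regions matrices, or a list
#'   of precomputed square connectivity matrices (detected by being square
#'   and symmetric).
#' @param atlas Optional `atlas_spec`; when given, edge columns are named
#'   with "LabelA-LabelB" labels and dimensions are checked.
#' @return Numeric matrix, subjects x edges, rownames = subject ids when
#'   available.
#' @export
cohort_edge_matrix <- function(cohort, atlas = NULL) {
  if (!is.list(cohort) || !length(cohort)) stop("cohort must be a non-empty list")
  get_mat <- function(s) if (is.list(s) && !is.null(s$timeseries)) s$timeseries else s
  one <- function(s) {
    m <- as.matrix(get_mat(s))
    sq <- nrow(m) == ncol(m) && isTRUE(all.equal(m, t(m), tolerance = 1e-8))
    z <- if (!sq) {
      fisher_z(correlation_matrix(m))
    } else if (all(abs(diag(m) - 1) < 1e-12)) {
      fisher_z(m)          # correlation matrix (unit diagonal)
    } else if (all(diag(m) == 0)) {
      m                    # already Fisher-z (zero diagonal convention)
    } else {
      stop("square matrix has neither unit nor zero diagonal; ",
           "cannot tell correlation from Fisher-z input")
    }
    if (!is.null(atlas) && nrow(z) != atlas$n_regions)
      stop("matrix has ", nrow(z), " regions; atlas has ", atlas$n_regions)
    vectorize(z)
  }
  out <- t(vapply(cohort, one, numeric(n_edges(ncol(as.matrix(get_mat(cohort[[1]])))))))
  ids <- vapply(seq_along(cohort), function(k) {
    s <- cohort[[k]]
    if (is.list(s) && !is.null(s$subject_id)) s$subject_id else paste0("S", k)
  }, "")
  rownames(out) <- ids
  if (!is.null(atlas))
    colnames(out) <- edge_labels(edge_pairs(atlas$n_regions), atlas)
  out
}
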