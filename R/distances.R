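#' Pairwise distances under the metrics used by the segmentation model
#'
#' Computes a dense symmetric distance matrix from a coordinate matrix.
#' Three metrics are supported: plain Euclidean; Euclidean with periodic
#' boundary conditions, for angular variables such as dihedral-angle vectors
#' (each coordinate difference is wrapped into `[-period/2, period/2]`
#' before squaring); and Euclidean after normalizing every row by its L2
#' norm, which removes overall size effects (e.g. firm size in balance-sheet
#' tables).
#'
#' @param data numeric matrix, rows = points, columns = features. All
#'   entries must be finite.
#' @param metric one of `"euclidean"`, `"periodic_euclidean"`,
#'   `"normalized_euclidean"`.
#' @param period for the periodic metric: the period of each coordinate,
#'   either a scalar (recycled) or a vector of length `ncol(data)`.
#'   Default `2*pi`, the natural choice for angles in radians.
#' @return an N x N symmetric numeric matrix with zero diagonal.
#' @examples
#' x <- matrix(c(3.1, -3.1), ncol = 1)
#' compute_distances(x, "periodic_euclidean")[1, 2]  # 2*pi - 6.2
#' @export
compute_distances <- function(data,
                              metric = c("euclidean", "periodic_euclidean",
                                         "normalized_euclidean"),
                              period = 2 * pi) {
  metric <- match.arg(metric)
  data <- as.matrix(data)
  if (!is.numeric(data) || ncol(data) < 1L)
    stop("`data` must be a numeric matrix with at least one column")
  if (!all(is.finite(data)))
    stop("`data` contains non-finite entries")
  n <- nrow(data)
  out <- switch(metric,
    euclidean = as.matrix(dist(data)),
    normalized_euclidean = {
      nrm <- sqrt(rowSums(data^2))
      bad <- which(nrm == 0)
      if (length(bad))
        stop("normalized_euclidean: row(s) with zero norm: ",
             paste(bad, collapse = ", "))
      as.matrix(dist(data / nrm))
    },
    periodic_euclidean = {
      if (any(period <= 0)) stop("`period` must be positive")
      period <- rep_len(period, ncol(data))
      acc <- matrix(0, n, n)
      for (j in seq_len(ncol(data))) {
        dif <- outer(data[, j], data[, j], "-")
        dif <- dif - period[j] * round(dif / period[j])
        acc <- acc + dif^2
      }
      sqrt(acc)
    })
  dimnames(out) <- NULL
  out
}

#' Validate a user-supplied distance matrix
#'
#' Checks squareness, zero diagonal, non-negativity and symmetry (within
#' `tol`); small asymmetries are symmetrized with a warning, larger ones are
#' an error.
#'
#' @param d numeric square matrix of distances.
#' @param tol absolute tolerance for the symmetry / zero-diagonal checks.
#' @return the validated (possibly symmetrized) matrix.
#' @export
validate_distances <- function(d, tol = 1e-9) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (!all(is.finite(d))) stop("distance matrix has non-finite entries")
  if (any(d < 0)) stop("distance matrix has negative entries")
  if (any(abs(diag(d)) > tol)) stop("distance matrix diagonal is not zero")
  asym <- max(abs(d - t(d)))
  if (asym > tol)
    stop("distance matrix is asymmetric (max |d - t(d)| = ",
         format(asym), ")")
  if (asym > 0) {
    warning("symmetrizing distance matrix (max asymmetry ", format(asym), ")")
    d <- (d + t(d)) / 2
  }
  diag(d) <- 0
  dimnames(d) <- NULL
  d
}
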