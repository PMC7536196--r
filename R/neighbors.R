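#' Nearest-neighbour structure and distance ratios
#'
#' From a distance matrix, finds for every point its `q` nearest neighbours
#' (ties in distance broken deterministically by the smaller point index)
#' and records the first- and second-neighbour distances `r1`, `r2`, which
#' are always taken from neighbour ranks 1 and 2 even when `q > 2`.
#'
#' Results on degenerate data with exactly tied distances can depend on the
#' input row order because of the index tie-break.
#'
#' @param dist N x N symmetric distance matrix (see [compute_distances()]).
#' @param q number of neighbours to record per point (the homogeneity range
#'   of the segmentation model).
#' @param jitter if `NULL` (default) any zero off-diagonal distance is an
#'   error, since tied points break the ratio statistic; a positive number
#'   adds uniform noise of that amplitude to off-diagonal entries instead
#'   (symmetrically), as an explicit opt-in for discrete-valued data.
#' @return an object of class `neighbor_stats`: a list with
#'   `neighbor_idx` (N x q integer matrix, increasing distance), `in_lists`
#'   (for each point i, the points having i among their own q neighbours),
#'   `r1`, `r2`, and slots `mu`, `V` filled by [compute_mu()].
#' @export
find_neighbors <- function(dist, q, jitter = NULL) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n != ncol(d)) stop("distance matrix must be square")
  q <- as.integer(q)
  if (q < 1L) stop("`q` must be a positive integer")
  if (n < max(q + 1L, 3L))
    stop("need at least max(q + 1, 3) = ", max(q + 1L, 3L),
         " points for q = ", q, " neighbours and a second-neighbour ratio")
  if (!is.null(jitter)) {
    stopifnot(jitter > 0)
    noise <- matrix(runif(n * n, 0, jitter), n, n)
    noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    d <- d + noise
  }
  off <- d
  diag(off) <- NA_real_
  if (any(off == 0, na.rm = TRUE))
    stop("zero distance between distinct points: the ratio statistic is ",
         "undefined for tied points. Deduplicate the data or pass a small ",
         "`jitter` amplitude.")
  m <- max(q, 2L)
  nbr <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    row <- d[i, ]
    row[i] <- Inf
    # stable order with explicit index tie-break
    nbr[i, ] <- order(row, seq_len(n))[seq_len(m)]
  }
  r1 <- d[cbind(seq_len(n), nbr[, 1L])]
  r2 <- d[cbind(seq_len(n), nbr[, 2L])]
  neighbor_idx <- nbr[, seq_len(q), drop = FALSE]
  in_lists <- build_in_lists(neighbor_idx, n)
  structure(list(neighbor_idx = neighbor_idx, in_lists = in_lists,
                 r1 = r1, r2 = r2, mu = NULL, V = NULL,
                 q = q, n = n),
            class = "neighbor_stats")
}

# transpose relation of the directed q-neighbour graph
build_in_lists <- function(neighbor_idx, n) {
  src <- rep(seq_len(n), times = ncol(neighbor_idx))
  dst <- as.vector(neighbor_idx)
  out <- split(src, factor(dst, levels = seq_len(n)))
  lapply(out, as.integer)
}

#' Distance-ratio statistic of every point
#'
#' Fills `mu = r2 / r1`, the per-point ratio of second- to first-neighbour
#' distance, and its log-sum `V = sum(log(mu))`. On a manifold of dimension
#' d (with the density locally constant up to the second neighbour), `mu`
#' follows a Pareto law with shape d, so `V` is the sufficient statistic for
#' the dimension likelihood.
#'
#' @param stats a `neighbor_stats` object from [find_neighbors()].
#' @return the same object with `mu` and `V` filled.
#' @export
compute_mu <- function(stats) {
  stopifnot(inherits(stats, "neighbor_stats"))
  if (any(stats$r1 <= 0))
    stop("r1 = 0 encountered; deduplicate the data first")
  stats$mu <- stats$r2 / stats$r1
  stats$V <- sum(log(stats$mu))
  stats
}

#' One-call construction of the model's sufficient statistics
#'
#' Convenience pipeline: coordinates (or a precomputed distance matrix)
#' -> distances -> q-nearest-neighbour structure -> ratio statistic.
#'
#' @param x numeric coordinate matrix, or a distance matrix when
#'   `distances = TRUE`.
#' @param q neighbours per point (default 3, the model's working point).
#' @param metric,period passed to [compute_distances()] (ignored for
#'   distance input).
#' @param distances set `TRUE` when `x` is already a distance matrix.
#' @param jitter passed to [find_neighbors()].
#' @return a `neighbor_stats` object with `mu` filled.
#' @export
neighbor_stats <- function(x, q = 3L, metric = "euclidean",
                           period = 2 * pi, distances = FALSE,
                           jitter = NULL) {
  d <- if (distances) validate_distances(x)
       else compute_distances(x, metric, period)
  compute_mu(find_neighbors(d, q, jitter = jitter))
}

#' Global two-neighbour dimension estimate
#'
#' The maximum-likelihood intrinsic dimension under a single Pareto
#' component, `N / V`. Useful as a quick homogeneous-data estimate and as a
#' sanity check on synthetic manifolds.
#'
#' @param stats a `neighbor_stats` object with `mu` filled, or a coordinate
#'   matrix (then [neighbor_stats()] is called with defaults).
#' @return scalar dimension estimate.
#' @export
twonn_dimension <- function(stats) {
  if (is.matrix(stats) || is.data.frame(stats))
    stats <- neighbor_stats(as.matrix(stats))
  stopifnot(inherits(stats, "neighbor_stats"), !is.null(stats$V))
  stats$n / stats$V
}

#' Greedy subset of points with non-overlapping first/second neighbours
#'
#' The ratio statistics of two points are dependent when their
#' \{self, first, second neighbour\} triples share a point. Scanning points
#' in index order, a point is kept iff its triple is disjoint from the
#' triples of all previously kept points. Typically about 15% of the points
#' survive; the model's estimates use all points by default, and this filter
#' is offered for checking robustness of the inference to the independence
#' assumption.
#'
#' @param stats a `neighbor_stats` object.
#' @return integer vector of kept point indices (increasing).
#' @export
independent_point_filter <- function(stats) {
  stopifnot(inherits(stats, "neighbor_stats"))
  n <- stats$n
  nn1 <- stats$neighbor_idx[, 1L]
  nn2 <- if (ncol(stats$neighbor_idx) >= 2L) stats$neighbor_idx[, 2L] else
    stop("filter requires q >= 2")
  used <- logical(n)
  kept <- integer(0)
  for (i in seq_len(n)) {
    trip <- c(i, nn1[i], nn2[i])
    if (!any(used[trip])) {
      kept <- c(kept, i)
      used[trip] <- TRUE
    }
  }
  kept
}

#' @export
print.neighbor_stats <- function(x, ...) {
  cat("neighbor_stats: ", x$n, " points, q = ", x$q, "\n", sep = "")
  if (!is.null(x$mu))
    cat("  mu in [", format(min(x$mu), digits = 4), ", ",
        format(max(x$mu), digits = 4), "], global TWO-NN estimate ",
        format(x$n / x$V, digits = 4), "\n", sep = "")
  invisible(x)
}
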