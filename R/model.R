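#' Configuration of the heterogeneous-dimension model
#'
#' Collects model hyperparameters and sampler settings. Defaults follow the
#' method's working point: `q = 3` neighbours, homogeneity level
#' `xi = 0.8`, flat Gamma(1,1) priors on the dimensions (prior mean 1),
#' flat Dirichlet(1,...,1) prior on the mixing proportions, 1e5 Gibbs
#' sweeps of which the last 10% are retained, 10 chains, and assignment
#' threshold 0.8 on the membership probability.
#'
#' `xi` is the probability that a point's neighbour lies on the same
#' manifold; `xi = 0.5` switches the neighbourhood constraint off (a useful
#' control) and values below 0.5 contradict the model's premise, so they
#' require `allow_low_xi = TRUE`.
#'
#' @param K number of manifolds (>= 1).
#' @param q neighbours per point used by the homogeneity term.
#' @param xi homogeneity level in `[0.5, 1)`.
#' @param a,b Gamma prior shape/rate on the dimensions; scalars or length-K.
#' @param c Dirichlet prior on proportions; scalar or length-K.
#' @param n_sweeps Gibbs sweeps per chain.
#' @param keep_fraction fraction of final sweeps retained for estimation.
#' @param n_chains independent chains (seeds `seed + 0 .. n_chains - 1`).
#' @param seed base RNG seed.
#' @param threshold membership probability above which a point is assigned;
#'   must exceed `1/K`.
#' @param allow_low_xi permit `xi < 0.5`.
#' @return an object of class `hidalgo_config`.
#' @export
hidalgo_config <- function(K, q = 3L, xi = 0.8, a = 1, b = 1, c = 1,
                           n_sweeps = 1e5, keep_fraction = 0.1,
                           n_chains = 10L, seed = 1L, threshold = 0.8,
                           allow_low_xi = FALSE) {
  K <- as.integer(K); q <- as.integer(q)
  if (K < 1L) stop("K must be >= 1")
  if (q < 1L) stop("q must be >= 1")
  if (xi >= 1 || xi <= 0) stop("xi must lie in (0, 1)")
  if (xi < 0.5 && !allow_low_xi)
    stop("xi < 0.5 contradicts the neighbourhood-homogeneity premise; ",
         "pass allow_low_xi = TRUE to override")
  a <- rep_len(a, K); b <- rep_len(b, K); c <- rep_len(c, K)
  if (any(a <= 0) || any(b <= 0) || any(c <= 0))
    stop("prior parameters a, b, c must be positive")
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must lie in (0, 1]")
  if (threshold > 1 || (K > 1L && threshold <= 1 / K))
    stop("threshold must lie in (1/K, 1]")
  if (n_chains < 1L) stop("n_chains must be >= 1")
  structure(list(K = K, q = q, xi = xi, a = a, b = b, c = c,
                 n_sweeps = as.integer(n_sweeps),
                 keep_fraction = keep_fraction,
                 n_chains = as.integer(n_chains),
                 seed = as.integer(seed), threshold = threshold),
            class = "hidalgo_config")
}

#' @export
print.hidalgo_config <- function(x, ...) {
  cat("hidalgo_config: K =", x$K, " q =", x$q, " xi =", x$xi,
      "\n  sweeps =", x$n_sweeps, " keep =", x$keep_fraction,
      " chains =", x$n_chains, " seed =", x$seed,
      " threshold =", x$threshold, "\n")
  invisible(x)
}

#' Pareto log-density of the distance-ratio statistic
#'
#' `log f(mu | d) = log d - (d + 1) log mu` on `mu >= 1`; summed over a
#' sample this is `N log d - (d + 1) V` with `V = sum(log mu)`.
#'
#' @param mu ratio values (each >= 1).
#' @param d dimension (> 0). `mu` and `d` are recycled together.
#' @return vector of log-densities.
#' @export
pareto_logpdf <- function(mu, d) {
  if (any(mu < 1)) stop("mu < 1 violates the ratio construction (r2 >= r1)")
  if (any(d <= 0)) stop("d must be positive")
  log(d) - (d + 1) * log(mu)
}

#' Partition factor of the neighbourhood likelihood
#'
#' Normalizes the homogeneity term over the possible in/out-manifold
#' identities of a point's q neighbour slots, given the manifold sizes:
#' `Z(xi, N_k) = sum_{n=0}^{q} C(N_k - 1, n) C(N - N_k, q - n) xi^n
#' (1 - xi)^(q - n)`. At `xi = 0.5` the Vandermonde identity makes Z
#' independent of `N_k`, so the homogeneity term becomes a constant: the
#' "no constraint" control is exactly neutral. A manifold size of 0 is
#' treated as size 1 (no in-manifold neighbours are possible either way).
#'
#' @param xi homogeneity level in (0, 1).
#' @param N_k manifold size(s); vectorized.
#' @param N total number of points.
#' @param q neighbours per point (`q <= N - 1`).
#' @param log return log Z instead of Z.
#' @return Z (or log Z), same length as `N_k`.
#' @export
partition_function <- function(xi, N_k, N, q, log = FALSE) {
  stopifnot(xi > 0, xi < 1, q >= 1, q <= N - 1, all(N_k >= 0), all(N_k <= N))
  N_k <- ifelse(N_k == 0, 1L, N_k)
  lxi <- base::log(xi); l1xi <- log1p(-xi)
  out <- vapply(N_k, function(s) {
    terms <- vapply(0:q, function(n)
      lchoose(s - 1, n) + lchoose(N - s, q - n) + n * lxi + (q - n) * l1xi,
      numeric(1))
    m <- max(terms)
    if (!is.finite(m)) return(-Inf)
    m + base::log(sum(exp(terms - m)))
  }, numeric(1))
  if (log) out else exp(out)
}

#' Neighbourhood-homogeneity log-likelihood
#'
#' The probability of the observed directed q-neighbour graph given labels:
#' each point contributes `n_in * log(xi) + (q - n_in) * log(1 - xi)
#' - log Z(xi, N_{z_i})`, where `n_in` counts its neighbours sharing its
#' label. At `xi = 0.5` the value does not depend on the labels.
#'
#' @param stats a `neighbor_stats` object.
#' @param z integer labels in `1..K`.
#' @param xi homogeneity level.
#' @param K number of manifolds (defaults to `max(z)`).
#' @return scalar log-likelihood.
#' @export
neighborhood_loglik <- function(stats, z, xi, K = max(z)) {
  stopifnot(inherits(stats, "neighbor_stats"), length(z) == stats$n)
  n <- stats$n; q <- stats$q
  zn <- matrix(z[stats$neighbor_idx], n, q)
  n_in <- rowSums(zn == z)
  counts <- tabulate(z, K)
  lz <- partition_function(xi, seq_len(n), n, q, log = TRUE)
  sum(n_in) * log(xi) + (n * q - sum(n_in)) * log1p(-xi) -
    sum(counts * lz[pmax(counts, 1L)])
}

# prior normalizing constants kept in the log-posterior so that values are
# comparable across K during model selection
prior_log_const <- function(cfg) {
  sum(cfg$a * log(cfg$b) - lgamma(cfg$a)) +
    lgamma(sum(cfg$c)) - sum(lgamma(cfg$c))
}

#' Full log-posterior of a sampler state
#'
#' Evaluates the (normalized up to the evidence) log-posterior of
#' `(z, d, p)`: the Pareto mixture likelihood of the ratio statistics, the
#' neighbourhood-homogeneity likelihood, the multinomial label prior, and
#' the Gamma/Dirichlet priors including their normalizing constants, so
#' that values are comparable across different K. Only the (z, d, p)- and
#' K-independent evidence term is dropped.
#'
#' @param state list with elements `z` (labels 1..K), `d` (length-K
#'   positive dimensions), `p` (length-K simplex).
#' @param stats a `neighbor_stats` object with `mu` filled.
#' @param cfg a [hidalgo_config()].
#' @return scalar log-posterior.
#' @export
log_posterior <- function(state, stats, cfg) {
  z <- state$z; d <- state$d; p <- state$p
  K <- cfg$K
  stopifnot(length(d) == K, length(p) == K, all(z >= 1L), all(z <= K))
  counts <- tabulate(z, K)
  lmu <- log(stats$mu)
  Vk <- vapply(seq_len(K), function(k) sum(lmu[z == k]), numeric(1))
  lp <- sum(counts * log(d)) - sum((d + 1) * Vk)
  lp <- lp + neighborhood_loglik(stats, z, cfg$xi, K)
  lp <- lp + sum(counts * log(p))
  lp <- lp + sum((cfg$a - 1) * log(d) - cfg$b * d)
  lp <- lp + sum((cfg$c - 1) * log(p))
  lp + prior_log_const(cfg)
}
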