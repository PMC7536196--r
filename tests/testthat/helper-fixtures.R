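# fixtures shared across test files; all randomness locally seeded

# three collinear points 0, 1, 3: neighbour structure is hand-checkable
line3_stats <- function(q = 2L) {
  compute_mu(find_neighbors(compute_distances(matrix(c(0, 1, 3), 3, 1)), q))
}

# small Gaussian mixture with stats, for sampler fixtures
small_pair_stats <- function(n = 15, d1 = 5, d2 = 2, seed = 4, q = 3L) {
  ds <- make_gaussian_pair(d1, d2, n = n, seed = seed)
  neighbor_stats(ds$data, q = q)
}

# direct Pareto(d) sample of ratio statistics
rpareto_mu <- function(n, d) runif(n)^(-1 / d)

# synthetic neighbor_stats with prescribed mu on a line (valid structure,
# arbitrary ratios) -- used where only the mu-likelihood matters
stats_with_mu <- function(mu, q = 2L) {
  n <- length(mu)
  s <- compute_mu(find_neighbors(compute_distances(matrix(seq_len(n)^1.1, n, 1)), q))
  s$mu <- mu
  s$V <- sum(log(mu))
  s
}
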