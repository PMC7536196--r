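#' Random initial state of a Gibbs chain
#'
#' Labels uniform over `1..K`, dimensions from their Gamma priors,
#' proportions from the Dirichlet prior; the log-posterior is evaluated at
#' the drawn state. Draws consume the current R RNG stream, so seeding is
#' the caller's responsibility (see [run_chain()]).
#'
#' @param stats a `neighbor_stats` object with `mu` filled.
#' @param cfg a [hidalgo_config()].
#' @return list `(z, d, p, log_post)`.
#' @export
init_state <- function(stats, cfg) {
  K <- cfg$K
  z <- if (K == 1L) rep(1L, stats$n) else
    sample.int(K, stats$n, replace = TRUE)
  d <- rgamma(K, shape = cfg$a, rate = cfg$b)
  p <- if (K == 1L) 1 else {
    g <- rgamma(K, shape = cfg$c, rate = 1)
    g / sum(g)
  }
  state <- list(z = z, d = d, p = p)
  state$log_post <- log_posterior(state, stats, cfg)
  state
}

# conditional Gamma parameters of the dimension of each component:
# shape a_k + N_k, rate b_k + V_k (empty components fall back to the prior
# automatically since N_k = 0, V_k = 0)
d_conditional_params <- function(z, stats, cfg) {
  counts <- tabulate(z, cfg$K)
  lmu <- log(stats$mu)
  Vk <- vapply(seq_len(cfg$K), function(k) sum(lmu[z == k]), numeric(1))
  list(shape = cfg$a + counts, rate = cfg$b + Vk)
}

#' Gibbs update of the manifold dimensions
#'
#' The Pareto likelihood is conjugate to the Gamma prior: given labels,
#' `d_k ~ Gamma(a_k + N_k, b_k + V_k)` with `V_k` the sum of `log mu` over
#' the members of component k.
#'
#' @inheritParams init_state
#' @param state current sampler state.
#' @return the state with `d` redrawn.
#' @export
sample_d <- function(state, stats, cfg) {
  par <- d_conditional_params(state$z, stats, cfg)
  state$d <- vapply(seq_len(cfg$K), function(k)
    rgamma(1, shape = par$shape[k], rate = par$rate[k]), numeric(1))
  state
}

#' Gibbs update of the mixing proportions
#'
#' The partition factor of the neighbourhood term depends on the component
#' sizes but not on `p`, so the conditional is exactly
#' `Dirichlet(c_1 + N_1, ..., c_K + N_K)`.
#'
#' @inheritParams sample_d
#' @return the state with `p` redrawn.
#' @export
sample_p <- function(state, cfg) {
  counts <- tabulate(state$z, cfg$K)
  g <- vapply(seq_len(cfg$K), function(k)
    rgamma(1, shape = cfg$c[k] + counts[k], rate = 1), numeric(1))
  state$p <- g / sum(g)
  state
}

#' Conditional log-weights of one point's label
#'
#' For each candidate component k, the log of the full conditional
#' probability that `z_i = k`, up to an additive constant shared by all k:
#' mixture weight and Pareto density of `mu_i`, the homogeneity reward for
#' point i's own neighbour row and for every row listing i as a neighbour,
#' and the change of the total partition-factor term caused by moving i
#' into component k.
#'
#' @param i point index.
#' @inheritParams sample_d
#' @return length-K vector of log-weights.
#' @export
z_logweights <- function(i, state, stats, cfg) {
  K <- cfg$K
  z <- state$z
  m <- tabulate(z, K)
  m[z[i]] <- m[z[i]] - 1L            # counts with i removed
  lmu_i <- log(stats$mu[i])
  beta <- log(cfg$xi) - log1p(-cfg$xi)
  cnt <- tabulate(z[stats$neighbor_idx[i, ]], K) +
    tabulate(z[setdiff(stats$in_lists[[i]], i)], K)
  lzm  <- partition_function(cfg$xi, m, stats$n, cfg$q, log = TRUE)
  lzm1 <- partition_function(cfg$xi, m + 1L, stats$n, cfg$q, log = TRUE)
  log(state$p) + log(state$d) - (state$d + 1) * lmu_i + beta * cnt +
    m * lzm - (m + 1L) * lzm1
}

#' One systematic Gibbs sweep (reference implementation)
#'
#' Updates every label in index order from its full conditional (component
#' counts refreshed after each draw), then redraws `d` and `p` from their
#' conjugate conditionals and re-evaluates the log-posterior. This pure-R
#' path defines the sampler's semantics; the compiled chain used by
#' [run_chain()] reproduces it draw for draw.
#'
#' @inheritParams sample_d
#' @return the updated state.
#' @export
gibbs_sweep <- function(state, stats, cfg) {
  for (i in seq_len(stats$n)) {
    lw <- z_logweights(i, state, stats, cfg)
    w <- exp(lw - max(lw))
    u <- runif(1) * sum(w)
    k <- which(cumsum(w) >= u)[1]
    if (is.na(k)) k <- cfg$K
    state$z[i] <- k
  }
  state <- sample_d(state, stats, cfg)
  state <- sample_p(state, cfg)
  state$log_post <- log_posterior(state, stats, cfg)
  state
}

#' Run one Gibbs chain
#'
#' Seeds the RNG, draws a random initial state and performs
#' `cfg$n_sweeps` sweeps, retaining the final `cfg$keep_fraction` of them
#' (`S = ceiling(keep_fraction * n_sweeps)` samples) for estimation. The
#' full log-posterior series is recorded for convergence inspection. A
#' label-switch monitor reports whether the identity of the largest
#' component changed within the retained samples (reported, not corrected).
#'
#' @inheritParams init_state
#' @param chain_seed RNG seed of this chain (default `cfg$seed`).
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference).
#' @param record_z also keep the retained label samples (S x N matrix;
#'   memory heavy, meant for small-fixture diagnostics).
#' @return an object of class `hidalgo_trace`: retained samples `d`, `p`
#'   (S x K), per-sweep component sizes `counts` (S x K), label tallies
#'   `z_tally` (N x K summing to S per point), `log_post` (length
#'   `n_sweeps`), `z_last`, and `S`.
#' @export
run_chain <- function(stats, cfg, chain_seed = cfg$seed,
                      engine = c("cpp", "r"), record_z = FALSE) {
  engine <- match.arg(engine)
  stopifnot(inherits(stats, "neighbor_stats"), !is.null(stats$mu))
  if (stats$q != cfg$q)
    stop("stats built with q = ", stats$q, " but config asks q = ", cfg$q)
  set.seed(chain_seed)
  state <- init_state(stats, cfg)
  n <- stats$n
  S <- as.integer(ceiling(cfg$keep_fraction * cfg$n_sweeps))
  if (engine == "cpp") {
    inl <- stats$in_lists
    in_len <- lengths(inl)
    in_ptr <- c(0L, cumsum(in_len))
    in_idx <- unlist(inl, use.names = FALSE) - 1L
    res <- gibbs_chain_cpp(log(stats$mu), stats$neighbor_idx - 1L,
                           in_ptr, as.integer(in_idx),
                           state$z, state$d, state$p,
                           cfg$K, cfg$xi, cfg$q,
                           cfg$a, cfg$b, cfg$c,
                           cfg$n_sweeps, S, record_z)
  } else {
    K <- cfg$K
    res <- list(d = matrix(NA_real_, S, K), p = matrix(NA_real_, S, K),
                counts = matrix(NA_integer_, S, K),
                z_tally = matrix(0L, n, K),
                log_post = numeric(cfg$n_sweeps), z_last = NULL)
    if (record_z) res$z <- matrix(NA_integer_, S, n)
    first_kept <- cfg$n_sweeps - S + 1L
    for (s in seq_len(cfg$n_sweeps)) {
      state <- gibbs_sweep(state, stats, cfg)
      res$log_post[s] <- state$log_post
      if (s >= first_kept) {
        j <- s - first_kept + 1L
        res$d[j, ] <- state$d
        res$p[j, ] <- state$p
        res$counts[j, ] <- tabulate(state$z, K)
        res$z_tally[cbind(seq_len(n), state$z)] <-
          res$z_tally[cbind(seq_len(n), state$z)] + 1L
        if (record_z) res$z[j, ] <- state$z
      }
    }
    res$z_last <- state$z
  }
  res$S <- S
  res$seed <- chain_seed
  # label-switch monitor: identity of the largest component in retained sweeps
  dom <- apply(res$counts, 1L, which.max)
  res$label_switch <- length(unique(dom)) > 1L
  class(res) <- "hidalgo_trace"
  res
}

#' Fit the heterogeneous-dimension model
#'
#' Runs `n_chains` independent Gibbs chains (seeds `seed + 0 ..
#' n_chains - 1`) and summarizes the best one, ranked by mean retained
#' log-posterior with ties broken by the maximum. Posterior means and SDs
#' of the dimensions and proportions, membership probabilities
#' `pi[i, k] = Pr(z_i = k)` (retained-sample frequencies), and hard labels
#' (component k when `pi > threshold`, else 0 = unassigned) are reported,
#' together with `L`, the mean retained log-posterior used for model
#' selection across K.
#'
#' @param x coordinate matrix, distance matrix (`distances = TRUE`) or a
#'   prebuilt `neighbor_stats` object.
#' @param K number of manifolds; ignored when `config` is given.
#' @param ... further arguments to [hidalgo_config()].
#' @param config a complete [hidalgo_config()] (overrides `K` and `...`).
#' @param metric,period,distances,jitter input handling, see
#'   [neighbor_stats()].
#' @param engine `"cpp"` or `"r"`.
#' @return an object of class `hidalgo_fit`.
#' @examples
#' set.seed(7)
#' bench <- make_gaussian_pair(d1 = 8, n = 150, center_offset = 10, seed = 7)
#' fit <- hidalgo(bench$data, K = 2, n_sweeps = 1500, n_chains = 2, seed = 1)
#' fit$d_mean
#' compare_labels(fit, bench$labels)$nmi
#' @export
hidalgo <- function(x, K = 2L, ..., config = NULL,
                    metric = "euclidean", period = 2 * pi,
                    distances = FALSE, jitter = NULL,
                    engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  cfg <- if (is.null(config)) hidalgo_config(K = K, ...) else config
  stats <- if (inherits(x, "neighbor_stats")) x else
    neighbor_stats(as.matrix(x), q = cfg$q, metric = metric,
                   period = period, distances = distances, jitter = jitter)
  traces <- lapply(seq_len(cfg$n_chains) - 1L, function(m)
    run_chain(stats, cfg, chain_seed = cfg$seed + m, engine = engine))
  retained <- lapply(traces, function(tr)
    tr$log_post[(cfg$n_sweeps - tr$S + 1L):cfg$n_sweeps])
  mean_lp <- vapply(retained, mean, numeric(1))
  max_lp <- vapply(traces, function(tr) max(tr$log_post), numeric(1))
  best <- order(-mean_lp, -max_lp)[1L]
  tr <- traces[[best]]
  pi_mat <- tr$z_tally / tr$S
  labels <- apply(pi_mat, 1L, function(row) {
    k <- which.max(row)
    if (row[k] > cfg$threshold) k else 0L
  })
  if (tr$label_switch)
    message("label-switch monitor: dominant component changed within the ",
            "retained samples of the best chain")
  structure(list(
    d_mean = colMeans(tr$d), d_sd = apply(tr$d, 2L, sd),
    p_mean = colMeans(tr$p),
    pi = pi_mat, labels = as.integer(labels),
    L = mean_lp[best], best_chain = best,
    diagnostics = list(mean_log_post = mean_lp, max_log_post = max_lp,
                       label_switch = vapply(traces, `[[`, logical(1),
                                             "label_switch")),
    trace = tr, config = cfg, n = stats$n),
    class = "hidalgo_fit")
}

#' @export
print.hidalgo_fit <- function(x, digits = 3, ...) {
  cfg <- x$config
  cat("Heterogeneous intrinsic dimension fit (K = ", cfg$K, ", q = ", cfg$q,
      ", xi = ", cfg$xi, ")\n", sep = "")
  tab <- data.frame(d_mean = round(x$d_mean, digits),
                    d_sd = round(x$d_sd, digits),
                    p_mean = round(x$p_mean, digits),
                    n_assigned = vapply(seq_len(cfg$K), function(k)
                      sum(x$labels == k), integer(1)))
  print(tab)
  cat("unassigned (pi <= ", cfg$threshold, "): ", sum(x$labels == 0L),
      " of ", x$n, "\n", sep = "")
  cat("mean retained log-posterior L = ", format(x$L, digits = 8),
      "  (best of ", cfg$n_chains, " chains)\n", sep = "")
  invisible(x)
}
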