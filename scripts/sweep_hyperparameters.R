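#!/usr/bin/env Rscript
# Sweep of the working point (q, xi) over synthetic benchmarks.
#
# Usage: Rscript scripts/sweep_hyperparameters.R [--seed <int>] [--out <path>]
#
# For each (q, xi) on a small grid, fits the two-Gaussian benchmark
# (dims 8 and 4, N = 1000 each) and the five-Gaussian benchmark, and
# records the NMI against ground truth and the unassigned fraction.
# Scaled to 1e4 sweeps and 2 chains per cell; roughly half an hour on one
# CPU for the full grid.

suppressPackageStartupMessages(library(hidalgo))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}
seed <- as.integer(get_arg("--seed", "1"))
out_path <- get_arg("--out", "results/hyperparameter_sweep.csv")
dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)

grid <- expand.grid(q = c(1L, 2L, 3L, 5L),
                    xi = c(0.55, 0.65, 0.75, 0.8, 0.9))
pair <- make_gaussian_pair(8, 4, n = 1000, seed = seed)
five <- make_five_gaussians(curved = FALSE, n = 1000, seed = seed)

rows <- lapply(seq_len(nrow(grid)), function(i) {
  q <- grid$q[i]; xi <- grid$xi[i]
  out <- data.frame(q = q, xi = xi)
  for (bench in c("pair", "five")) {
    ds <- get(bench)
    K <- length(unique(ds$labels))
    fit <- hidalgo(ds$data, K = K, q = q, xi = xi, n_sweeps = 10000,
                   n_chains = 2, seed = seed)
    cmp <- compare_labels(fit, ds$labels)
    out[[paste0(bench, "_nmi")]] <- cmp$nmi
    out[[paste0(bench, "_unassigned")]] <- cmp$n_unassigned / fit$n
  }
  message(sprintf("q = %d xi = %.2f: pair NMI %.3f, five NMI %.3f",
                  q, xi, out$pair_nmi, out$five_nmi))
  out
})
res <- do.call(rbind, rows)
write.csv(res, out_path, row.names = FALSE)
message("wrote ", out_path)
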