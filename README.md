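# hidalgo — segmentation of data by heterogeneous intrinsic dimension

Point clouds sampled from real systems often live on a *union* of
manifolds whose intrinsic dimension (ID) differs from region to region:
folded protein configurations explore more independent directions than
unfolded ones, task-active brain voxels more than idle ones. This package
identifies such regions and assigns every point to one of `K` manifolds of
different local ID, using **only pairwise distances** — no coordinates, no
density estimation. It is aimed at practitioners of unsupervised analysis
of high-dimensional scientific data (molecular dynamics observables,
imaging time series, tabular measurements) who suspect that a single
global dimension does not describe their data.

## The model

For each point, the ratio of its second- to first-nearest-neighbour
distance μ = r₂/r₁ follows a Pareto law f(μ|d) = d·μ^−(d+1) whose shape is
the *local* dimension d, regardless of the sampling density. With K
manifolds the μ's form a mixture of Pareto laws with latent labels z, but
Pareto components overlap too much for μ alone to identify the labels. The
model therefore treats the directed q-nearest-neighbour graph as data too:
with probability ξ a neighbour lies on the same manifold,

    P(N^(q) | z) = ∏ᵢ ξ^{nᵢ} (1−ξ)^{q−nᵢ} / Z(ξ, N_{zᵢ}) ,

where nᵢ counts point i's neighbours sharing its label and the partition
factor Z(ξ, N_k) = Σₙ C(N_k−1, n)·C(N−N_k, q−n)·ξⁿ(1−ξ)^{q−n} normalizes
over the possible neighbour identities given the component sizes. With
Gamma priors on the dimensions and a Dirichlet prior on the mixture
weights, the posterior over (z, d, p) is sampled by Gibbs sampling
(conjugate updates for d and p; full conditionals for each zᵢ; compiled
inner loop). Estimates use the last 10% of sweeps of the best of M chains;
point i is assigned to manifold k when its membership probability π_ik
exceeds 0.8, and is reported *unassigned* otherwise. The number of
manifolds is chosen by scanning K and comparing the mean retained
log-posterior. Working point: q = 3, ξ = 0.8 (ξ = 0.5 switches the
neighbourhood term off — a useful negative control).

## Worked example

```r
library(hidalgo)
bench <- make_gaussian_pair(d1 = 6, d2 = 2, n = 500, center_offset = 4, seed = 7)
fit <- hidalgo(bench$data, K = 2, n_sweeps = 5000, n_chains = 2, seed = 1)
print(fit)
#> Heterogeneous intrinsic dimension fit (K = 2, q = 3, xi = 0.8)
#>   d_mean  d_sd p_mean n_assigned
#> 1  5.587 0.248  0.535        533
#> 2  2.150 0.099  0.465        458
#> unassigned (pi <= 0.8): 9 of 1000
#> mean retained log-posterior L = -18287.337  (best of 2 chains)
compare_labels(fit, bench$labels)$nmi
#> [1] 0.7864414
```

The two components (true dimensions 6 and 2, five hundred points each,
overlapping Gaussian clouds) are recovered with posterior-mean dimensions
5.6 and 2.2; 9 points sit below the 0.8 membership threshold and stay
unassigned; the normalized mutual information between the assignment and
the ground truth, computed over assigned points, is 0.79. `scan_k()`
chooses K when it is unknown, `neighbor_stats()` exposes the sufficient
statistics (with periodic and norm-normalized metrics for angle and
balance-sheet data), and `write_results()` saves labels, membership
probabilities, traces and a reproducibility manifest.

A command-line wrapper ships in `inst/cli/hidalgo.R`:

```sh
Rscript inst/cli/hidalgo.R simulate --preset gauss5 --n 1000 --seed 1 --out bench
Rscript inst/cli/hidalgo.R fit --input bench/data.csv --k 5 --sweeps 20000 --chains 3 --out bench/fit
Rscript inst/cli/hidalgo.R evaluate --pred bench/fit/labels.csv --truth bench/labels.csv
```

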