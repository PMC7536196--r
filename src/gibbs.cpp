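// Compiled Gibbs chain for the heterogeneous-dimension mixture.
//
// Semantics are defined by the pure-R reference sweep (gibbs_sweep): one
// systematic scan over the labels (full conditionals with component counts
// refreshed after every draw), then conjugate updates of the dimensions and
// proportions, then the full log-posterior. All randomness flows through
// R's RNG in exactly the same order as the reference path, so a chain run
// with either engine from the same seed is bit-identical.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// log partition factor of the neighbourhood term, tabulated for every
// possible component size 0..N (size 0 mapped to size 1)
static std::vector<double> logZ_table(int N, int q, double xi) {
  std::vector<double> tab(N + 1);
  const double lxi = std::log(xi), l1xi = std::log1p(-xi);
  std::vector<double> terms(q + 1);
  for (int s = 0; s <= N; ++s) {
    const int sz = (s == 0) ? 1 : s;
    double mx = R_NegInf;
    for (int n = 0; n <= q; ++n) {
      double t = Rf_lchoose(sz - 1.0, n) + Rf_lchoose((double)(N - sz), q - n)
        + n * lxi + (q - n) * l1xi;
      terms[n] = t;
      if (t > mx) mx = t;
    }
    if (!R_FINITE(mx)) { tab[s] = R_NegInf; continue; }
    double acc = 0.0;
    for (int n = 0; n <= q; ++n) acc += std::exp(terms[n] - mx);
    tab[s] = mx + std::log(acc);
  }
  return tab;
}

// matches R's runif(): rejects the endpoints of unif_rand()
static inline double runif01() {
  double u;
  do { u = unif_rand(); } while (u <= 0.0 || u >= 1.0);
  return u;
}

// [[Rcpp::export]]
List gibbs_chain_cpp(NumericVector lmu, IntegerMatrix nbr,
                     IntegerVector in_ptr, IntegerVector in_idx,
                     IntegerVector z0, NumericVector d0, NumericVector p0,
                     int K, double xi, int q,
                     NumericVector a, NumericVector b, NumericVector c,
                     int n_sweeps, int n_keep, bool record_z) {
  const int N = lmu.size();
  const double beta = std::log(xi) - std::log1p(-xi);
  const double lxi = std::log(xi), l1xi = std::log1p(-xi);
  std::vector<double> logZ = logZ_table(N, q, xi);

  std::vector<int> z(N);
  for (int i = 0; i < N; ++i) z[i] = z0[i] - 1;
  std::vector<double> d(K), p(K), logd(K), logp(K);
  for (int k = 0; k < K; ++k) {
    d[k] = d0[k]; p[k] = p0[k];
    logd[k] = std::log(d[k]); logp[k] = std::log(p[k]);
  }
  std::vector<int> counts(K, 0);
  std::vector<double> Vk(K, 0.0);
  for (int i = 0; i < N; ++i) { counts[z[i]]++; Vk[z[i]] += lmu[i]; }

  // K-independent prior normalizers, kept for cross-K comparability
  double prior_const = 0.0, csum = 0.0;
  for (int k = 0; k < K; ++k) {
    prior_const += a[k] * std::log(b[k]) - R::lgammafn(a[k]);
    prior_const -= R::lgammafn(c[k]);
    csum += c[k];
  }
  prior_const += R::lgammafn(csum);

  NumericMatrix d_s(n_keep, K), p_s(n_keep, K);
  IntegerMatrix counts_s(n_keep, K), z_tally(N, K);
  IntegerMatrix z_s(record_z ? n_keep : 0, record_z ? N : 0);
  NumericVector log_post(n_sweeps);

  std::vector<double> lw(K), w(K);
  std::vector<int> cnt(K);
  const int first_kept = n_sweeps - n_keep;  // 0-based sweep index

  for (int s = 0; s < n_sweeps; ++s) {
    // --- label scan ---
    for (int i = 0; i < N; ++i) {
      const int zi = z[i];
      counts[zi]--; Vk[zi] -= lmu[i];
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int t = 0; t < q; ++t) cnt[z[nbr(i, t)]]++;
      for (int j = in_ptr[i]; j < in_ptr[i + 1]; ++j) cnt[z[in_idx[j]]]++;
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) {
        const int m = counts[k];
        double v = logp[k] + logd[k] - (d[k] + 1.0) * lmu[i] + beta * cnt[k]
          + m * logZ[m] - (m + 1.0) * logZ[m + 1];
        lw[k] = v;
        if (v > mx) mx = v;
      }
      // long-double accumulation mirrors R's sum()/cumsum() exactly
      long double tot = 0.0;
      for (int k = 0; k < K; ++k) { w[k] = std::exp(lw[k] - mx); tot += w[k]; }
      const double u = runif01() * (double)tot;
      int knew = K - 1;
      long double cum = 0.0;
      for (int k = 0; k < K; ++k) {
        cum += w[k];
        if ((double)cum >= u) { knew = k; break; }
      }
      z[i] = knew;
      counts[knew]++; Vk[knew] += lmu[i];
    }
    // refresh V_k from scratch (guards against incremental round-off and
    // reproduces the reference path's summation order exactly)
    {
      std::vector<long double> acc(K, 0.0L);
      for (int i = 0; i < N; ++i) acc[z[i]] += lmu[i];
      for (int k = 0; k < K; ++k) Vk[k] = (double)acc[k];
    }
    // --- conjugate updates ---
    for (int k = 0; k < K; ++k) {
      d[k] = R::rgamma(a[k] + counts[k], 1.0 / (b[k] + Vk[k]));
      logd[k] = std::log(d[k]);
    }
    long double gsum = 0.0L;
    for (int k = 0; k < K; ++k) {
      p[k] = R::rgamma(c[k] + counts[k], 1.0);
      gsum += p[k];
    }
    for (int k = 0; k < K; ++k) {
      p[k] /= (double)gsum;
      logp[k] = std::log(p[k]);
    }
    // --- log-posterior ---
    double lp = prior_const;
    for (int k = 0; k < K; ++k) {
      lp += counts[k] * logd[k] - (d[k] + 1.0) * Vk[k];
      lp += counts[k] * logp[k];
      lp += (a[k] - 1.0) * logd[k] - b[k] * d[k] + (c[k] - 1.0) * logp[k];
      lp -= counts[k] * logZ[counts[k]];
    }
    long n_in_tot = 0;
    for (int i = 0; i < N; ++i)
      for (int t = 0; t < q; ++t)
        if (z[nbr(i, t)] == z[i]) n_in_tot++;
    lp += n_in_tot * lxi + ((long)N * q - n_in_tot) * l1xi;
    log_post[s] = lp;

    if (s >= first_kept) {
      const int j = s - first_kept;
      for (int k = 0; k < K; ++k) {
        d_s(j, k) = d[k]; p_s(j, k) = p[k]; counts_s(j, k) = counts[k];
      }
      for (int i = 0; i < N; ++i) {
        z_tally(i, z[i])++;
        if (record_z) z_s(j, i) = z[i] + 1;
      }
    }
  }

  IntegerVector z_last(N);
  for (int i = 0; i < N; ++i) z_last[i] = z[i] + 1;
  List out = List::create(
    Named("d") = d_s, Named("p") = p_s, Named("counts") = counts_s,
    Named("z_tally") = z_tally, Named("log_post") = log_post,
    Named("z_last") = z_last);
  if (record_z) out["z"] = z_s;
  return out;
}
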