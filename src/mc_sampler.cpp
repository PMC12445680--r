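#include <Rcpp.h>
using namespace Rcpp;

// Metropolis Monte Carlo over titration microstates.
//
// Sites carry n_states[i] states each; global state indices are contiguous
// per site (offsets[i] .. offsets[i]+n_states[i]-1).  Microstate energy is
//   G = sum_i g[idx_i] + 1/2 sum_{i!=j} W(idx_i, idx_j)
// with W anchored so rows/columns of per-site reference states are zero.
// Moves: single-site state changes, plus joint moves for listed strongly
// coupled pairs.  Ties (dG <= 0) are always accepted.  Uses R's RNG so runs
// are reproducible under set.seed().
//
// Returns a n_blocks x S matrix of per-block mean state occupancies over the
// production sweeps.
// [[Rcpp::export]]
NumericMatrix mc_sample_cpp(IntegerVector n_states, IntegerVector offsets,
                            NumericVector g, NumericMatrix W,
                            IntegerVector init, LogicalVector is_free,
                            int sweeps, int burn, IntegerMatrix pairs,
                            double kT, int n_blocks) {
  const int n = n_states.size();
  const int S = g.size();
  std::vector<int> cur(init.begin(), init.end());   // global 0-based indices
  std::vector<int> free_sites;
  for (int i = 0; i < n; ++i) if (is_free[i]) free_sites.push_back(i);
  const int nf = free_sites.size();
  if (nf == 0) stop("no free sites to sample");
  const int npairs = pairs.ncol();

  RNGScope scope;

  auto delta_single = [&](int i, int snew) {
    double dg = g[snew] - g[cur[i]];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      dg += W(snew, cur[j]) - W(cur[i], cur[j]);
    }
    return dg;
  };

  auto propose_state = [&](int i) {
    // uniform over the site's states excluding the current one
    int ns = n_states[i];
    int cur_local = cur[i] - offsets[i];
    int k = (int)(unif_rand() * (ns - 1));
    if (k >= ns - 1) k = ns - 2;
    if (k >= cur_local) k += 1;
    return offsets[i] + k;
  };

  auto sweep_once = [&]() {
    for (int m = 0; m < nf; ++m) {
      int i = free_sites[(int)(unif_rand() * nf) % nf];
      int snew = propose_state(i);
      double dg = delta_single(i, snew);
      if (dg <= 0.0 || unif_rand() < std::exp(-dg / kT)) cur[i] = snew;
    }
    if (npairs > 0) {
      int p = (int)(unif_rand() * npairs) % npairs;
      int i = pairs(0, p), j = pairs(1, p);
      int si = propose_state(i), sj = propose_state(j);
      double dg = g[si] - g[cur[i]] + g[sj] - g[cur[j]];
      for (int kk = 0; kk < n; ++kk) {
        if (kk == i || kk == j) continue;
        dg += W(si, cur[kk]) - W(cur[i], cur[kk]);
        dg += W(sj, cur[kk]) - W(cur[j], cur[kk]);
      }
      dg += W(si, sj) - W(cur[i], cur[j]);
      if (dg <= 0.0 || unif_rand() < std::exp(-dg / kT)) {
        cur[i] = si; cur[j] = sj;
      }
    }
  };

  for (int s = 0; s < burn; ++s) sweep_once();

  NumericMatrix blocks(n_blocks, S);
  const int per_block = sweeps / n_blocks;
  for (int b = 0; b < n_blocks; ++b) {
    for (int s = 0; s < per_block; ++s) {
      sweep_once();
      for (int i = 0; i < n; ++i) blocks(b, cur[i]) += 1.0;
    }
    for (int k = 0; k < S; ++k) blocks(b, k) /= per_block;
  }
  return blocks;
}
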