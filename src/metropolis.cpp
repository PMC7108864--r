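#include <Rcpp.h>
using namespace Rcpp;

// Single-site-flip Metropolis sampler for an Ising model over {-1,+1}^N.
// One sweep = N proposed flips at uniformly chosen sites; one pattern is
// recorded per sweep after a burn-in. Energy convention:
//   E(s) = -sum_i h_i s_i - 0.5 * sum_ij J_ij s_i s_j   (J symmetric, diag 0)
// so flipping site i changes the energy by dE = 2 s_i (h_i + sum_j J_ij s_j).
// Uses R's RNG stream, so set.seed() in R makes the chain deterministic.
// [[Rcpp::export(name = ".metropolis_chain")]]
IntegerMatrix metropolis_chain(NumericVector h, NumericMatrix J,
                               int n_samples, int burnin) {
  const int N = h.size();
  IntegerMatrix out(n_samples, N);
  std::vector<int> s(N);
  for (int i = 0; i < N; ++i) s[i] = (unif_rand() < 0.5) ? -1 : 1;

  const int total_sweeps = burnin + n_samples;
  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    for (int p = 0; p < N; ++p) {
      int i = (int)(unif_rand() * N);
      if (i == N) i = N - 1;
      double field = h[i];
      for (int j = 0; j < N; ++j) field += J(i, j) * s[j];
      double dE = 2.0 * s[i] * field;
      if (dE <= 0.0 || unif_rand() < std::exp(-dE)) s[i] = -s[i];
    }
    if (sweep >= burnin) {
      int row = sweep - burnin;
      for (int j = 0; j < N; ++j) out(row, j) = s[j];
    }
  }
  return out;
}
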