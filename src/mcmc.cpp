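#include <Rcpp.h>
using namespace Rcpp;

// Random-walk Metropolis sampler for the log topic rates g = log(p) of one
// feature under the Poisson model x_i ~ Poisson(s_i * sum_k L[i,k] p_k)
// with a flat (improper) prior on p. Working on the log scale introduces a
// Jacobian factor p*_k / p_k in the acceptance ratio.
//
// Only cells with x_i > 0 enter the log-rate part of the likelihood
// difference; the linear part collapses to sum_i s_i L[i,k] * (p*_k - p_k),
// with the per-topic totals supplied precomputed in sum_sl. theta is
// maintained only at the nonzero cells.
//
// Inputs:
//   nz_idx  0-based row indices of cells with x_i > 0 (may include
//           pseudocount rows)
//   nz_x    the corresponding counts (pseudocounts may be fractional)
//   L       dense (n x K) membership matrix including any pseudocount rows
//   sum_sl  length-K vector of sum_i s_i L[i,k] over ALL rows
//   g0      initial state, log p
//   ns      number of states to simulate
//   sigma   sd of the Gaussian proposal
//
// Returns an ns x K matrix of sampled g vectors. Uses R's RNG, so results
// are reproducible under set.seed().
// [[Rcpp::export(name = ".mcmc_rates_cpp")]]
NumericMatrix mcmc_rates_cpp(IntegerVector nz_idx, NumericVector nz_x,
                             NumericMatrix L, NumericVector sum_sl,
                             NumericVector g0, int ns, double sigma) {
  const int K = L.ncol();
  const int nnz = nz_idx.size();
  NumericMatrix out(ns, K);
  std::vector<double> g(g0.begin(), g0.end());
  std::vector<double> p(K);
  for (int k = 0; k < K; k++) p[k] = std::exp(g[k]);

  // theta at nonzero cells
  std::vector<double> theta(nnz, 0.0);
  for (int t = 0; t < nnz; t++) {
    const int i = nz_idx[t];
    double th = 0;
    for (int k = 0; k < K; k++) th += L(i, k) * p[k];
    theta[t] = th;
  }

  std::vector<double> theta_new(nnz);
  GetRNGstate();
  for (int s = 0; s < ns; s++) {
    int k = (int)(unif_rand() * K);
    if (k >= K) k = K - 1;
    const double delta = norm_rand() * sigma;
    const double gk_new = g[k] + delta;
    const double pk_new = std::exp(gk_new);
    const double dp = pk_new - p[k];
    double log_acc = delta; // Jacobian term log(p*_k / p_k)
    log_acc -= sum_sl[k] * dp;
    bool ok = true;
    for (int t = 0; t < nnz; t++) {
      const double lik = L(nz_idx[t], k);
      double th = theta[t] + lik * dp;
      if (lik != 0.0) {
        if (th <= 0) { ok = false; break; }
        log_acc += nz_x[t] * (std::log(th) - std::log(theta[t]));
      }
      theta_new[t] = th;
    }
    if (ok && std::log(unif_rand()) < log_acc) {
      g[k] = gk_new;
      p[k] = pk_new;
      std::swap(theta, theta_new);
    }
    for (int kk = 0; kk < K; kk++) out(s, kk) = g[kk];
  }
  PutRNGstate();
  return out;
}
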