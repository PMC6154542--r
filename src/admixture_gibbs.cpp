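#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Collapsed-z Gibbs sweep engine for the binary admixture model:
//   q_i     ~ Dirichlet(1,...,1)          (membership of individual i)
//   z_ij    ~ Categorical(q_i)            (cluster of origin of band score)
//   x_ij    ~ Bernoulli(theta[z_ij, j])   (band presence)
//   theta_kj ~ Beta(1, 1)
// z is sampled per sweep but only its sufficient statistics (per-individual
// cluster counts, per-cluster band tallies) are kept.  The traced
// log-likelihood is the observed-data mixture log-likelihood
// sum_ij log sum_k q_ik theta_kj^x (1-theta_kj)^(1-x) evaluated at the
// state entering each sweep; the per-(i,j) mixture sums are exactly the
// normalizing constants of the z draws, so the trace costs nothing extra.
// Uses R's RNG, so set.seed() on the R side makes runs reproducible.

// [[Rcpp::export]]
List gibbs_admixture(IntegerMatrix X, int K, int iterations, int burnin) {
  const int n = X.nrow(), J = X.ncol();
  const double eps = 1e-12;

  // q and theta are stored cluster-major (K x n, K x J) for locality in
  // the (j, i, k) inner loops
  std::vector<double> q(K * n), theta(K * J);
  std::vector<double> qsum(K * n, 0.0), thetasum(K * J, 0.0);
  std::vector<int> nik(K * n), s1(K * J), s0(K * J);
  std::vector<double> p(K), th1(K), th0(K);
  NumericVector trace(iterations);

  // column-major copy of X
  std::vector<int> x(n * J);
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < n; ++i) x[i + n * j] = X(i, j);

  // init: theta ~ Beta(1,1) = U(0,1); q_i ~ Dirichlet(1)
  for (int t = 0; t < K * J; ++t) theta[t] = unif_rand();
  for (int i = 0; i < n; ++i) {
    double tot = 0.0;
    for (int k = 0; k < K; ++k) { q[k + K * i] = R::rgamma(1.0, 1.0) + eps; tot += q[k + K * i]; }
    for (int k = 0; k < K; ++k) q[k + K * i] /= tot;
  }

  int kept = 0;
  double llsum = 0.0;

  for (int it = 0; it < iterations; ++it) {
    std::fill(nik.begin(), nik.end(), 0);
    std::fill(s1.begin(), s1.end(), 0);
    std::fill(s0.begin(), s0.end(), 0);

    // z-update, accumulating sufficient statistics and the log-likelihood
    double ll = 0.0;
    for (int j = 0; j < J; ++j) {
      for (int k = 0; k < K; ++k) {
        th1[k] = theta[k + K * j];
        th0[k] = 1.0 - th1[k];
      }
      const int *xj = &x[n * j];
      for (int i = 0; i < n; ++i) {
        const double *qi = &q[K * i];
        const double *th = xj[i] ? th1.data() : th0.data();
        double tot = 0.0;
        for (int k = 0; k < K; ++k) { p[k] = qi[k] * th[k]; tot += p[k]; }
        ll += std::log(tot);
        double u = unif_rand() * tot;
        int z = 0;
        while (z < K - 1 && u > p[z]) { u -= p[z]; ++z; }
        ++nik[z + K * i];
        if (xj[i]) ++s1[z + K * j]; else ++s0[z + K * j];
      }
    }
    trace[it] = ll;

    // theta | z, x
    for (int j = 0; j < J; ++j)
      for (int k = 0; k < K; ++k) {
        double th = R::rbeta(1.0 + s1[k + K * j], 1.0 + s0[k + K * j]);
        if (th < eps) th = eps;
        if (th > 1.0 - eps) th = 1.0 - eps;
        theta[k + K * j] = th;
      }

    // q | z
    for (int i = 0; i < n; ++i) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(1.0 + nik[k + K * i], 1.0) + eps;
        q[k + K * i] = g;
        tot += g;
      }
      for (int k = 0; k < K; ++k) q[k + K * i] /= tot;
    }

    if (it >= burnin) {
      ++kept;
      llsum += ll;
      for (int t = 0; t < K * n; ++t) qsum[t] += q[t];
      for (int t = 0; t < K * J; ++t) thetasum[t] += theta[t];
    }
  }

  NumericMatrix qmean(n, K), thetamean(K, J);
  for (int i = 0; i < n; ++i) {
    double tot = 0.0;
    for (int k = 0; k < K; ++k) tot += qsum[k + K * i];
    for (int k = 0; k < K; ++k) qmean(i, k) = qsum[k + K * i] / tot;
  }
  for (int j = 0; j < J; ++j)
    for (int k = 0; k < K; ++k) thetamean(k, j) = thetasum[k + K * j] / kept;

  return List::create(_["q"] = qmean, _["theta"] = thetamean,
                      _["loglik_trace"] = trace,
                      _["mean_loglik"] = llsum / kept);
}

// Mixture log-likelihood at fixed parameters; exposed for invariance
// checks (label switching must leave it unchanged).
// [[Rcpp::export]]
double admixture_loglik(IntegerMatrix X, NumericMatrix q,
                        NumericMatrix theta) {
  const int n = X.nrow(), J = X.ncol(), K = q.ncol();
  double ll = 0.0;
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        const double th = theta(k, j);
        s += q(i, k) * (X(i, j) ? th : 1.0 - th);
      }
      ll += std::log(s);
    }
  return ll;
}
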