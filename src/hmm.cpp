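#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for a discrete-emission HMM.
// obs: 0-based symbol indices; pi: K; A: K x K; B: K x M.
// Returns log-likelihood plus the expected-count accumulators the
// Baum-Welch M-step needs (gamma at t=0, summed xi, per-symbol gamma sums).
// Hot loops use contiguous row-major copies; NumericMatrix element access
// is too slow for 1e5-step sequences.
// [[Rcpp::export]]
List hmm_forward_backward(IntegerVector obs, NumericVector pi,
                          NumericMatrix A_, NumericMatrix B_) {
  const int n = obs.size();
  const int K = pi.size();
  const int M = B_.ncol();

  std::vector<double> A((size_t)K * K), B((size_t)K * M);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k) A[(size_t)j * K + k] = A_(j, k);
  for (int k = 0; k < K; ++k)
    for (int m = 0; m < M; ++m) B[(size_t)k * M + m] = B_(k, m);

  std::vector<double> alpha((size_t)n * K), beta((size_t)n * K), scale(n);

  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha[k] = pi[k] * B[(size_t)k * M + obs[0]];
    s += alpha[k];
  }
  if (s <= 0.0) stop("zero-probability symbol at step 1");
  scale[0] = s;
  for (int k = 0; k < K; ++k) alpha[k] /= s;

  for (int t = 1; t < n; ++t) {
    const double* ap = &alpha[(size_t)(t - 1) * K];
    double* ac = &alpha[(size_t)t * K];
    const int o = obs[t];
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += ap[j] * A[(size_t)j * K + k];
      a *= B[(size_t)k * M + o];
      ac[k] = a;
      s += a;
    }
    if (s <= 0.0) stop("zero-probability symbol at step " +
                       std::to_string(t + 1));
    scale[t] = s;
    for (int k = 0; k < K; ++k) ac[k] /= s;
  }

  // backward
  for (int k = 0; k < K; ++k) beta[(size_t)(n - 1) * K + k] = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    double* bc = &beta[(size_t)t * K];
    const double* bn = &beta[(size_t)(t + 1) * K];
    const int o = obs[t + 1];
    const double sc = scale[t + 1];
    for (int j = 0; j < K; ++j) {
      double b = 0.0;
      for (int k = 0; k < K; ++k)
        b += A[(size_t)j * K + k] * B[(size_t)k * M + o] * bn[k];
      bc[j] = b / sc;
    }
  }

  double loglik = 0.0;
  for (int t = 0; t < n; ++t) loglik += std::log(scale[t]);

  // accumulators
  NumericVector gamma0(K), gamma_tot(K), gamma_tot_nolast(K);
  NumericMatrix xi_sum(K, K), gamma_sym(K, M);

  for (int t = 0; t < n; ++t) {
    const double* ap = &alpha[(size_t)t * K];
    const double* bp = &beta[(size_t)t * K];
    const int o = obs[t];
    for (int k = 0; k < K; ++k) {
      double g = ap[k] * bp[k];
      if (t == 0) gamma0[k] = g;
      gamma_sym(k, o) += g;
      gamma_tot[k] += g;
      if (t < n - 1) gamma_tot_nolast[k] += g;
    }
  }
  for (int t = 0; t < n - 1; ++t) {
    const double* ap = &alpha[(size_t)t * K];
    const double* bn = &beta[(size_t)(t + 1) * K];
    const int o = obs[t + 1];
    const double sc = scale[t + 1];
    for (int j = 0; j < K; ++j) {
      const double aj = ap[j];
      if (aj == 0.0) continue;
      for (int k = 0; k < K; ++k)
        xi_sum(j, k) += aj * A[(size_t)j * K + k] *
                        B[(size_t)k * M + o] * bn[k] / sc;
    }
  }

  return List::create(_["loglik"] = loglik, _["gamma0"] = gamma0,
                      _["xi_sum"] = xi_sum, _["gamma_sym"] = gamma_sym,
                      _["gamma_tot"] = gamma_tot,
                      _["gamma_tot_nolast"] = gamma_tot_nolast);
}

// Log-space Viterbi; ties broken toward the lower state index.
// Returns 1-based path and the log-probability of the best path.
// [[Rcpp::export]]
List hmm_viterbi(IntegerVector obs, NumericVector logpi,
                 NumericMatrix logA_, NumericMatrix logB_) {
  const int n = obs.size();
  const int K = logpi.size();
  const int M = logB_.ncol();
  std::vector<double> logA((size_t)K * K), logB((size_t)K * M);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k) logA[(size_t)j * K + k] = logA_(j, k);
  for (int k = 0; k < K; ++k)
    for (int m = 0; m < M; ++m) logB[(size_t)k * M + m] = logB_(k, m);

  std::vector<double> delta((size_t)n * K);
  std::vector<int> psi((size_t)n * K);

  for (int k = 0; k < K; ++k)
    delta[k] = logpi[k] + logB[(size_t)k * M + obs[0]];
  for (int t = 1; t < n; ++t) {
    const double* dp = &delta[(size_t)(t - 1) * K];
    double* dc = &delta[(size_t)t * K];
    const int o = obs[t];
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf;
      int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = dp[j] + logA[(size_t)j * K + k];
        if (v > best) { best = v; arg = j; }  // strict > keeps lowest index
      }
      dc[k] = best + logB[(size_t)k * M + o];
      psi[(size_t)t * K + k] = arg;
    }
  }

  IntegerVector path(n);
  double best = R_NegInf;
  int arg = 0;
  for (int k = 0; k < K; ++k) {
    double v = delta[(size_t)(n - 1) * K + k];
    if (v > best) { best = v; arg = k; }
  }
  if (!R_finite(best)) stop("zero-probability symbol sequence under model");
  path[n - 1] = arg;
  for (int t = n - 2; t >= 0; --t)
    path[t] = psi[(size_t)(t + 1) * K + path[t + 1]];
  for (int t = 0; t < n; ++t) path[t] += 1;

  return List::create(_["path"] = path, _["log_prob"] = best);
}
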