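#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// log(sum(exp(x))) over n contiguous doubles, guarded against -Inf
static double logsumexp(const double* x, int n) {
  double m = R_NegInf;
  for (int i = 0; i < n; ++i) if (x[i] > m) m = x[i];
  if (!R_FINITE(m)) return m;
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::exp(x[i] - m);
  return m + std::log(s);
}

// Exact HMM smoothing in log space.
// logB: T x K per-trial emission log-likelihoods, logA: K x K log transition
// matrix, logpi: length-K log initial distribution. Returns per-trial state
// posteriors (gamma), summed pairwise transition posteriors (xi, K x K) and
// the log marginal likelihood of the session.
// [[Rcpp::export]]
List fb_cpp(NumericMatrix logB, NumericMatrix logA, NumericVector logpi) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix la(T, K), lb(T, K), gamma(T, K);
  NumericMatrix xi(K, K);
  std::vector<double> buf(K);

  for (int k = 0; k < K; ++k) la(0, k) = logpi[k] + logB(0, k);
  for (int t = 1; t < T; ++t)
    for (int j = 0; j < K; ++j) {
      for (int k = 0; k < K; ++k) buf[k] = la(t - 1, k) + logA(k, j);
      la(t, j) = logsumexp(buf.data(), K) + logB(t, j);
    }

  std::vector<double> last(K);
  for (int k = 0; k < K; ++k) last[k] = la(T - 1, k);
  const double loglik = logsumexp(last.data(), K);

  for (int k = 0; k < K; ++k) lb(T - 1, k) = 0.0;
  for (int t = T - 2; t >= 0; --t)
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j)
        buf[j] = logA(k, j) + logB(t + 1, j) + lb(t + 1, j);
      lb(t, k) = logsumexp(buf.data(), K);
    }

  for (int t = 0; t < T; ++t) {
    for (int k = 0; k < K; ++k) buf[k] = la(t, k) + lb(t, k);
    const double norm = logsumexp(buf.data(), K);
    for (int k = 0; k < K; ++k) gamma(t, k) = std::exp(buf[k] - norm);
  }

  for (int t = 0; t + 1 < T; ++t)
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < K; ++j)
        xi(k, j) += std::exp(la(t, k) + logA(k, j) + logB(t + 1, j) +
                             lb(t + 1, j) - loglik);

  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["loglik"] = loglik);
}

// Gamma-weighted multinomial logistic negative log-likelihood with an
// optional ridge penalty (lambda = 1/prior variance for MAP fits).
// par: (D weights + 1 bias) per free category, reference category last with
// all parameters fixed at zero. U: T x D inputs, y: 1-based category codes,
// g: per-trial posterior weights.
static double mnl_core(const NumericVector& par, const NumericMatrix& U,
                       const IntegerVector& y, const NumericVector& g,
                       int C, double lambda, NumericVector* grad) {
  const int T = U.nrow(), D = U.ncol(), F = C - 1, P = D + 1;
  std::vector<double> logits(C);
  double nll = 0.0;
  if (grad) std::fill(grad->begin(), grad->end(), 0.0);

  for (int t = 0; t < T; ++t) {
    for (int c = 0; c < F; ++c) {
      double l = par[c * P + D];  // bias
      for (int d = 0; d < D; ++d) l += par[c * P + d] * U(t, d);
      logits[c] = l;
    }
    logits[C - 1] = 0.0;
    const double lse = logsumexp(logits.data(), C);
    nll -= g[t] * (logits[y[t] - 1] - lse);
    if (grad) {
      for (int c = 0; c < F; ++c) {
        const double p = std::exp(logits[c] - lse);
        const double resid = g[t] * (p - (y[t] - 1 == c ? 1.0 : 0.0));
        for (int d = 0; d < D; ++d) (*grad)[c * P + d] += resid * U(t, d);
        (*grad)[c * P + D] += resid;
      }
    }
  }
  if (lambda > 0.0) {
    for (int i = 0; i < par.size(); ++i) {
      nll += 0.5 * lambda * par[i] * par[i];
      if (grad) (*grad)[i] += lambda * par[i];
    }
  }
  return nll;
}

// [[Rcpp::export]]
double mnl_nll_cpp(NumericVector par, NumericMatrix U, IntegerVector y,
                   NumericVector g, int C, double lambda) {
  return mnl_core(par, U, y, g, C, lambda, nullptr);
}

// value and gradient in one pass (optim queries both at the same point)
// [[Rcpp::export]]
List mnl_obj_cpp(NumericVector par, NumericMatrix U, IntegerVector y,
                 NumericVector g, int C, double lambda) {
  NumericVector grad(par.size());
  const double value = mnl_core(par, U, y, g, C, lambda, &grad);
  return List::create(_["value"] = value, _["grad"] = grad);
}

// [[Rcpp::export]]
NumericVector mnl_grad_cpp(NumericVector par, NumericMatrix U,
                           IntegerVector y, NumericVector g, int C,
                           double lambda) {
  NumericVector grad(par.size());
  mnl_core(par, U, y, g, C, lambda, &grad);
  return grad;
}
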