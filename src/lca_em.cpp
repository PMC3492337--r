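#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Polytomous latent class model EM.
//
// y:  n x J integer matrix of 1-based category indices (no NA; listwise
//     deletion happens in R before the call)
// L:  J level counts
// pi0, p0: starting values; p0 is a list of L_j x K matrices
// prob_floor: lower bound applied to conditional probabilities in the
//     M-step (renormalised afterwards) so no observed pattern can get
//     exactly zero mass.

static double logsumexp(const std::vector<double>& a) {
  double m = a[0];
  for (size_t k = 1; k < a.size(); ++k) if (a[k] > m) m = a[k];
  double s = 0.0;
  for (size_t k = 0; k < a.size(); ++k) s += std::exp(a[k] - m);
  return m + std::log(s);
}

// one E-step: fills post (n x K), returns log-likelihood
static double e_step_impl(const IntegerMatrix& y,
                          const std::vector<NumericMatrix>& p,
                          const NumericVector& pi,
                          NumericMatrix& post) {
  const int n = y.nrow(), J = y.ncol(), K = pi.size();
  std::vector<double> logpi(K);
  for (int k = 0; k < K; ++k) logpi[k] = std::log(pi[k]);
  // per-variable log conditional tables
  std::vector<std::vector<double> > logp(J);
  for (int j = 0; j < J; ++j) {
    const NumericMatrix& pj = p[j];
    logp[j].resize(pj.nrow() * K);
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < pj.nrow(); ++l)
        logp[j][k * pj.nrow() + l] = std::log(pj(l, k));
  }
  double ll = 0.0;
  std::vector<double> a(K);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < K; ++k) a[k] = logpi[k];
    for (int j = 0; j < J; ++j) {
      const int yij = y(i, j) - 1;
      const int Lj = p[j].nrow();
      for (int k = 0; k < K; ++k) a[k] += logp[j][k * Lj + yij];
    }
    const double lse = logsumexp(a);
    if (!std::isfinite(lse))
      stop("degenerate response pattern: zero probability under all classes");
    for (int k = 0; k < K; ++k) post(i, k) = std::exp(a[k] - lse);
    ll += lse;
  }
  return ll;
}

// [[Rcpp::export(name = ".lca_estep_cpp")]]
List lca_estep_cpp(IntegerMatrix y, NumericVector pi, List p0) {
  const int n = y.nrow(), J = y.ncol(), K = pi.size();
  std::vector<NumericMatrix> p(J);
  for (int j = 0; j < J; ++j) p[j] = as<NumericMatrix>(p0[j]);
  NumericMatrix post(n, K);
  double ll = e_step_impl(y, p, pi, post);
  return List::create(_["posterior"] = post, _["log_likelihood"] = ll);
}

// [[Rcpp::export(name = ".lca_em_cpp")]]
List lca_em_cpp(IntegerMatrix y, NumericVector pi0, List p0,
                double tol, int max_iter, double prob_floor) {
  const int n = y.nrow(), J = y.ncol(), K = pi0.size();
  NumericVector pi = clone(pi0);
  std::vector<NumericMatrix> p(J);
  for (int j = 0; j < J; ++j) p[j] = clone(as<NumericMatrix>(p0[j]));
  NumericMatrix post(n, K);
  std::vector<double> trace;
  trace.reserve(256);
  double ll_old = R_NegInf;
  bool converged = false;
  int floor_hits = 0;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    double ll = e_step_impl(y, p, pi, post);
    trace.push_back(ll);
    if (iter > 1 &&
        std::fabs(ll - ll_old) < tol * (std::fabs(ll_old) + 1e-3)) {
      converged = true;
      break;
    }
    ll_old = ll;
    // M-step
    std::vector<double> cs(K, 0.0);
    for (int k = 0; k < K; ++k)
      for (int i = 0; i < n; ++i) cs[k] += post(i, k);
    for (int k = 0; k < K; ++k) {
      if (cs[k] <= 0.0) stop("degenerate class: zero posterior mass");
      pi[k] = cs[k] / n;
    }
    for (int j = 0; j < J; ++j) {
      NumericMatrix& pj = p[j];
      const int Lj = pj.nrow();
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < Lj; ++l) pj(l, k) = 0.0;
      for (int i = 0; i < n; ++i) {
        const int yij = y(i, j) - 1;
        for (int k = 0; k < K; ++k) pj(yij, k) += post(i, k);
      }
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int l = 0; l < Lj; ++l) {
          double v = pj(l, k) / cs[k];
          if (v < prob_floor) { v = prob_floor; ++floor_hits; }
          pj(l, k) = v;
          s += v;
        }
        for (int l = 0; l < Lj; ++l) pj(l, k) /= s;
      }
    }
  }
  // log-likelihood and posterior consistent with the returned parameters
  double ll_final = e_step_impl(y, p, pi, post);
  List pout(J);
  for (int j = 0; j < J; ++j) pout[j] = p[j];
  return List::create(
    _["pi"] = pi, _["p"] = pout, _["posterior"] = post,
    _["log_likelihood"] = ll_final,
    _["trace"] = NumericVector(trace.begin(), trace.end()),
    _["converged"] = converged,
    _["n_iter"] = std::min(iter, max_iter),
    _["floor_hits"] = floor_hits);
}
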