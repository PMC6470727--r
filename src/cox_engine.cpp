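#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Partial likelihood machinery for the Cox model on (entry, exit] intervals
// (counting-process / left-truncated data). One sweep over the unique event
// times in increasing order maintains the risk-set sums
//   S0 = sum w, S1 = sum w*x, S2 = sum w*x*x'
// over {i : entry_i < t <= exit_i}: subjects are added as t passes their
// entry age and removed as t passes their exit age, so the whole sweep is
// O(n log n + n p^2).

namespace {

struct Sweep {
  int n, p;
  const double *entry, *exit_, *eta;
  const int *status;
  const NumericMatrix *X;
  std::vector<int> ord_in, ord_out, deaths; // deaths sorted by exit time
  std::vector<double> utimes;               // unique event times, ascending

  Sweep(const NumericVector& entry_, const NumericVector& exit__,
        const IntegerVector& status_, const NumericMatrix& X_,
        const NumericVector& eta_)
      : n(X_.nrow()), p(X_.ncol()), entry(entry_.begin()),
        exit_(exit__.begin()), eta(eta_.begin()), status(status_.begin()),
        X(&X_) {
    ord_in.resize(n);
    ord_out.resize(n);
    for (int i = 0; i < n; ++i) ord_in[i] = ord_out[i] = i;
    std::sort(ord_in.begin(), ord_in.end(),
              [&](int a, int b) { return entry[a] < entry[b]; });
    std::sort(ord_out.begin(), ord_out.end(),
              [&](int a, int b) { return exit_[a] < exit_[b]; });
    for (int i = 0; i < n; ++i)
      if (status[ord_out[i]] == 1) deaths.push_back(ord_out[i]);
    for (size_t k = 0; k < deaths.size(); ++k) {
      double t = exit_[deaths[k]];
      if (utimes.empty() || utimes.back() != t) utimes.push_back(t);
    }
  }
};

} // namespace

// [[Rcpp::export]]
List cox_pl_cpp(NumericVector beta, NumericVector entry, NumericVector exit,
                IntegerVector status, NumericMatrix X, bool efron) {
  int n = X.nrow(), p = X.ncol();
  NumericVector eta(n);
  double etabar = 0.0;
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    eta[i] = e;
    etabar += e;
  }
  etabar /= n; // centre linear predictor for exp() stability; loglik invariant
  std::vector<double> w(n);
  for (int i = 0; i < n; ++i) {
    eta[i] -= etabar;
    w[i] = std::exp(eta[i]);
  }

  Sweep sw(entry, exit, status, X, eta);
  // row-major covariate copy: the sweep touches one subject's whole row at
  // a time, so contiguous rows keep the inner p^2 updates in cache
  std::vector<double> xr((size_t)n * p);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) xr[(size_t)i * p + j] = X(i, j);
  double loglik = 0.0;
  NumericVector grad(p);
  NumericMatrix imat(p, p);
  std::vector<double> S1(p, 0.0), S2(p * p, 0.0), D1(p), D2(p * p);
  double S0 = 0.0;
  size_t a = 0, b = 0, dptr = 0;

  for (double t : sw.utimes) {
    while (a < sw.ord_in.size() && entry[sw.ord_in[a]] < t) {
      int i = sw.ord_in[a++];
      double wi = w[i];
      const double *xi = &xr[(size_t)i * p];
      S0 += wi;
      for (int j = 0; j < p; ++j) {
        double xj = xi[j] * wi;
        S1[j] += xj;
        double *s2j = &S2[(size_t)j * p];
        for (int k = 0; k <= j; ++k) s2j[k] += xj * xi[k];
      }
    }
    while (b < sw.ord_out.size() && exit[sw.ord_out[b]] < t) {
      int i = sw.ord_out[b++];
      double wi = w[i];
      const double *xi = &xr[(size_t)i * p];
      S0 -= wi;
      for (int j = 0; j < p; ++j) {
        double xj = xi[j] * wi;
        S1[j] -= xj;
        double *s2j = &S2[(size_t)j * p];
        for (int k = 0; k <= j; ++k) s2j[k] -= xj * xi[k];
      }
    }
    // deaths at t
    int d0 = dptr;
    double D0 = 0.0;
    std::fill(D1.begin(), D1.end(), 0.0);
    std::fill(D2.begin(), D2.end(), 0.0);
    while (dptr < sw.deaths.size() && exit[sw.deaths[dptr]] == t) {
      int i = sw.deaths[dptr++];
      loglik += eta[i];
      double wi = w[i];
      const double *xi = &xr[(size_t)i * p];
      D0 += wi;
      for (int j = 0; j < p; ++j) {
        grad[j] += xi[j];
        double xj = xi[j] * wi;
        D1[j] += xj;
        double *d2j = &D2[(size_t)j * p];
        for (int k = 0; k <= j; ++k) d2j[k] += xj * xi[k];
      }
    }
    int d = (int)dptr - d0;
    for (int jj = 0; jj < d; ++jj) {
      double f = efron ? (double)jj / d : 0.0;
      double s0 = S0 - f * D0;
      loglik -= std::log(s0);
      for (int j = 0; j < p; ++j) {
        double m_j = (S1[j] - f * D1[j]) / s0;
        grad[j] -= m_j;
        for (int k = 0; k <= j; ++k) {
          double m_k = (S1[k] - f * D1[k]) / s0;
          imat(j, k) += (S2[j * p + k] - f * D2[j * p + k]) / s0 - m_j * m_k;
        }
      }
    }
  }
  for (int j = 0; j < p; ++j)
    for (int k = j + 1; k < p; ++k) imat(j, k) = imat(k, j);
  return List::create(_["loglik"] = loglik, _["grad"] = grad,
                      _["imat"] = imat, _["nevent"] = (int)sw.deaths.size());
}

// Schoenfeld residuals at beta-hat, one row per death in ascending death-time
// order. Under Efron ties each death at a tied time gets x_i minus the
// average over j of the Efron-weighted risk-set means, so the residuals sum
// to the score vector (~0 at the MLE).
// [[Rcpp::export]]
List cox_schoenfeld_cpp(NumericVector beta, NumericVector entry,
                        NumericVector exit, IntegerVector status,
                        NumericMatrix X, bool efron) {
  int n = X.nrow(), p = X.ncol();
  NumericVector eta(n);
  double etabar = 0.0;
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    eta[i] = e;
    etabar += e;
  }
  etabar /= n;
  std::vector<double> w(n);
  for (int i = 0; i < n; ++i) w[i] = std::exp(eta[i] - etabar);

  Sweep sw(entry, exit, status, X, eta);
  int ndeath = (int)sw.deaths.size();
  NumericMatrix resid(ndeath, p);
  NumericVector dtimes(ndeath);
  std::vector<double> S1(p, 0.0), D1(p), xbar(p);
  double S0 = 0.0;
  size_t a = 0, b = 0, dptr = 0;

  for (double t : sw.utimes) {
    while (a < sw.ord_in.size() && entry[sw.ord_in[a]] < t) {
      int i = sw.ord_in[a++];
      S0 += w[i];
      for (int j = 0; j < p; ++j) S1[j] += X(i, j) * w[i];
    }
    while (b < sw.ord_out.size() && exit[sw.ord_out[b]] < t) {
      int i = sw.ord_out[b++];
      S0 -= w[i];
      for (int j = 0; j < p; ++j) S1[j] -= X(i, j) * w[i];
    }
    int d0 = (int)dptr;
    double D0 = 0.0;
    std::fill(D1.begin(), D1.end(), 0.0);
    size_t look = dptr;
    while (look < sw.deaths.size() && exit[sw.deaths[look]] == t) {
      int i = sw.deaths[look++];
      D0 += w[i];
      for (int j = 0; j < p; ++j) D1[j] += X(i, j) * w[i];
    }
    int d = (int)look - d0;
    std::fill(xbar.begin(), xbar.end(), 0.0);
    for (int jj = 0; jj < d; ++jj) {
      double f = efron ? (double)jj / d : 0.0;
      double s0 = S0 - f * D0;
      for (int j = 0; j < p; ++j) xbar[j] += (S1[j] - f * D1[j]) / s0 / d;
    }
    while (dptr < look) {
      int i = sw.deaths[dptr];
      dtimes[dptr] = t;
      for (int j = 0; j < p; ++j) resid(dptr, j) = X(i, j) - xbar[j];
      ++dptr;
    }
  }
  return List::create(_["residuals"] = resid, _["time"] = dtimes,
                      _["id"] = wrap(sw.deaths));
}
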