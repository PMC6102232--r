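#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// The binned-photon HMM evaluates, per bin, Poisson factors in two
// detection channels. Counts per bin are small integers, so the pmfs are
// tabulated once per call (state x count); the per-bin work is then a
// matrix-vector product plus table lookups.

struct PoisTables {
  int S, nmax;
  std::vector<double> pd, pa;    // linear pmf, state-major
  std::vector<double> lpd, lpa;  // log pmf
  double at(const std::vector<double>& v, int i, int n) const {
    return v[static_cast<size_t>(i) * (nmax + 1) + n];
  }
};

static PoisTables build_tables(int S, int nmax,
                               const NumericVector& mu_d,
                               const NumericVector& mu_a) {
  PoisTables tb;
  tb.S = S; tb.nmax = nmax;
  tb.pd.resize(static_cast<size_t>(S) * (nmax + 1));
  tb.pa.resize(tb.pd.size());
  tb.lpd.resize(tb.pd.size());
  tb.lpa.resize(tb.pd.size());
  for (int i = 0; i < S; ++i) {
    for (int n = 0; n <= nmax; ++n) {
      const size_t k = static_cast<size_t>(i) * (nmax + 1) + n;
      tb.pd[k] = R::dpois(n, mu_d[i], 0);
      tb.pa[k] = R::dpois(n, mu_a[i], 0);
      tb.lpd[k] = R::dpois(n, mu_d[i], 1);
      tb.lpa[k] = R::dpois(n, mu_a[i], 1);
    }
  }
  return tb;
}

static int max_count(const IntegerVector& nd, const IntegerVector& na) {
  int nmax = 0;
  for (int t = 0; t < nd.size(); ++t) {
    if (nd[t] < 0 || na[t] < 0) stop("negative photon counts");
    if (nd[t] > nmax) nmax = nd[t];
    if (na[t] > nmax) nmax = na[t];
  }
  return nmax;
}

// Forward (filtering) recursion for the binned-photon likelihood
//   L = 1^T [ prod_t F_t P ] p0,  P = exp(delta * K)  (column convention:
//   P(j,i) = prob of i -> j over one bin), F_t diagonal with Poisson
//   factors in both channels. Rescaled every bin; returns log L. Bins
//   whose emission factors underflow in linear space are redone in log
//   space, so the result stays finite whenever the true likelihood is.
// mu_d, mu_a: expected counts per bin per state (rate * delta, background
// included by the caller).
// [[Rcpp::export]]
double forward_loglik_cpp(IntegerVector nd, IntegerVector na,
                          NumericMatrix P,
                          NumericVector mu_d, NumericVector mu_a,
                          NumericVector p0) {
  const int S = P.nrow();
  const int T = nd.size();
  if (na.size() != T) stop("channel lengths differ");
  if (mu_d.size() != S || mu_a.size() != S || p0.size() != S ||
      P.ncol() != S)
    stop("dimension mismatch");
  const int nmax = max_count(nd, na);
  const PoisTables tb = build_tables(S, nmax, mu_d, mu_a);
  const double* Pp = REAL(P);

  std::vector<double> alpha(S), tmp(S);
  for (int i = 0; i < S; ++i) alpha[i] = p0[i];
  double loglik = 0.0;

  for (int t = 0; t < T; ++t) {
    for (int j = 0; j < S; ++j) tmp[j] = 0.0;
    for (int i = 0; i < S; ++i) {
      const double ai = alpha[i];
      if (ai == 0.0) continue;
      const double* Pcol = Pp + static_cast<size_t>(i) * S;
      for (int j = 0; j < S; ++j) tmp[j] += Pcol[j] * ai;
    }
    double s = 0.0;
    for (int i = 0; i < S; ++i) {
      alpha[i] = tmp[i] * tb.at(tb.pd, i, nd[t]) * tb.at(tb.pa, i, na[t]);
      s += alpha[i];
    }
    if (s <= 0.0 || !std::isfinite(s)) {
      // redo this bin in log space (emission underflow)
      double m = R_NegInf;
      std::vector<double> le(S);
      for (int i = 0; i < S; ++i) {
        le[i] = tb.at(tb.lpd, i, nd[t]) + tb.at(tb.lpa, i, na[t]);
        if (tmp[i] > 0.0 && le[i] > m) m = le[i];
      }
      if (m == R_NegInf) return R_NegInf;
      s = 0.0;
      for (int i = 0; i < S; ++i) {
        alpha[i] = (tmp[i] > 0.0 && std::isfinite(le[i]))
          ? tmp[i] * std::exp(le[i] - m) : 0.0;
        s += alpha[i];
      }
      if (s <= 0.0 || !std::isfinite(s)) return R_NegInf;
      loglik += m;
    }
    for (int i = 0; i < S; ++i) alpha[i] /= s;
    loglik += std::log(s);
  }
  return loglik;
}

// Viterbi decoding of the most likely state path under the same binned
// HMM. Ties in the backtrack resolve to the lowest state index (states
// scanned in ascending order with a strict improvement test). Returns
// 1-based state indices per bin.
// [[Rcpp::export]]
IntegerVector viterbi_cpp(IntegerVector nd, IntegerVector na,
                          NumericMatrix P,
                          NumericVector mu_d, NumericVector mu_a,
                          NumericVector p0) {
  const int S = P.nrow();
  const int T = nd.size();
  if (na.size() != T) stop("channel lengths differ");
  const int nmax = max_count(nd, na);
  const PoisTables tb = build_tables(S, nmax, mu_d, mu_a);

  std::vector<double> lP(static_cast<size_t>(S) * S), lp0(S);
  for (int i = 0; i < S; ++i) {
    lp0[i] = p0[i] > 0 ? std::log(p0[i]) : R_NegInf;
    for (int j = 0; j < S; ++j)
      lP[static_cast<size_t>(i) * S + j] =
        P(j, i) > 0 ? std::log(P(j, i)) : R_NegInf;
  }

  std::vector<double> dprev(S), dcur(S);
  std::vector<int> back(static_cast<size_t>(T) * S);

  for (int j = 0; j < S; ++j) {
    // first bin: one propagation step from the stationary start
    double best = R_NegInf;
    int arg = 0;
    for (int i = 0; i < S; ++i) {
      const double v = lp0[i] + lP[static_cast<size_t>(i) * S + j];
      if (v > best) { best = v; arg = i; }
    }
    dprev[j] = best + tb.at(tb.lpd, j, nd[0]) + tb.at(tb.lpa, j, na[0]);
    back[j] = arg;
  }

  for (int t = 1; t < T; ++t) {
    int* bk = back.data() + static_cast<size_t>(t) * S;
    for (int j = 0; j < S; ++j) {
      double best = R_NegInf;
      int arg = 0;
      for (int i = 0; i < S; ++i) {
        const double v = dprev[i] + lP[static_cast<size_t>(i) * S + j];
        if (v > best) { best = v; arg = i; }
      }
      dcur[j] = best + tb.at(tb.lpd, j, nd[t]) + tb.at(tb.lpa, j, na[t]);
      bk[j] = arg;
    }
    std::swap(dprev, dcur);
  }

  int jbest = 0;
  for (int j = 1; j < S; ++j)
    if (dprev[j] > dprev[jbest]) jbest = j;

  IntegerVector path(T);
  path[T - 1] = jbest + 1;
  for (int t = T - 1; t > 0; --t) {
    jbest = back[static_cast<size_t>(t) * S + jbest];
    path[t - 1] = jbest + 1;
  }
  return path;
}

// Forward recursion with a configurable rescaling stride (testing aid for
// the schedule-invariance property of the log-likelihood).
// [[Rcpp::export]]
double forward_loglik_stride_cpp(IntegerVector nd, IntegerVector na,
                                 NumericMatrix P,
                                 NumericVector mu_d, NumericVector mu_a,
                                 NumericVector p0, int stride) {
  const int S = P.nrow();
  const int T = nd.size();
  std::vector<double> alpha(S), tmp(S);
  for (int i = 0; i < S; ++i) alpha[i] = p0[i];
  double loglik = 0.0;
  for (int t = 0; t < T; ++t) {
    for (int j = 0; j < S; ++j) tmp[j] = 0.0;
    for (int i = 0; i < S; ++i)
      for (int j = 0; j < S; ++j) tmp[j] += P(j, i) * alpha[i];
    for (int i = 0; i < S; ++i) {
      const double e = R::dpois(nd[t], mu_d[i], 0) *
        R::dpois(na[t], mu_a[i], 0);
      alpha[i] = tmp[i] * e;
    }
    if ((t + 1) % stride == 0) {
      double s = 0.0;
      for (int i = 0; i < S; ++i) s += alpha[i];
      if (s <= 0.0) return R_NegInf;
      for (int i = 0; i < S; ++i) alpha[i] /= s;
      loglik += std::log(s);
    }
  }
  double s = 0.0;
  for (int i = 0; i < S; ++i) s += alpha[i];
  if (s <= 0.0) return R_NegInf;
  return loglik + std::log(s);
}
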