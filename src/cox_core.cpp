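// Core numerics for weighted Cox partial-likelihood models on counting-process
// data (start, stop] with Breslow ties, plus the penalised coordinate-descent
// path solver and O(n^2) concordance kernels.
//
// Row i is at risk at time t iff start[i] < t <= stop[i]; a row with status 1
// fails at stop[i]. Barlow case-cohort weighting is expressed upstream by row
// expansion (pre-event and at-event rows with different weights).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

namespace {

struct EventStruct {
  std::vector<double> evtime;       // distinct event times, ascending
  std::vector<double> dk;           // weighted failure mass per event time
  std::vector<int> lo, hi;          // per-row inclusive risk range over event idx
  std::vector<int> fail_k;          // per-row event index if status==1, else -1
  int D;
};

EventStruct build_events(const NumericVector& start, const NumericVector& stop,
                         const IntegerVector& status, const NumericVector& w) {
  int n = stop.size();
  std::vector<double> ev;
  ev.reserve(n);
  for (int i = 0; i < n; ++i)
    if (status[i] == 1) ev.push_back(stop[i]);
  std::sort(ev.begin(), ev.end());
  ev.erase(std::unique(ev.begin(), ev.end()), ev.end());
  EventStruct es;
  es.evtime = ev;
  es.D = (int)ev.size();
  es.dk.assign(es.D, 0.0);
  es.lo.assign(n, 0);
  es.hi.assign(n, -1);
  es.fail_k.assign(n, -1);
  for (int i = 0; i < n; ++i) {
    // first event time > start[i]
    int lo = (int)(std::upper_bound(ev.begin(), ev.end(), start[i]) - ev.begin());
    // last event time <= stop[i]
    int hi = (int)(std::upper_bound(ev.begin(), ev.end(), stop[i]) - ev.begin()) - 1;
    es.lo[i] = lo;
    es.hi[i] = hi;
    if (status[i] == 1) {
      int k = (int)(std::lower_bound(ev.begin(), ev.end(), stop[i]) - ev.begin());
      es.fail_k[i] = k;
      es.dk[k] += w[i];
    }
  }
  return es;
}

// Risk-set sums S0 (and optionally S1, S2) at each event time via a single
// sweep: rows enter at event index lo and leave after hi.
void risk_sums(const EventStruct& es, const NumericMatrix& X,
               const NumericVector& w, const std::vector<double>& elp,
               std::vector<double>& S0, std::vector<double>* S1,
               std::vector<double>* S2, int p) {
  int n = w.size(), D = es.D;
  S0.assign(D, 0.0);
  if (S1) S1->assign((size_t)D * p, 0.0);
  if (S2) S2->assign((size_t)D * p * p, 0.0);
  // order rows by lo (additions) and by hi (removals)
  std::vector<int> by_lo(n), by_hi(n);
  for (int i = 0; i < n; ++i) by_lo[i] = by_hi[i] = i;
  std::sort(by_lo.begin(), by_lo.end(),
            [&](int a, int b) { return es.lo[a] < es.lo[b]; });
  std::sort(by_hi.begin(), by_hi.end(),
            [&](int a, int b) { return es.hi[a] < es.hi[b]; });
  double s0 = 0.0;
  std::vector<double> s1(p, 0.0), s2((size_t)p * p, 0.0);
  size_t ia = 0, ir = 0;
  // skip rows never at risk
  while (ir < by_hi.size() && es.hi[by_hi[ir]] < 0) ++ir;
  for (int k = 0; k < D; ++k) {
    while (ia < by_lo.size() && es.lo[by_lo[ia]] <= k) {
      int i = by_lo[ia++];
      if (es.hi[i] < es.lo[i]) continue;  // never at risk
      double we = w[i] * elp[i];
      s0 += we;
      if (S1)
        for (int j = 0; j < p; ++j) s1[j] += we * X(i, j);
      if (S2)
        for (int j = 0; j < p; ++j) {
          double a = we * X(i, j);
          for (int l = j; l < p; ++l) s2[(size_t)j * p + l] += a * X(i, l);
        }
    }
    S0[k] = s0;
    if (S1)
      for (int j = 0; j < p; ++j) (*S1)[(size_t)k * p + j] = s1[j];
    if (S2)
      for (size_t q = 0; q < s2.size(); ++q) (*S2)[(size_t)k * p * p + q] = s2[q];
    while (ir < by_hi.size() && es.hi[by_hi[ir]] <= k) {
      int i = by_hi[ir++];
      if (es.hi[i] < es.lo[i] || es.hi[i] < 0) continue;
      double we = w[i] * elp[i];
      s0 -= we;
      if (S1)
        for (int j = 0; j < p; ++j) s1[j] -= we * X(i, j);
      if (S2)
        for (int j = 0; j < p; ++j) {
          double a = we * X(i, j);
          for (int l = j; l < p; ++l) s2[(size_t)j * p + l] -= a * X(i, l);
        }
    }
  }
}

std::vector<double> centered_elp(const NumericVector& lp, double& shift) {
  int n = lp.size();
  shift = 0.0;
  for (int i = 0; i < n; ++i) shift += lp[i];
  shift /= std::max(1, n);
  std::vector<double> elp(n);
  for (int i = 0; i < n; ++i) elp[i] = std::exp(lp[i] - shift);
  return elp;
}

// log partial likelihood given S0 computed from centred elp with given shift
double loglik_from(const EventStruct& es, const NumericVector& lp,
                   const IntegerVector& status, const NumericVector& w,
                   const std::vector<double>& S0, double shift) {
  int n = lp.size();
  double ll = 0.0;
  for (int i = 0; i < n; ++i)
    if (status[i] == 1) ll += w[i] * (lp[i] - shift);
  for (int k = 0; k < es.D; ++k)
    if (es.dk[k] > 0) ll -= es.dk[k] * std::log(S0[k]);
  return ll;
}

}  // namespace

// [[Rcpp::export]]
List cox_eval_cpp(NumericMatrix X, NumericVector start, NumericVector stop,
                  IntegerVector status, NumericVector w, NumericVector beta,
                  bool want_hessian) {
  int n = X.nrow(), p = X.ncol();
  NumericVector lp(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += X(i, j) * beta[j];
    lp[i] = s;
  }
  EventStruct es = build_events(start, stop, status, w);
  double shift;
  std::vector<double> elp = centered_elp(lp, shift);
  std::vector<double> S0, S1, S2;
  risk_sums(es, X, w, elp, S0, &S1, want_hessian ? &S2 : nullptr, p);

  double ll = loglik_from(es, lp, status, w, S0, shift);
  NumericVector grad(p);
  for (int i = 0; i < n; ++i)
    if (status[i] == 1)
      for (int j = 0; j < p; ++j) grad[j] += w[i] * X(i, j);
  for (int k = 0; k < es.D; ++k) {
    if (es.dk[k] <= 0) continue;
    for (int j = 0; j < p; ++j) grad[j] -= es.dk[k] * S1[(size_t)k * p + j] / S0[k];
  }
  NumericMatrix info(p, p);
  if (want_hessian) {
    for (int k = 0; k < es.D; ++k) {
      if (es.dk[k] <= 0) continue;
      double s0 = S0[k];
      for (int j = 0; j < p; ++j) {
        double mj = S1[(size_t)k * p + j] / s0;
        for (int l = j; l < p; ++l) {
          double ml = S1[(size_t)k * p + l] / s0;
          double v = es.dk[k] * (S2[(size_t)k * p * p + (size_t)j * p + l] / s0 - mj * ml);
          info(j, l) += v;
        }
      }
    }
    for (int j = 0; j < p; ++j)
      for (int l = 0; l < j; ++l) info(j, l) = info(l, j);
  }
  // Breslow baseline increments dk / S0 (on the centred scale; rescale in R)
  NumericVector h0inc(es.D), evt(es.D);
  for (int k = 0; k < es.D; ++k) {
    evt[k] = es.evtime[k];
    h0inc[k] = es.dk[k] / S0[k] * std::exp(-shift);
  }
  return List::create(_["loglik"] = ll, _["grad"] = grad, _["info"] = info,
                      _["event_times"] = evt, _["h0_increment"] = h0inc,
                      _["n_events"] = es.D);
}

// Per-row score residuals U_i (n x p); aggregate by subject in R for the
// sandwich variance.
// [[Rcpp::export]]
NumericMatrix cox_score_resid_cpp(NumericMatrix X, NumericVector start,
                                  NumericVector stop, IntegerVector status,
                                  NumericVector w, NumericVector beta) {
  int n = X.nrow(), p = X.ncol();
  NumericVector lp(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += X(i, j) * beta[j];
    lp[i] = s;
  }
  EventStruct es = build_events(start, stop, status, w);
  double shift;
  std::vector<double> elp = centered_elp(lp, shift);
  std::vector<double> S0, S1;
  risk_sums(es, X, w, elp, S0, &S1, nullptr, p);
  int D = es.D;
  // cumulative A_k = sum dk/S0, Bmat_k = sum dk*S1/S0^2 (prefix, inclusive)
  std::vector<double> A(D + 1, 0.0), B((size_t)(D + 1) * p, 0.0);
  for (int k = 0; k < D; ++k) {
    double r = (S0[k] > 0) ? es.dk[k] / S0[k] : 0.0;
    A[k + 1] = A[k] + r;
    for (int j = 0; j < p; ++j)
      B[(size_t)(k + 1) * p + j] =
          B[(size_t)k * p + j] + ((S0[k] > 0) ? es.dk[k] * S1[(size_t)k * p + j] / (S0[k] * S0[k]) : 0.0);
  }
  NumericMatrix U(n, p);
  for (int i = 0; i < n; ++i) {
    int lo = es.lo[i], hi = es.hi[i];
    if (status[i] == 1) {
      int k = es.fail_k[i];
      for (int j = 0; j < p; ++j)
        U(i, j) += w[i] * (X(i, j) - S1[(size_t)k * p + j] / S0[k]);
    }
    if (hi >= lo) {
      double a = A[hi + 1] - A[lo];
      double we = w[i] * elp[i];
      for (int j = 0; j < p; ++j) {
        double b = B[(size_t)(hi + 1) * p + j] - B[(size_t)lo * p + j];
        U(i, j) -= we * (X(i, j) * a - b);
      }
    }
  }
  return U;
}

// Gradient and positive diagonal curvature of the log partial likelihood with
// respect to each row's linear predictor; used by the IRLS lasso solver.
// [[Rcpp::export]]
List cox_lp_derivs_cpp(NumericVector lp, NumericVector start, NumericVector stop,
                       IntegerVector status, NumericVector w) {
  int n = lp.size();
  EventStruct es = build_events(start, stop, status, w);
  double shift;
  std::vector<double> elp = centered_elp(lp, shift);
  NumericMatrix dummy(n, 0);
  std::vector<double> S0;
  risk_sums(es, dummy, w, elp, S0, nullptr, nullptr, 0);
  int D = es.D;
  std::vector<double> A1(D + 1, 0.0), A2(D + 1, 0.0);
  for (int k = 0; k < D; ++k) {
    double r = (S0[k] > 0) ? es.dk[k] / S0[k] : 0.0;
    A1[k + 1] = A1[k] + r;
    A2[k + 1] = A2[k] + ((S0[k] > 0) ? r / S0[k] : 0.0);
  }
  NumericVector rvec(n), hvec(n);
  for (int i = 0; i < n; ++i) {
    double cumh = 0.0, cumh2 = 0.0;
    if (es.hi[i] >= es.lo[i]) {
      cumh = A1[es.hi[i] + 1] - A1[es.lo[i]];
      cumh2 = A2[es.hi[i] + 1] - A2[es.lo[i]];
    }
    double we = w[i] * elp[i];
    rvec[i] = w[i] * (status[i] == 1 ? 1.0 : 0.0) - we * cumh;
    double h = we * cumh - we * we * cumh2;
    hvec[i] = (h > 0) ? h : 0.0;
  }
  double ll = loglik_from(es, lp, status, w, S0, shift);
  return List::create(_["r"] = rvec, _["h"] = hvec, _["loglik"] = ll);
}

// [[Rcpp::export]]
NumericVector cox_loglik_multi_cpp(NumericMatrix LP, NumericVector start,
                                   NumericVector stop, IntegerVector status,
                                   NumericVector w) {
  int n = LP.nrow(), M = LP.ncol();
  EventStruct es = build_events(start, stop, status, w);
  NumericVector out(M);
  NumericVector lp(n);
  for (int m = 0; m < M; ++m) {
    for (int i = 0; i < n; ++i) lp[i] = LP(i, m);
    double shift;
    std::vector<double> elp = centered_elp(lp, shift);
    NumericMatrix dummy(n, 0);
    std::vector<double> S0;
    risk_sums(es, dummy, w, elp, S0, nullptr, nullptr, 0);
    out[m] = loglik_from(es, lp, status, w, S0, shift);
  }
  return out;
}

// [[Rcpp::export]]
double cox_loglik_cpp(NumericVector lp, NumericVector start, NumericVector stop,
                      IntegerVector status, NumericVector w) {
  EventStruct es = build_events(start, stop, status, w);
  double shift;
  std::vector<double> elp = centered_elp(lp, shift);
  NumericMatrix dummy(lp.size(), 0);
  std::vector<double> S0;
  risk_sums(es, dummy, w, elp, S0, nullptr, nullptr, 0);
  return loglik_from(es, lp, status, w, S0, shift);
}

namespace {

struct LpWork {
  EventStruct es;
  std::vector<double> S0;
  std::vector<int> by_lo, by_hi;  // rows ever at risk, sorted by entry/exit

  void init_orders(int n) {
    by_lo.clear(); by_hi.clear();
    by_lo.reserve(n); by_hi.reserve(n);
    for (int i = 0; i < n; ++i)
      if (es.hi[i] >= es.lo[i]) { by_lo.push_back(i); by_hi.push_back(i); }
    std::sort(by_lo.begin(), by_lo.end(),
              [&](int a, int b) { return es.lo[a] < es.lo[b]; });
    std::sort(by_hi.begin(), by_hi.end(),
              [&](int a, int b) { return es.hi[a] < es.hi[b]; });
  }
  // gradient r and positive diagonal curvature h of the log partial
  // likelihood with respect to each row's linear predictor
  void derivs(const std::vector<double>& lp, const std::vector<double>& elp,
              double shift, const NumericVector& w,
              const IntegerVector& status, std::vector<double>& r,
              std::vector<double>& h, double* ll) {
    int n = (int)lp.size(), D = es.D;
    S0.assign(D, 0.0);
    std::vector<double> diff(D + 1, 0.0);
    for (int i = 0; i < n; ++i) {
      if (es.hi[i] < es.lo[i]) continue;
      double we = w[i] * elp[i];
      diff[es.lo[i]] += we;
      diff[es.hi[i] + 1] -= we;
    }
    double run = 0.0;
    for (int k = 0; k < D; ++k) {
      run += diff[k];
      S0[k] = run;
    }
    std::vector<double> A1(D + 1, 0.0), A2(D + 1, 0.0);
    for (int k = 0; k < D; ++k) {
      double rr = (S0[k] > 0) ? es.dk[k] / S0[k] : 0.0;
      A1[k + 1] = A1[k] + rr;
      A2[k + 1] = A2[k] + ((S0[k] > 0) ? rr / S0[k] : 0.0);
    }
    r.assign(n, 0.0);
    h.assign(n, 0.0);
    for (int i = 0; i < n; ++i) {
      double cumh = 0.0, cumh2 = 0.0;
      if (es.hi[i] >= es.lo[i]) {
        cumh = A1[es.hi[i] + 1] - A1[es.lo[i]];
        cumh2 = A2[es.hi[i] + 1] - A2[es.lo[i]];
      }
      double we = w[i] * elp[i];
      r[i] = w[i] * (status[i] == 1 ? 1.0 : 0.0) - we * cumh;
      double hh = we * cumh - we * we * cumh2;
      h[i] = (hh > 0) ? hh : 0.0;
    }
    if (ll) {
      double l = 0.0;
      for (int i = 0; i < n; ++i)
        if (status[i] == 1) l += w[i] * (lp[i] - shift);
      for (int k = 0; k < D; ++k)
        if (es.dk[k] > 0) l -= es.dk[k] * std::log(S0[k]);
      *ll = l;
    }
  }

  double loglik(const std::vector<double>& lp, const std::vector<double>& elp,
                double shift, const NumericVector& w,
                const IntegerVector& status) {
    int n = (int)lp.size(), D = es.D;
    std::vector<double> diff(D + 1, 0.0);
    for (int i = 0; i < n; ++i) {
      if (es.hi[i] < es.lo[i]) continue;
      double we = w[i] * elp[i];
      diff[es.lo[i]] += we;
      diff[es.hi[i] + 1] -= we;
    }
    double run = 0.0, l = 0.0;
    for (int i = 0; i < n; ++i)
      if (status[i] == 1) l += w[i] * (lp[i] - shift);
    for (int k = 0; k < D; ++k) {
      run += diff[k];
      if (es.dk[k] > 0) l -= es.dk[k] * std::log(run);
    }
    return l;
  }

  // log partial likelihood, gradient and Hessian restricted to the columns
  // in A, by a single sweep over event times
  void grad_hess_sub(const NumericMatrix& X, const NumericVector& w,
                     const IntegerVector& status,
                     const std::vector<double>& lp,
                     const std::vector<double>& elp, double shift,
                     const std::vector<int>& A,
                     std::vector<double>& g, std::vector<double>& H,
                     double* ll) {
    int n = (int)lp.size(), D = es.D, pa = (int)A.size();
    g.assign(pa, 0.0);
    H.assign((size_t)pa * pa, 0.0);
    double l = 0.0;
    for (int i = 0; i < n; ++i)
      if (status[i] == 1) {
        l += w[i] * (lp[i] - shift);
        for (int q = 0; q < pa; ++q) g[q] += w[i] * X(i, A[q]);
      }
    // sweep additions/removals ordered by lo / hi
    double s0 = 0.0;
    std::vector<double> s1(pa, 0.0), s2((size_t)pa * pa, 0.0), xi(pa);
    size_t ia = 0, ir = 0;
    for (int k = 0; k < D; ++k) {
      while (ia < by_lo.size() && es.lo[by_lo[ia]] <= k) {
        int i = by_lo[ia++];
        double we = w[i] * elp[i];
        s0 += we;
        for (int q = 0; q < pa; ++q) xi[q] = X(i, A[q]);
        for (int q = 0; q < pa; ++q) {
          s1[q] += we * xi[q];
          double a = we * xi[q];
          for (int t = q; t < pa; ++t) s2[(size_t)q * pa + t] += a * xi[t];
        }
      }
      if (es.dk[k] > 0 && s0 > 0) {
        l -= es.dk[k] * std::log(s0);
        for (int q = 0; q < pa; ++q) {
          double mq = s1[q] / s0;
          g[q] -= es.dk[k] * mq;
          for (int t = q; t < pa; ++t)
            H[(size_t)q * pa + t] +=
                es.dk[k] * (s2[(size_t)q * pa + t] / s0 - mq * s1[t] / s0);
        }
      }
      while (ir < by_hi.size() && es.hi[by_hi[ir]] <= k) {
        int i = by_hi[ir++];
        double we = w[i] * elp[i];
        s0 -= we;
        for (int q = 0; q < pa; ++q) xi[q] = X(i, A[q]);
        for (int q = 0; q < pa; ++q) {
          s1[q] -= we * xi[q];
          double a = we * xi[q];
          for (int t = q; t < pa; ++t) s2[(size_t)q * pa + t] -= a * xi[t];
        }
      }
    }
    for (int q = 0; q < pa; ++q)
      for (int t = 0; t < q; ++t)
        H[(size_t)q * pa + t] = H[(size_t)t * pa + q];
    if (ll) *ll = l;
  }

  // gradient (and log likelihood) restricted to columns in A; no Hessian
  void grad_sub(const NumericMatrix& X, const NumericVector& w,
                const IntegerVector& status, const std::vector<double>& lp,
                const std::vector<double>& elp, double shift,
                const std::vector<int>& A, std::vector<double>& g, double* ll) {
    int n = (int)lp.size(), D = es.D, pa = (int)A.size();
    g.assign(pa, 0.0);
    double l = 0.0;
    for (int i = 0; i < n; ++i)
      if (status[i] == 1) {
        l += w[i] * (lp[i] - shift);
        for (int q = 0; q < pa; ++q) g[q] += w[i] * X(i, A[q]);
      }
    double s0 = 0.0;
    std::vector<double> s1(pa, 0.0);
    size_t ia = 0, ir = 0;
    for (int k = 0; k < D; ++k) {
      while (ia < by_lo.size() && es.lo[by_lo[ia]] <= k) {
        int i = by_lo[ia++];
        double we = w[i] * elp[i];
        s0 += we;
        for (int q = 0; q < pa; ++q) s1[q] += we * X(i, A[q]);
      }
      if (es.dk[k] > 0 && s0 > 0) {
        l -= es.dk[k] * std::log(s0);
        for (int q = 0; q < pa; ++q) g[q] -= es.dk[k] * s1[q] / s0;
      }
      while (ir < by_hi.size() && es.hi[by_hi[ir]] <= k) {
        int i = by_hi[ir++];
        double we = w[i] * elp[i];
        s0 -= we;
        for (int q = 0; q < pa; ++q) s1[q] -= we * X(i, A[q]);
      }
    }
    if (ll) *ll = l;
  }
};

// Cholesky factorisation of (M + ridge I) into L (row-major lower);
// returns false if not positive definite
bool chol_factor(const std::vector<double>& M, std::vector<double>& L, int m,
                 double ridge) {
  L = M;
  for (int j = 0; j < m; ++j) L[(size_t)j * m + j] += ridge;
  for (int j = 0; j < m; ++j) {
    double d = L[(size_t)j * m + j];
    for (int k = 0; k < j; ++k) d -= L[(size_t)j * m + k] * L[(size_t)j * m + k];
    if (d <= 0) return false;
    d = std::sqrt(d);
    L[(size_t)j * m + j] = d;
    for (int i = j + 1; i < m; ++i) {
      double v = L[(size_t)i * m + j];
      for (int k = 0; k < j; ++k)
        v -= L[(size_t)i * m + k] * L[(size_t)j * m + k];
      L[(size_t)i * m + j] = v / d;
    }
  }
  return true;
}

void chol_backsolve(const std::vector<double>& L, std::vector<double>& b, int m) {
  for (int i = 0; i < m; ++i) {
    double v = b[i];
    for (int k = 0; k < i; ++k) v -= L[(size_t)i * m + k] * b[k];
    b[i] = v / L[(size_t)i * m + i];
  }
  for (int i = m - 1; i >= 0; --i) {
    double v = b[i];
    for (int k = i + 1; k < m; ++k) v -= L[(size_t)k * m + i] * b[k];
    b[i] = v / L[(size_t)i * m + i];
  }
}

}  // namespace

// Penalised Cox path solved by an active-set Newton method with warm starts:
// at each grid point the penalised problem is solved exactly on the current
// active set (sign-constrained Newton with step-halving on the penalised
// objective), KKT conditions are then checked against the exact
// partial-likelihood gradient over all predictors, violators join the active
// set, and the cycle repeats until the certificate holds. X must arrive
// standardised; pf = 0 marks force-included (unpenalised) columns. The path
// stops early once more than dfmax penalised covariates are active.
// [[Rcpp::export]]
List cox_lasso_path_cpp(NumericMatrix X, NumericVector start, NumericVector stop,
                        IntegerVector status, NumericVector w, NumericVector pf,
                        NumericVector lambda, int nlambda,
                        double lambda_min_ratio, double kkt_tol, int maxit_irls,
                        int maxit_cd, int dfmax, int scan_stride) {
  int n = X.nrow(), p = X.ncol();
  LpWork work;
  work.es = build_events(start, stop, status, w);
  work.init_orders(n);

  std::vector<double> beta(p, 0.0), lp(n, 0.0);
  std::vector<double> sgn(p, 0.0);  // fixed subgradient sign of active coords
  std::vector<double> r(n), h(n), g(p, 0.0);
  double ll = 0.0;
  // cached exp(lp - shift), kept in sync with lp
  std::vector<double> elp(n, 1.0), elp_try(n);
  double shift = 0.0, shift_try = 0.0;
  auto refresh_elp = [&](const std::vector<double>& lpv,
                         std::vector<double>& e, double& sh) {
    sh = 0.0;
    for (int i = 0; i < n; ++i) sh += lpv[i];
    sh /= std::max(1, n);
    for (int i = 0; i < n; ++i) e[i] = std::exp(lpv[i] - sh);
  };

  auto update_lp = [&](const std::vector<int>& A,
                       const std::vector<double>& delta) {
    for (size_t q = 0; q < A.size(); ++q) {
      int j = A[q];
      if (delta[q] == 0.0) continue;
      for (int i = 0; i < n; ++i) lp[i] += delta[q] * X(i, j);
    }
  };

  // sign-constrained Newton on the active set; returns achieved KKT
  // residual. The Hessian (and its Cholesky factor) is reused across
  // iterations and grid points while the active set is unchanged and
  // progress is fast; it is refreshed when convergence slows.
  std::vector<double> Lfac;
  std::vector<int> Lset;
  bool Lvalid = false;
  auto polish = [&](double lam, std::vector<int>& A) -> double {
    double prev_viol = std::numeric_limits<double>::infinity();
    for (int it = 0; it < maxit_irls; ++it) {
      int pa = (int)A.size();
      if (!pa) return 0.0;
      std::vector<double> gA, HA;
      work.grad_sub(X, w, status, lp, elp, shift, A, gA, &ll);
      std::vector<double> rhs(pa);
      double viol = 0.0;
      for (int q = 0; q < pa; ++q) {
        int j = A[q];
        rhs[q] = gA[q] - lam * pf[j] * sgn[j];
        viol = std::max(viol, std::fabs(rhs[q]));
      }
      if (viol <= kkt_tol) return viol;
      bool need_h = !Lvalid || Lset != A || viol > 0.5 * prev_viol;
      prev_viol = viol;
      bool fresh = need_h;
      if (need_h) {
        work.grad_hess_sub(X, w, status, lp, elp, shift, A, gA, HA, &ll);
        for (int q = 0; q < pa; ++q)
          rhs[q] = gA[q] - lam * pf[A[q]] * sgn[A[q]];
        bool solved = false;
        for (double ridge = 0.0; ridge <= 1e2;
             ridge = (ridge == 0.0) ? 1e-8 : ridge * 100) {
          if (chol_factor(HA, Lfac, pa, ridge)) { solved = true; break; }
        }
        if (!solved) return viol;
        Lset = A;
        Lvalid = true;
      }
      std::vector<double> delta = rhs;
      chol_backsolve(Lfac, delta, pa);
      // penalised objective at current point
      double pen = 0.0;
      for (int j = 0; j < p; ++j) pen += lam * pf[j] * std::fabs(beta[j]);
      double obj_old = -ll + pen;
      double step = 1.0;
      std::vector<double> beta_try(pa), dstep(pa);
      bool accepted = false;
      for (int halv = 0; halv < 25; ++halv) {
        for (int q = 0; q < pa; ++q) {
          int j = A[q];
          double b_new = beta[j] + step * delta[q];
          // a penalised coefficient may not cross zero within one step
          if (pf[j] > 0 && sgn[j] != 0 && b_new * sgn[j] < 0) b_new = 0.0;
          beta_try[q] = b_new;
          dstep[q] = b_new - beta[j];
        }
        update_lp(A, dstep);
        refresh_elp(lp, elp_try, shift_try);
        double ll_try = work.loglik(lp, elp_try, shift_try, w, status);
        double pen_try = pen;
        for (int q = 0; q < pa; ++q) {
          int j = A[q];
          pen_try += lam * pf[j] * (std::fabs(beta_try[q]) - std::fabs(beta[j]));
        }
        if (-ll_try + pen_try <= obj_old + 1e-12) {
          for (int q = 0; q < pa; ++q) beta[A[q]] = beta_try[q];
          ll = ll_try;
          elp.swap(elp_try);
          shift = shift_try;
          accepted = true;
          break;
        }
        // revert lp and halve
        for (int q = 0; q < pa; ++q) dstep[q] = -dstep[q];
        update_lp(A, dstep);
        step /= 2.0;
      }
      if (!accepted) {
        if (fresh) return viol;  // genuine stall with an exact Hessian
        Lvalid = false;          // stale curvature: refresh and retry
        continue;
      }
      // drop clamped (zero) penalised coords from the active set
      std::vector<int> A2;
      A2.reserve(A.size());
      for (size_t q = 0; q < A.size(); ++q) {
        int j = A[q];
        if (pf[j] > 0 && beta[j] == 0.0) { sgn[j] = 0.0; Lvalid = false; continue; }
        A2.push_back(j);
      }
      A.swap(A2);
    }
    // report residual at exit
    int pa = (int)A.size();
    std::vector<double> gA;
    if (!pa) return 0.0;
    work.grad_sub(X, w, status, lp, elp, shift, A, gA, &ll);
    double viol = 0.0;
    for (int q = 0; q < pa; ++q)
      viol = std::max(viol, std::fabs(gA[q] - lam * pf[A[q]] * sgn[A[q]]));
    return viol;
  };

  auto full_gradient = [&]() {
    work.derivs(lp, elp, shift, w, status, r, h, &ll);
    for (int j = 0; j < p; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += X(i, j) * r[i];
      g[j] = s;
    }
  };

  // baseline: unpenalised columns only
  std::vector<int> active;
  for (int j = 0; j < p; ++j)
    if (pf[j] == 0.0) active.push_back(j);
  polish(0.0, active);
  full_gradient();
  double lmax = 0.0;
  for (int j = 0; j < p; ++j)
    if (pf[j] > 0.0) lmax = std::max(lmax, std::fabs(g[j]) / pf[j]);
  if (lmax <= 0.0) lmax = 1.0;

  std::vector<double> grid;
  if (lambda.size() > 0) {
    grid.assign(lambda.begin(), lambda.end());
  } else {
    double l0 = std::log(lmax), l1 = std::log(lmax * lambda_min_ratio);
    for (int m = 0; m < nlambda; ++m)
      grid.push_back(std::exp(l0 + (l1 - l0) * m / (double)(nlambda - 1)));
  }
  int M = (int)grid.size();
  NumericMatrix betas(p, M);
  NumericVector llv(M, NA_REAL), dfv(M, NA_REAL), kktv(M, NA_REAL);
  LogicalVector fitted(M, false);

  for (int m = 0; m < M; ++m) {
    double lam = grid[m];
    // active set from warm start
    active.clear();
    for (int j = 0; j < p; ++j) {
      if (pf[j] == 0.0) {
        active.push_back(j);
      } else if (beta[j] != 0.0) {
        active.push_back(j);
        sgn[j] = (beta[j] > 0) ? 1.0 : -1.0;
      } else {
        sgn[j] = 0.0;
      }
    }
    // pre-admit coordinates already violating at the warm-start gradient
    for (int j = 0; j < p; ++j) {
      if (pf[j] == 0.0 || beta[j] != 0.0) continue;
      if (std::fabs(g[j]) > lam * pf[j] + kkt_tol) {
        sgn[j] = (g[j] > 0) ? 1.0 : -1.0;
        active.push_back(j);
      }
    }
    double kkt = 0.0;
    // the exhaustive per-grid-point KKT scan may be strided for internal
    // (cross-validation fold) fits; pre-admission still screens entrants
    // against the most recent full gradient
    bool scan = (scan_stride <= 1) || (m % scan_stride == 0) || (m == M - 1);
    if (!scan) {
      kkt = polish(lam, active);
    } else
    for (int guard = 0; guard < maxit_cd; ++guard) {
      double in_viol = polish(lam, active);
      full_gradient();
      kkt = in_viol;
      // exact KKT over all predictors; admit violators
      int added = 0;
      for (int j = 0; j < p; ++j) {
        if (pf[j] == 0.0) {
          kkt = std::max(kkt, std::fabs(g[j]));
          continue;
        }
        if (beta[j] != 0.0) {
          kkt = std::max(kkt, std::fabs(g[j] - lam * pf[j] * sgn[j]));
        } else {
          double v = std::fabs(g[j]) - lam * pf[j];
          if (v > kkt_tol) {
            sgn[j] = (g[j] > 0) ? 1.0 : -1.0;
            active.push_back(j);
            ++added;
          }
          if (v > 0) kkt = std::max(kkt, v);
        }
      }
      if (!added) break;  // zeros within tolerance; certificate recorded
    }
    int df = 0;
    for (int j = 0; j < p; ++j) {
      betas(j, m) = beta[j];
      if (pf[j] > 0.0 && beta[j] != 0.0) ++df;
    }
    llv[m] = ll;
    dfv[m] = df;
    kktv[m] = kkt;
    fitted[m] = true;
    if (df > dfmax) break;
  }

  return List::create(_["lambda"] = NumericVector(grid.begin(), grid.end()),
                      _["beta"] = betas, _["loglik"] = llv, _["df"] = dfv,
                      _["kkt"] = kktv, _["fitted"] = fitted,
                      _["lambda_max"] = lmax);
}

namespace {

// pairwise comparability/concordance under Harrell's rules; fills per-subject
// usable-pair counts g and concordance mass h1 (and h2 when s2 given)
void conc_accumulate(const NumericVector& time, const IntegerVector& status,
                     const NumericVector& s1, const NumericVector* s2,
                     std::vector<double>& gbar, std::vector<double>& h1bar,
                     std::vector<double>* h2bar) {
  int n = time.size();
  gbar.assign(n, 0.0);
  h1bar.assign(n, 0.0);
  if (h2bar) h2bar->assign(n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int a = -1, b = -1;  // a = subject whose event orders the pair
      if (time[i] < time[j]) {
        if (status[i] == 1) { a = i; b = j; }
      } else if (time[j] < time[i]) {
        if (status[j] == 1) { a = j; b = i; }
      } else {  // tied times: event vs censored is comparable
        if (status[i] == 1 && status[j] == 0) { a = i; b = j; }
        else if (status[j] == 1 && status[i] == 0) { a = j; b = i; }
      }
      if (a < 0) continue;
      gbar[i] += 1.0;
      gbar[j] += 1.0;
      double c1 = (s1[a] > s1[b]) ? 1.0 : (s1[a] == s1[b] ? 0.5 : 0.0);
      h1bar[i] += c1;
      h1bar[j] += c1;
      if (s2 && h2bar) {
        double c2 = ((*s2)[a] > (*s2)[b]) ? 1.0 : ((*s2)[a] == (*s2)[b] ? 0.5 : 0.0);
        (*h2bar)[i] += c2;
        (*h2bar)[j] += c2;
      }
    }
  }
}

}  // namespace

// Harrell's C with a U-statistic projection variance.
// [[Rcpp::export]]
List concordance_cpp(NumericVector time, IntegerVector status, NumericVector score) {
  int n = time.size();
  std::vector<double> gbar, hbar;
  conc_accumulate(time, status, score, nullptr, gbar, hbar, nullptr);
  double sg = 0.0, sh = 0.0;
  for (int i = 0; i < n; ++i) { sg += gbar[i]; sh += hbar[i]; }
  double npairs = sg / 2.0, conc = sh / 2.0;
  if (npairs <= 0)
    return List::create(_["C"] = NA_REAL, _["pairs"] = 0.0, _["var"] = NA_REAL);
  double C = conc / npairs;
  double Ug = sg / (double)n / (double)(n - 1);
  double mean_phi = 0.0;
  std::vector<double> phi(n);
  for (int i = 0; i < n; ++i) {
    double gb = gbar[i] / (n - 1.0), hb = hbar[i] / (n - 1.0);
    phi[i] = (hb - C * gb) / Ug;
    mean_phi += phi[i];
  }
  mean_phi /= n;
  double v = 0.0;
  for (int i = 0; i < n; ++i) v += (phi[i] - mean_phi) * (phi[i] - mean_phi);
  v = (n > 1) ? v / (n - 1.0) : 0.0;
  double varC = 4.0 * v / n;
  return List::create(_["C"] = C, _["pairs"] = npairs, _["var"] = varC);
}

// Difference of two correlated C-indices with U-statistic variance of the
// difference (projection / delta-method estimator).
// [[Rcpp::export]]
List compare_c_cpp(NumericVector time, IntegerVector status, NumericVector s1,
                   NumericVector s2) {
  int n = time.size();
  std::vector<double> gbar, h1bar, h2bar;
  conc_accumulate(time, status, s1, &s2, gbar, h1bar, &h2bar);
  double sg = 0.0, sh1 = 0.0, sh2 = 0.0;
  for (int i = 0; i < n; ++i) { sg += gbar[i]; sh1 += h1bar[i]; sh2 += h2bar[i]; }
  if (sg <= 0)
    return List::create(_["C1"] = NA_REAL, _["C2"] = NA_REAL,
                        _["var_diff"] = NA_REAL);
  double C1 = sh1 / sg, C2 = sh2 / sg;
  double Ug = sg / (double)n / (double)(n - 1);
  std::vector<double> phi1(n), phi2(n);
  double m1 = 0.0, m2 = 0.0;
  for (int i = 0; i < n; ++i) {
    double gb = gbar[i] / (n - 1.0);
    phi1[i] = (h1bar[i] / (n - 1.0) - C1 * gb) / Ug;
    phi2[i] = (h2bar[i] / (n - 1.0) - C2 * gb) / Ug;
    m1 += phi1[i];
    m2 += phi2[i];
  }
  m1 /= n; m2 /= n;
  double v1 = 0.0, v2 = 0.0, cv = 0.0;
  for (int i = 0; i < n; ++i) {
    v1 += (phi1[i] - m1) * (phi1[i] - m1);
    v2 += (phi2[i] - m2) * (phi2[i] - m2);
    cv += (phi1[i] - m1) * (phi2[i] - m2);
  }
  double denom = (n > 1) ? (n - 1.0) : 1.0;
  v1 /= denom; v2 /= denom; cv /= denom;
  double var1 = 4.0 * v1 / n, var2 = 4.0 * v2 / n, cov12 = 4.0 * cv / n;
  double var_diff = var1 + var2 - 2.0 * cov12;
  if (var_diff < 0) var_diff = 0.0;
  return List::create(_["C1"] = C1, _["C2"] = C2, _["var1"] = var1,
                      _["var2"] = var2, _["cov"] = cov12,
                      _["var_diff"] = var_diff);
}
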