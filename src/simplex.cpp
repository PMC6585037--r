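// Dense bounded-variable primal simplex.
//
// Solves  min c'x  s.t.  rlb <= A x <= rub,  lb <= x <= ub
// after rewriting every row as an equality through a logical (slack)
// variable bounded by the row range: [A -I] [x; s] = 0, s in [rlb, rub].
// Phase 1 uses a single artificial column scaled so the slack basis is
// feasible at t = 1; minimizing t to zero yields a feasible basis.
//
// Scope: the small dense LPs of toy/desk-scale metabolic networks
// (tens of rows/columns). Not a general-purpose solver.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

enum Status { OPTIMAL = 0, INFEASIBLE = 1, UNBOUNDED = 2, ITER_LIMIT = 3, NUMERIC_FAIL = 9 };

struct Simplex {
  int m, n, N;                 // rows, structural cols, total cols (n + m + 1)
  std::vector<double> W;       // tableau B^{-1} G, m x N, row-major
  std::vector<double> LB, UB;  // bounds per column
  std::vector<double> val;     // nonbasic resting value per column
  std::vector<int> basis;      // basic column per row
  std::vector<char> inbasis;
  std::vector<double> xB;      // basic values
  double tol;

  double& w(int i, int j) { return W[(size_t)i * N + j]; }

  void recompute_xB() {
    for (int i = 0; i < m; ++i) xB[i] = 0.0;
    for (int j = 0; j < N; ++j) {
      if (inbasis[j] || val[j] == 0.0) continue;
      double v = val[j];
      for (int i = 0; i < m; ++i) xB[i] -= w(i, j) * v;
    }
  }

  // one phase of minimization for cost vector cc; returns status
  int iterate(const std::vector<double>& cc, int max_iter) {
    std::vector<double> y(m);
    int degen = 0;
    bool bland = false;
    for (int iter = 0; iter < max_iter; ++iter) {
      for (int i = 0; i < m; ++i) y[i] = cc[basis[i]];
      // entering
      int enter = -1, dir = 0;
      double best = tol;
      for (int j = 0; j < N; ++j) {
        if (inbasis[j] || LB[j] == UB[j]) continue;
        double r = cc[j];
        for (int i = 0; i < m; ++i) r -= y[i] * w(i, j);
        bool at_lb = std::isfinite(LB[j]) && val[j] <= LB[j] + 1e-12;
        bool at_ub = std::isfinite(UB[j]) && val[j] >= UB[j] - 1e-12;
        bool freev = !at_lb && !at_ub;
        int d = 0;
        double gain = 0.0;
        if (freev) { if (std::fabs(r) > tol) { d = r > 0 ? -1 : 1; gain = std::fabs(r); } }
        else if (at_lb && r < -tol) { d = 1; gain = -r; }
        else if (at_ub && r > tol) { d = -1; gain = r; }
        if (d != 0) {
          if (bland) { enter = j; dir = d; break; }
          if (gain > best) { best = gain; enter = j; dir = d; }
        }
      }
      if (enter < 0) return OPTIMAL;

      // ratio test
      double delta = INF;
      int lrow = -1;        // leaving basic row; -1 => bound flip of entering
      double lpiv = 0.0;
      if (std::isfinite(UB[enter] - LB[enter])) delta = UB[enter] - LB[enter];
      for (int i = 0; i < m; ++i) {
        double rate = -w(i, enter) * dir;   // d xB_i / d delta
        double lim = INF;
        int bj = basis[i];
        if (rate > 1e-9) {
          if (std::isfinite(UB[bj])) lim = (UB[bj] - xB[i]) / rate;
        } else if (rate < -1e-9) {
          if (std::isfinite(LB[bj])) lim = (xB[i] - LB[bj]) / (-rate);
        }
        if (lim < -1e-9) lim = 0.0;
        if (lim < delta - 1e-10 ||
            (lim < delta + 1e-10 && lrow >= 0 && std::fabs(w(i, enter)) > std::fabs(lpiv)) ||
            (bland && lim < delta + 1e-10 && lrow >= 0 && basis[i] < basis[lrow])) {
          if (lim < delta) delta = lim;
          lrow = i; lpiv = w(i, enter);
        }
      }
      if (!std::isfinite(delta)) return UNBOUNDED;
      if (delta < 1e-11) { if (++degen > 2 * (m + 5)) bland = true; }
      else { degen = 0; bland = false; }

      if (lrow < 0) {
        // bound flip
        val[enter] = (dir > 0) ? UB[enter] : LB[enter];
        recompute_xB();
        continue;
      }
      int leave = basis[lrow];
      double rate = -w(lrow, enter) * dir;
      val[leave] = (rate > 0) ? UB[leave] : LB[leave];
      if (!std::isfinite(val[leave])) return NUMERIC_FAIL;
      // pivot
      double p = w(lrow, enter);
      if (std::fabs(p) < 1e-11) return NUMERIC_FAIL;
      for (int j = 0; j < N; ++j) w(lrow, j) /= p;
      for (int i = 0; i < m; ++i) {
        if (i == lrow) continue;
        double f = w(i, enter);
        if (f == 0.0) continue;
        for (int j = 0; j < N; ++j) w(i, j) -= f * w(lrow, j);
        w(i, enter) = 0.0;   // exact
      }
      w(lrow, enter) = 1.0;
      inbasis[leave] = 0;
      inbasis[enter] = 1;
      basis[lrow] = enter;
      recompute_xB();
    }
    return ITER_LIMIT;
  }
};

// [[Rcpp::export(name = ".simplex_solve")]]
List simplex_solve(NumericVector obj, NumericMatrix A,
                   NumericVector rlb, NumericVector rub,
                   NumericVector lb, NumericVector ub,
                   bool maximize = false, int max_iter = 50000) {
  int m = A.nrow(), n = A.ncol();
  Simplex S;
  S.m = m; S.n = n; S.N = n + m + 1;
  S.tol = 1e-9;
  S.W.assign((size_t)m * S.N, 0.0);
  S.LB.resize(S.N); S.UB.resize(S.N); S.val.assign(S.N, 0.0);
  S.basis.resize(m); S.inbasis.assign(S.N, 0); S.xB.assign(m, 0.0);

  for (int j = 0; j < n; ++j) { S.LB[j] = lb[j]; S.UB[j] = ub[j]; }
  for (int i = 0; i < m; ++i) { S.LB[n + i] = rlb[i]; S.UB[n + i] = rub[i]; }
  int tcol = n + m;
  S.LB[tcol] = 0.0; S.UB[tcol] = 1.0;

  // nonbasic resting values for x
  for (int j = 0; j < n; ++j) {
    if (std::isfinite(lb[j])) S.val[j] = lb[j];
    else if (std::isfinite(ub[j])) S.val[j] = ub[j];
    else S.val[j] = 0.0;
  }
  // slack basis: B = -I (G slack columns are -e_i), so W = -G = [-A, I, -d]
  std::vector<double> act(m, 0.0), d(m, 0.0);
  for (int i = 0; i < m; ++i) {
    double a = 0.0;
    for (int j = 0; j < n; ++j) a += A(i, j) * S.val[j];
    act[i] = a;
    double cl = a;
    if (cl < rlb[i]) cl = rlb[i];
    if (cl > rub[i]) cl = rub[i];
    d[i] = cl - a;
  }
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) S.w(i, j) = -A(i, j);
    S.w(i, n + i) = 1.0;
    S.w(i, tcol) = -d[i];
    S.basis[i] = n + i;
    S.inbasis[n + i] = 1;
  }

  double dmax = 0.0;
  for (int i = 0; i < m; ++i) dmax = std::max(dmax, std::fabs(d[i]));
  int status;
  std::vector<double> cc(S.N, 0.0);
  if (dmax > 1e-10) {
    S.val[tcol] = 1.0;
    S.recompute_xB();
    cc[tcol] = 1.0;
    status = S.iterate(cc, max_iter);
    double tval = S.inbasis[tcol] ? 0.0 : S.val[tcol];
    if (S.inbasis[tcol]) {
      for (int i = 0; i < m; ++i) if (S.basis[i] == tcol) tval = S.xB[i];
    }
    if (status == UNBOUNDED) status = NUMERIC_FAIL;
    if (status == OPTIMAL && tval > 1e-7) status = INFEASIBLE;
    if (status != OPTIMAL)
      return List::create(_["status"] = (int)status, _["x"] = R_NilValue, _["objval"] = NA_REAL);
    S.LB[tcol] = S.UB[tcol] = 0.0;
    if (!S.inbasis[tcol]) S.val[tcol] = 0.0;
    S.recompute_xB();
  } else {
    S.LB[tcol] = S.UB[tcol] = 0.0;
    S.val[tcol] = 0.0;
    S.recompute_xB();
  }

  std::fill(cc.begin(), cc.end(), 0.0);
  double sgn = maximize ? -1.0 : 1.0;
  for (int j = 0; j < n; ++j) cc[j] = sgn * obj[j];
  status = S.iterate(cc, max_iter);
  if (status != OPTIMAL && status != UNBOUNDED)
    return List::create(_["status"] = (int)status, _["x"] = R_NilValue, _["objval"] = NA_REAL);

  NumericVector x(n);
  for (int j = 0; j < n; ++j) x[j] = S.inbasis[j] ? 0.0 : S.val[j];
  for (int i = 0; i < m; ++i) if (S.basis[i] < n) x[S.basis[i]] = S.xB[i];
  // clip roundoff onto bounds
  for (int j = 0; j < n; ++j) {
    if (std::isfinite(lb[j]) && x[j] < lb[j]) x[j] = lb[j];
    if (std::isfinite(ub[j]) && x[j] > ub[j]) x[j] = ub[j];
  }
  double objval = 0.0;
  for (int j = 0; j < n; ++j) objval += obj[j] * x[j];
  if (status == UNBOUNDED)
    return List::create(_["status"] = (int)UNBOUNDED, _["x"] = x, _["objval"] = maximize ? R_PosInf : R_NegInf);
  return List::create(_["status"] = (int)OPTIMAL, _["x"] = x, _["objval"] = objval);
}
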