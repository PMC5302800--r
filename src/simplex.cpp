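// Dense bounded-variable two-phase primal simplex.
//
// Solves   max/min  c'x   s.t.  A x {<=,=,>=} b,   l <= x <= u
// with l, u possibly infinite.  Sized for constraint-based metabolic
// models of a few hundred rows/columns; the basis inverse is kept
// explicitly and refactorised periodically to bound round-off drift.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = 1e30;
static const double PIV_TOL = 1e-9;   // minimal acceptable pivot magnitude
static const double DJ_TOL = 1e-9;    // reduced-cost optimality tolerance
static const double FEAS_TOL = 1e-8;  // bound/row feasibility tolerance

struct LP {
  int m, n;                  // rows, total columns (structural+slack+artificial)
  int nstruct;               // structural columns
  std::vector<double> Acol;  // dense columns, m * n
  std::vector<double> b;
  std::vector<double> lb, ub;
  std::vector<double> obj;   // current phase objective
  std::vector<int> basis;    // size m, column index basic in each row
  std::vector<int> vstat;    // 0 nonbasic-lb, 1 nonbasic-ub, 2 basic, 3 nonbasic-free(0)
  std::vector<double> x;     // current values, size n
  std::vector<double> Binv;  // m*m row-major
  double* col(int j) { return &Acol[(size_t)j * m]; }
};

static void refactorize(LP& lp) {
  int m = lp.m;
  // Gauss-Jordan inversion of the basis matrix with partial pivoting.
  std::vector<double> M((size_t)m * 2 * m, 0.0);
  for (int i = 0; i < m; ++i) {
    for (int k = 0; k < m; ++k) M[(size_t)i * 2 * m + k] = lp.col(lp.basis[k])[i];
    M[(size_t)i * 2 * m + m + i] = 1.0;
  }
  for (int p = 0; p < m; ++p) {
    int best = p; double bv = std::fabs(M[(size_t)p * 2 * m + p]);
    for (int i = p + 1; i < m; ++i) {
      double v = std::fabs(M[(size_t)i * 2 * m + p]);
      if (v > bv) { bv = v; best = i; }
    }
    if (best != p)
      for (int k = 0; k < 2 * m; ++k) std::swap(M[(size_t)p * 2 * m + k], M[(size_t)best * 2 * m + k]);
    double piv = M[(size_t)p * 2 * m + p];
    if (std::fabs(piv) < 1e-12) piv = (piv >= 0 ? 1e-12 : -1e-12);
    double inv = 1.0 / piv;
    for (int k = 0; k < 2 * m; ++k) M[(size_t)p * 2 * m + k] *= inv;
    for (int i = 0; i < m; ++i) {
      if (i == p) continue;
      double f = M[(size_t)i * 2 * m + p];
      if (f == 0.0) continue;
      for (int k = 0; k < 2 * m; ++k) M[(size_t)i * 2 * m + k] -= f * M[(size_t)p * 2 * m + k];
    }
  }
  for (int i = 0; i < m; ++i)
    for (int k = 0; k < m; ++k) lp.Binv[(size_t)i * m + k] = M[(size_t)i * 2 * m + m + k];
}

static void recompute_basics(LP& lp) {
  int m = lp.m;
  // x_B = Binv (b - sum_{nonbasic} A_j x_j)
  std::vector<double> r(lp.b);
  for (int j = 0; j < lp.n; ++j) {
    if (lp.vstat[j] == 2) continue;
    double v = lp.x[j];
    if (v == 0.0) continue;
    double* a = lp.col(j);
    for (int i = 0; i < m; ++i) r[i] -= a[i] * v;
  }
  for (int i = 0; i < m; ++i) {
    double s = 0.0;
    const double* bi = &lp.Binv[(size_t)i * m];
    for (int k = 0; k < m; ++k) s += bi[k] * r[k];
    lp.x[lp.basis[i]] = s;
  }
}

// one simplex phase; returns 0 optimal, 1 unbounded, 2 iteration limit
static int simplex_phase(LP& lp, int maxit, bool phase1) {
  int m = lp.m, n = lp.n;
  std::vector<double> y(m), w(m);
  int stall = 0, since_refac = 0;
  double last_obj = -INF;

  for (int it = 0; it < maxit; ++it) {
    // duals y' = c_B' Binv
    for (int k = 0; k < m; ++k) {
      double s = 0.0;
      for (int i = 0; i < m; ++i) s += lp.obj[lp.basis[i]] * lp.Binv[(size_t)i * m + k];
      y[k] = s;
    }
    bool bland = stall > 2 * (m + n);
    int enter = -1, dir = 0; double bestv = DJ_TOL;
    for (int j = 0; j < n; ++j) {
      int st = lp.vstat[j];
      if (st == 2) continue;
      if (lp.lb[j] >= lp.ub[j] - 1e-15 && st != 3) continue;  // fixed
      double* a = lp.col(j);
      double d = lp.obj[j];
      for (int i = 0; i < m; ++i) d -= y[i] * a[i];
      int dj_dir = 0;
      if (st == 0 && d > DJ_TOL) dj_dir = 1;
      else if (st == 1 && d < -DJ_TOL) dj_dir = -1;
      else if (st == 3 && std::fabs(d) > DJ_TOL) dj_dir = (d > 0 ? 1 : -1);
      if (!dj_dir) continue;
      if (bland) { enter = j; dir = dj_dir; break; }
      if (std::fabs(d) > bestv) { bestv = std::fabs(d); enter = j; dir = dj_dir; }
    }
    if (enter < 0) return 0;  // optimal

    // w = Binv * A_enter
    {
      double* a = lp.col(enter);
      for (int i = 0; i < m; ++i) {
        double s = 0.0;
        const double* bi = &lp.Binv[(size_t)i * m];
        for (int k = 0; k < m; ++k) s += bi[k] * a[k];
        w[i] = s;
      }
    }
    // ratio test: entering moves by t*dir, basic i moves by -dir*w[i]*t
    double tmax = (lp.ub[enter] - lp.lb[enter] < INF) ? (lp.ub[enter] - lp.lb[enter]) : INF;
    int leave = -1; double lt = tmax; int leave_bound = 0;  // 0 lb, 1 ub
    for (int i = 0; i < m; ++i) {
      double coef = -dir * w[i];
      if (std::fabs(coef) < PIV_TOL) continue;
      int bj = lp.basis[i];
      double v = lp.x[bj], lim, t;
      if (coef > 0) {
        lim = lp.ub[bj];
        if (lim >= INF) continue;
        t = (lim - v) / coef;
      } else {
        lim = lp.lb[bj];
        if (lim <= -INF) continue;
        t = (lim - v) / coef;
      }
      if (t < -1e-11) t = 0.0;
      if (t < lt - 1e-12 || (bland && t <= lt + 1e-12 && (leave < 0 || bj < lp.basis[leave]))) {
        lt = t; leave = i; leave_bound = (coef > 0) ? 1 : 0;
      }
    }
    if (lt >= INF) return 1;  // unbounded
    if (lt < 0) lt = 0;

    // apply step
    for (int i = 0; i < m; ++i) lp.x[lp.basis[i]] += -dir * w[i] * lt;
    lp.x[enter] += dir * lt;

    double cur = 0.0;
    for (int j = 0; j < n; ++j) if (lp.obj[j] != 0.0) cur += lp.obj[j] * lp.x[j];
    if (cur > last_obj + 1e-12) { stall = 0; last_obj = cur; } else ++stall;

    if (leave < 0) {
      // bound flip of entering variable
      lp.vstat[enter] = (dir > 0) ? 1 : 0;
      if (lp.vstat[enter] == 1) lp.x[enter] = lp.ub[enter]; else lp.x[enter] = lp.lb[enter];
      continue;
    }
    int out = lp.basis[leave];
    lp.vstat[out] = leave_bound;
    lp.x[out] = leave_bound ? lp.ub[out] : lp.lb[out];
    lp.basis[leave] = enter;
    lp.vstat[enter] = 2;
    // eta update of Binv
    double piv = w[leave];
    if (std::fabs(piv) < PIV_TOL) { refactorize(lp); recompute_basics(lp); continue; }
    double* rr = &lp.Binv[(size_t)leave * m];
    for (int k = 0; k < m; ++k) rr[k] /= piv;
    for (int i = 0; i < m; ++i) {
      if (i == leave) continue;
      double f = w[i];
      if (f == 0.0) continue;
      double* ri = &lp.Binv[(size_t)i * m];
      for (int k = 0; k < m; ++k) ri[k] -= f * rr[k];
    }
    if (++since_refac >= 150) {
      refactorize(lp); recompute_basics(lp); since_refac = 0;
    }
  }
  return 2;
}

// [[Rcpp::export(name = ".cpp_simplex")]]
List cpp_simplex(NumericMatrix Amat, NumericVector rhs, IntegerVector sense,
                 NumericVector lower, NumericVector upper, NumericVector objective,
                 bool maximize, int maxit) {
  int m = Amat.nrow(), ns = Amat.ncol();
  LP lp;
  lp.m = m; lp.nstruct = ns;
  int nslack = m;               // one slack per row (fixed to 0 for '=' rows)
  int nart = m;
  lp.n = ns + nslack + nart;
  lp.Acol.assign((size_t)lp.n * m, 0.0);
  lp.b.assign(rhs.begin(), rhs.end());
  lp.lb.assign(lp.n, 0.0); lp.ub.assign(lp.n, 0.0);
  lp.obj.assign(lp.n, 0.0);
  lp.x.assign(lp.n, 0.0);
  lp.vstat.assign(lp.n, 0);
  lp.basis.assign(m, 0);
  lp.Binv.assign((size_t)m * m, 0.0);

  for (int j = 0; j < ns; ++j) {
    double* a = lp.col(j);
    for (int i = 0; i < m; ++i) a[i] = Amat(i, j);
    double l = lower[j], u = upper[j];
    if (!R_finite(l)) l = -INF;
    if (!R_finite(u)) u = INF;
    lp.lb[j] = l; lp.ub[j] = u;
    // nonbasic start at the finite bound closest to zero, or free at 0
    if (l <= -INF && u >= INF) { lp.vstat[j] = 3; lp.x[j] = 0.0; }
    else if (l <= -INF) { lp.vstat[j] = 1; lp.x[j] = u; }
    else if (u >= INF) { lp.vstat[j] = 0; lp.x[j] = l; }
    else { if (std::fabs(l) <= std::fabs(u)) { lp.vstat[j] = 0; lp.x[j] = l; }
           else { lp.vstat[j] = 1; lp.x[j] = u; } }
  }
  for (int i = 0; i < m; ++i) {
    int j = ns + i;
    lp.col(j)[i] = 1.0;
    if (sense[i] < 0) { lp.lb[j] = 0.0; lp.ub[j] = INF; lp.vstat[j] = 0; }
    else if (sense[i] > 0) { lp.lb[j] = -INF; lp.ub[j] = 0.0; lp.vstat[j] = 1; }
    else { lp.lb[j] = 0.0; lp.ub[j] = 0.0; lp.vstat[j] = 0; }
    lp.x[j] = 0.0;
  }
  // residuals determine artificial orientation
  std::vector<double> r(lp.b);
  for (int j = 0; j < ns; ++j) {
    double v = lp.x[j];
    if (v == 0.0) continue;
    double* a = lp.col(j);
    for (int i = 0; i < m; ++i) r[i] -= a[i] * v;
  }
  for (int i = 0; i < m; ++i) {
    int j = ns + nslack + i;
    lp.col(j)[i] = 1.0;
    if (r[i] >= 0) { lp.lb[j] = 0.0; lp.ub[j] = INF; lp.obj[j] = -1.0; }
    else { lp.lb[j] = -INF; lp.ub[j] = 0.0; lp.obj[j] = 1.0; }
    lp.basis[i] = j; lp.vstat[j] = 2; lp.x[j] = r[i];
    lp.Binv[(size_t)i * m + i] = 1.0;
  }

  std::string status = "optimal";
  int rc = simplex_phase(lp, maxit, true);
  double infeas = 0.0;
  for (int i = 0; i < m; ++i) {
    int j = ns + nslack + i;
    infeas += std::fabs(lp.x[j]);
  }
  if (rc == 2) status = "maxit";
  else if (infeas > 1e-6) status = "infeasible";
  else {
    // phase 2: fix artificials at zero, restore true objective
    for (int i = 0; i < m; ++i) {
      int j = ns + nslack + i;
      lp.lb[j] = 0.0; lp.ub[j] = 0.0; lp.obj[j] = 0.0;
      if (lp.vstat[j] != 2) lp.x[j] = 0.0;
    }
    for (int j = 0; j < ns; ++j) lp.obj[j] = maximize ? objective[j] : -objective[j];
    refactorize(lp); recompute_basics(lp);
    rc = simplex_phase(lp, maxit, false);
    if (rc == 1) status = "unbounded";
    else if (rc == 2) status = "maxit";
  }

  NumericVector xout(ns);
  double z = 0.0;
  for (int j = 0; j < ns; ++j) { xout[j] = lp.x[j]; z += objective[j] * lp.x[j]; }
  // duals of the rows under the true objective
  NumericVector duals(m);
  if (status == "optimal") {
    for (int k = 0; k < m; ++k) {
      double s = 0.0;
      for (int i = 0; i < m; ++i) s += lp.obj[lp.basis[i]] * lp.Binv[(size_t)i * m + k];
      duals[k] = maximize ? s : -s;
    }
  }
  return List::create(_["status"] = status, _["objval"] = z, _["x"] = xout,
                      _["duals"] = duals);
}
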