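#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dense two-phase tableau simplex.
//
// Solves   min c'x   s.t.  A x (rel) b,  x >= 0
// where rel[i] is -1 (<=), 0 (=) or +1 (>=). Upper bounds on variables are
// expressed as <= rows by the R wrapper; problems here are small (a few
// hundred rows/columns) so a dense tableau is adequate.
//
// Anti-cycling: Dantzig pricing with a switch to Bland's rule after an
// iteration budget proportional to problem size.

static const double EPS = 1e-9;

struct Tableau {
  int m, n_total;               // rows, structural+slack+artificial columns
  std::vector<double> T;        // (m+1) x (n_total+1), row-major; last row = objective
  std::vector<int> basis;       // basic column per row
  double& at(int i, int j) { return T[(size_t)i * (n_total + 1) + j]; }
};

static void pivot(Tableau& tb, int pr, int pc) {
  int w = tb.n_total + 1;
  double piv = tb.at(pr, pc);
  for (int j = 0; j < w; ++j) tb.at(pr, j) /= piv;
  for (int i = 0; i <= tb.m; ++i) {
    if (i == pr) continue;
    double f = tb.at(i, pc);
    if (std::fabs(f) < EPS) continue;
    for (int j = 0; j < w; ++j) tb.at(i, j) -= f * tb.at(pr, j);
  }
  tb.basis[pr] = pc;
}

// returns 0 optimal, 1 unbounded
static int run_simplex(Tableau& tb, int ncols_active) {
  long iter = 0, bland_after = 50L * (tb.m + ncols_active), max_iter = 2000L * (tb.m + ncols_active) + 20000L;
  while (true) {
    if (++iter > max_iter) Rcpp::stop("simplex iteration limit exceeded");
    bool bland = iter > bland_after;
    int pc = -1; double best = -EPS;
    for (int j = 0; j < ncols_active; ++j) {
      double rc = tb.at(tb.m, j);
      if (rc < -EPS) {
        if (bland) { pc = j; break; }
        if (rc < best) { best = rc; pc = j; }
      }
    }
    if (pc < 0) return 0;  // optimal
    int pr = -1; double ratio = 0;
    for (int i = 0; i < tb.m; ++i) {
      double a = tb.at(i, pc);
      if (a > EPS) {
        double r = tb.at(i, tb.n_total) / a;
        if (pr < 0 || r < ratio - EPS ||
            (std::fabs(r - ratio) <= EPS && tb.basis[i] < tb.basis[pr])) {
          pr = i; ratio = r;
        }
      }
    }
    if (pr < 0) return 1;  // unbounded
    pivot(tb, pr, pc);
  }
}

// [[Rcpp::export(name = ".cpp_simplex")]]
List cpp_simplex(NumericVector obj, NumericMatrix A, IntegerVector rel,
                 NumericVector rhs, bool maximize) {
  int m = A.nrow(), n = A.ncol();
  if (obj.size() != n || rel.size() != m || rhs.size() != m)
    stop("inconsistent LP dimensions");

  // column layout: [0,n) structural, then one slack/surplus per inequality,
  // then one artificial per (=, >=, or negative-rhs) row
  int n_slack = 0;
  for (int i = 0; i < m; ++i) if (rel[i] != 0) ++n_slack;

  std::vector<double> a((size_t)m * n);
  std::vector<double> b(m);
  std::vector<int> r(m);
  for (int i = 0; i < m; ++i) {
    double s = (rhs[i] < 0) ? -1.0 : 1.0;   // make rhs nonnegative
    b[i] = s * rhs[i];
    r[i] = (int)(s * rel[i]);
    for (int j = 0; j < n; ++j) a[(size_t)i * n + j] = s * A(i, j);
  }

  // artificial needed where no natural basic column: rows with r==0 or r==+1
  int n_art = 0;
  for (int i = 0; i < m; ++i) if (r[i] != -1) ++n_art;

  Tableau tb;
  tb.m = m;
  tb.n_total = n + n_slack + n_art;
  tb.T.assign((size_t)(m + 1) * (tb.n_total + 1), 0.0);
  tb.basis.assign(m, -1);

  int sc = n, ac = n + n_slack;
  std::vector<int> art_col(m, -1);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) tb.at(i, j) = a[(size_t)i * n + j];
    tb.at(i, tb.n_total) = b[i];
    if (r[i] == -1) { tb.at(i, sc) = 1.0; tb.basis[i] = sc; ++sc; }
    else if (r[i] == 1) { tb.at(i, sc) = -1.0; ++sc; }
    if (r[i] != -1) { tb.at(i, ac) = 1.0; tb.basis[i] = ac; art_col[i] = ac; ++ac; }
  }

  // phase 1: minimise sum of artificials
  if (n_art > 0) {
    for (int i = 0; i < m; ++i)
      if (art_col[i] >= 0)
        for (int j = 0; j <= tb.n_total; ++j) tb.at(m, j) -= tb.at(i, j);
    for (int i = 0; i < m; ++i)
      if (art_col[i] >= 0) tb.at(m, art_col[i]) = 0.0;
    int st = run_simplex(tb, n + n_slack + n_art);
    if (st == 1) stop("phase-1 LP unbounded (internal error)");
    if (tb.at(m, tb.n_total) < -1e-7)
      return List::create(_["status"] = "infeasible", _["objective"] = NA_REAL,
                          _["x"] = NumericVector(0));
    // drive remaining artificials out of the basis
    for (int i = 0; i < m; ++i) {
      if (tb.basis[i] >= n + n_slack) {
        int pc = -1;
        for (int j = 0; j < n + n_slack; ++j)
          if (std::fabs(tb.at(i, j)) > 1e-7) { pc = j; break; }
        if (pc >= 0) pivot(tb, i, pc);
        // else: redundant row, artificial stays at zero level
      }
    }
  }

  // phase 2 objective (min form)
  for (int j = 0; j <= tb.n_total; ++j) tb.at(m, j) = 0.0;
  for (int j = 0; j < n; ++j) tb.at(m, j) = maximize ? -obj[j] : obj[j];
  for (int j = n + n_slack; j < tb.n_total; ++j) tb.at(m, j) = 1e9;  // block artificials
  // restore reduced costs w.r.t. current basis
  for (int i = 0; i < m; ++i) {
    double cb = tb.at(m, tb.basis[i]);
    if (std::fabs(cb) > 0)
      for (int j = 0; j <= tb.n_total; ++j) tb.at(m, j) -= cb * tb.at(i, j);
  }
  int st = run_simplex(tb, n + n_slack);
  if (st == 1)
    return List::create(_["status"] = "unbounded", _["objective"] = NA_REAL,
                        _["x"] = NumericVector(0));

  NumericVector x(n);
  for (int i = 0; i < m; ++i)
    if (tb.basis[i] < n) x[tb.basis[i]] = tb.at(i, tb.n_total);
  double z = -tb.at(m, tb.n_total);
  if (maximize) z = -z;
  return List::create(_["status"] = "optimal", _["objective"] = z, _["x"] = x);
}
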