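// Dense two-phase primal simplex with Bland's rule.
//
// Solves  min c'x  s.t.  A_ub x <= b_ub,  A_eq x = b_eq,  x >= 0.
// Sized for the small LPs arising in the clone-proportion updates
// (tens of variables, ~100 constraints); Bland's rule guarantees
// termination on the degenerate instances these produce.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double EPS = 1e-9;

// [[Rcpp::export]]
List simplex_lp(NumericVector c, NumericMatrix A_ub, NumericVector b_ub,
                NumericMatrix A_eq, NumericVector b_eq, int max_iter = 20000) {
  const int n = c.size();
  const int m1 = b_ub.size();
  const int m2 = b_eq.size();
  const int m = m1 + m2;

  // columns: n structural + m1 slack + m artificial (allocated lazily below)
  const int nslack = m1;
  const int ncol = n + nslack + m; // upper bound on columns
  // tableau rows: m constraints + phase2 cost + phase1 cost
  std::vector<std::vector<double>> T(m + 2, std::vector<double>(ncol + 1, 0.0));
  std::vector<int> basis(m, -1);
  std::vector<bool> is_artificial(ncol, false);

  int nart = 0;
  std::vector<int> unit_col(m);   // initial identity column of each row
  std::vector<double> b0(m);      // unperturbed rhs, sign-adjusted
  for (int i = 0; i < m; ++i) {
    double bi = (i < m1) ? b_ub[i] : b_eq[i - m1];
    for (int j = 0; j < n; ++j)
      T[i][j] = (i < m1) ? A_ub(i, j) : A_eq(i - m1, j);
    if (i < m1) T[i][n + i] = 1.0; // slack
    // deterministic perturbation against degenerate pivot stalls; the
    // final solution is reconstructed with the exact rhs below
    T[i][ncol] = bi + 1e-9 * (i + 1);
    double sign = 1.0;
    if (T[i][ncol] < 0) {
      sign = -1.0;
      for (int j = 0; j <= ncol; ++j) T[i][j] = -T[i][j];
    }
    b0[i] = sign * bi;
    bool need_art = true;
    if (i < m1 && T[i][n + i] > 0.5) { // slack still +1 => usable basis
      basis[i] = n + i;
      need_art = false;
      unit_col[i] = n + i;
    }
    if (need_art) {
      int col = n + nslack + nart;
      T[i][col] = 1.0;
      is_artificial[col] = true;
      basis[i] = col;
      unit_col[i] = col;
      ++nart;
    }
  }
  const int used_cols = n + nslack + nart;

  // phase-2 cost row
  for (int j = 0; j < n; ++j) T[m][j] = c[j];
  // phase-1 cost row: sum of artificials; express in nonbasic terms
  for (int i = 0; i < m; ++i) {
    if (is_artificial[basis[i]]) {
      for (int j = 0; j <= ncol; ++j) T[m + 1][j] -= T[i][j];
    }
  }
  // make cost rows consistent with initial basis for phase 2 as well
  for (int i = 0; i < m; ++i) {
    int b = basis[i];
    double cb = T[m][b];
    if (std::abs(cb) > 0) {
      for (int j = 0; j <= ncol; ++j) T[m][j] -= cb * T[i][j];
    }
  }

  auto pivot = [&](int prow, int pcol) {
    double pv = T[prow][pcol];
    for (int j = 0; j <= ncol; ++j) T[prow][j] /= pv;
    for (int i = 0; i < m + 2; ++i) {
      if (i == prow) continue;
      double f = T[i][pcol];
      if (std::abs(f) < 1e-14) continue;
      for (int j = 0; j <= ncol; ++j) T[i][j] -= f * T[prow][j];
    }
    basis[prow] = pcol;
  };

  auto run_phase = [&](int costrow, bool allow_art) -> int {
    // Dantzig rule for speed; switch to Bland's rule (guaranteed
    // termination) if the iteration count suggests cycling
    const int bland_after = 5 * (m + used_cols);
    for (int iter = 0; iter < max_iter; ++iter) {
      int enter = -1;
      if (iter < bland_after) {
        double most = -EPS;
        for (int j = 0; j < used_cols; ++j) {
          if (!allow_art && is_artificial[j]) continue;
          if (T[costrow][j] < most) { most = T[costrow][j]; enter = j; }
        }
      } else {
        for (int j = 0; j < used_cols; ++j) {
          if (!allow_art && is_artificial[j]) continue;
          if (T[costrow][j] < -EPS) { enter = j; break; }
        }
      }
      if (enter < 0) return 0; // optimal
      int leave = -1;
      double best = std::numeric_limits<double>::infinity();
      for (int i = 0; i < m; ++i) {
        if (T[i][enter] > EPS) {
          double ratio = T[i][ncol] / T[i][enter];
          if (ratio < best - EPS ||
              (ratio < best + EPS && (leave < 0 || basis[i] < basis[leave]))) {
            best = ratio;
            leave = i;
          }
        }
      }
      if (leave < 0) return 2; // unbounded
      pivot(leave, enter);
    }
    return 3; // iteration limit
  };

  int st = run_phase(m + 1, true);
  if (st != 0) return List::create(_["status"] = st);
  if (T[m + 1][ncol] < -1e-7) {
    return List::create(_["status"] = 1); // infeasible
  }
  // drive artificials out of the basis where possible
  for (int i = 0; i < m; ++i) {
    if (is_artificial[basis[i]]) {
      int enter = -1;
      for (int j = 0; j < n + nslack; ++j) {
        if (std::abs(T[i][j]) > EPS) { enter = j; break; }
      }
      if (enter >= 0) pivot(i, enter);
    }
  }
  st = run_phase(m, false);
  if (st != 0) return List::create(_["status"] = st);

  // reconstruct the basic solution with the unperturbed rhs: row i of the
  // final tableau holds row i of B^-1 in the initial identity columns
  NumericVector x(n);
  for (int i = 0; i < m; ++i) {
    if (basis[i] < n) {
      double xi = 0.0;
      for (int j = 0; j < m; ++j) xi += T[i][unit_col[j]] * b0[j];
      x[basis[i]] = xi > 0 ? xi : 0.0;
    }
  }
  double val = 0.0;
  for (int j = 0; j < n; ++j) val += c[j] * x[j];
  return List::create(_["status"] = 0, _["x"] = x, _["value"] = val);
}
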