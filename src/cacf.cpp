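// Exact per-cluster integer copy-number update for the constrained
// allele-specific factorization.
//
// For fixed clone proportions U the weighted-L1 objective separates by
// cluster; per cluster the minimization over integer allele copy numbers is
// solved by enumerating tumor-clone copy vectors that satisfy the
// one-sidedness constraint around theta, and coupling the two alleles
// through a_i + b_i <= cmax. For <= 2 tumor clones all (A, B) vector pairs
// are enumerated directly with the (theta, theta)-proximity tie-break; for
// more clones a box-minimum dynamic program over the copy grid finds, for
// each A vector, the best compatible B vector.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// enumerate vectors in {0..cmax}^nt with all entries <= theta or >= theta
static void valid_vectors(int nt, int cmax, int theta,
                          std::vector<std::vector<int>> &out) {
  std::vector<int> v(nt, 0);
  long total = 1;
  for (int i = 0; i < nt; ++i) total *= (cmax + 1);
  for (long code = 0; code < total; ++code) {
    long c = code;
    bool all_le = true, all_ge = true;
    for (int i = 0; i < nt; ++i) {
      v[i] = c % (cmax + 1);
      c /= (cmax + 1);
      if (v[i] > theta) all_le = false;
      if (v[i] < theta) all_ge = false;
    }
    if (all_le || all_ge) out.push_back(v);
  }
}

// cost of tumor copy vector products P (nv x k) for one cluster row
static inline double row_cost(const std::vector<double> &P, int iv, int k,
                              const double *f, const double *u1, double len) {
  double s = 0.0;
  for (int p = 0; p < k; ++p) {
    s += std::fabs(f[p] - u1[p] - P[(size_t)iv * k + p]);
  }
  return len * s;
}

static inline double tie_key(const std::vector<int> &a, int theta) {
  double s = 0.0;
  for (size_t i = 0; i < a.size(); ++i) s += std::abs(a[i] - theta);
  return s;
}

static bool lex_less(const std::vector<int> &a, const std::vector<int> &b,
                     const std::vector<int> &a2, const std::vector<int> &b2) {
  // compare concatenated (A vector, B vector) lexicographically
  for (size_t i = 0; i < a.size(); ++i) {
    if (a[i] != a2[i]) return a[i] < a2[i];
  }
  for (size_t i = 0; i < b.size(); ++i) {
    if (b[i] != b2[i]) return b[i] < b2[i];
  }
  return false;
}

// [[Rcpp::export]]
List cacf_update_ab(NumericMatrix FA, NumericMatrix FB, NumericVector lens,
                    NumericMatrix U, int cmax, int theta) {
  const int m = FA.nrow();
  const int k = FA.ncol();
  const int n = U.nrow();
  const int nt = n - 1;
  if (nt < 1) stop("At least one tumor clone is required.");
  if (nt > 5) stop("Copy-number update supports at most 5 tumor clones.");

  std::vector<std::vector<int>> V;
  valid_vectors(nt, cmax, theta, V);
  const int nv = V.size();

  // products P[v, p] = sum_i v_i * u_{i+1, p}
  std::vector<double> P((size_t)nv * k);
  for (int iv = 0; iv < nv; ++iv) {
    for (int p = 0; p < k; ++p) {
      double s = 0.0;
      for (int i = 0; i < nt; ++i) s += V[iv][i] * U(i + 1, p);
      P[(size_t)iv * k + p] = s;
    }
  }
  std::vector<double> u1(k);
  for (int p = 0; p < k; ++p) u1[p] = U(0, p);

  IntegerMatrix A(m, n), B(m, n);
  for (int s = 0; s < m; ++s) { A(s, 0) = 1; B(s, 0) = 1; }
  double total = 0.0;

  std::vector<double> costA(nv), costB(nv);
  // DP structures over the full grid for nt >= 3
  long grid = 1;
  for (int i = 0; i < nt; ++i) grid *= (cmax + 1);
  std::vector<double> boxmin;
  std::vector<int> boxarg;
  std::vector<long> code_of(nv);
  std::vector<long> stride(nt);
  stride[0] = 1;
  for (int i = 1; i < nt; ++i) stride[i] = stride[i - 1] * (cmax + 1);
  for (int iv = 0; iv < nv; ++iv) {
    long code = 0;
    for (int i = 0; i < nt; ++i) code += stride[i] * V[iv][i];
    code_of[iv] = code;
  }

  std::vector<double> fa(k), fb(k);
  for (int s = 0; s < m; ++s) {
    for (int p = 0; p < k; ++p) { fa[p] = FA(s, p); fb[p] = FB(s, p); }
    const double len = lens[s];
    for (int iv = 0; iv < nv; ++iv) {
      costA[iv] = row_cost(P, iv, k, fa.data(), u1.data(), len);
      costB[iv] = row_cost(P, iv, k, fb.data(), u1.data(), len);
    }
    int best_a = -1, best_b = -1;
    double best = INF;
    if (nt <= 2) {
      double best_key = INF;
      for (int ia = 0; ia < nv; ++ia) {
        for (int ib = 0; ib < nv; ++ib) {
          bool ok = true;
          for (int i = 0; i < nt; ++i) {
            if (V[ia][i] + V[ib][i] > cmax) { ok = false; break; }
          }
          if (!ok) continue;
          double cst = costA[ia] + costB[ib];
          if (cst < best - 1e-12) {
            best = cst; best_a = ia; best_b = ib;
            best_key = tie_key(V[ia], theta) + tie_key(V[ib], theta);
          } else if (cst < best + 1e-12) {
            double key = tie_key(V[ia], theta) + tie_key(V[ib], theta);
            bool better = key < best_key - 1e-12;
            if (!better && key < best_key + 1e-12) {
              better = lex_less(V[ia], V[ib], V[best_a], V[best_b]);
            }
            if (better) { best_a = ia; best_b = ib; best_key = key; }
          }
        }
      }
    } else {
      // box-min DP: boxmin[g] = min over valid b-vectors <= g (elementwise)
      boxmin.assign(grid, INF);
      boxarg.assign(grid, -1);
      for (int iv = 0; iv < nv; ++iv) {
        long g = code_of[iv];
        if (costB[iv] < boxmin[g]) { boxmin[g] = costB[iv]; boxarg[g] = iv; }
      }
      for (int dim = 0; dim < nt; ++dim) {
        long st = stride[dim];
        for (long g = 0; g < grid; ++g) {
          long digit = (g / st) % (cmax + 1);
          if (digit == 0) continue;
          long prev = g - st;
          if (boxmin[prev] < boxmin[g]) {
            boxmin[g] = boxmin[prev];
            boxarg[g] = boxarg[prev];
          }
        }
      }
      for (int ia = 0; ia < nv; ++ia) {
        long g = 0;
        for (int i = 0; i < nt; ++i) g += stride[i] * (cmax - V[ia][i]);
        if (boxarg[g] < 0) continue;
        double cst = costA[ia] + boxmin[g];
        if (cst < best - 1e-12) {
          best = cst; best_a = ia; best_b = boxarg[g];
        }
      }
    }
    if (best_a < 0) stop("No feasible copy-number state (invalid parameters).");
    for (int i = 0; i < nt; ++i) {
      A(s, i + 1) = V[best_a][i];
      B(s, i + 1) = V[best_b][i];
    }
    total += best;
  }
  return List::create(_["A"] = A, _["B"] = B, _["objective"] = total);
}
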