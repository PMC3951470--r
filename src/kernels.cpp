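#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Collins-Duffy convolution tree kernel.
//
// Trees arrive flattened from R: `prod` holds an interned production id per
// internal node (the id encodes node label + ordered child labels, with
// token leaves tagged separately, so equal ids imply identical productions
// and identical leaf/internal child patterns); `children` holds, per internal
// node, the 0-based indices of its *internal* children in order (token-leaf
// children contribute a unit factor and are omitted).
// ---------------------------------------------------------------------------

struct FlatTree {
  std::vector<int> prod;
  std::vector<std::vector<int> > kids;
};

static FlatTree as_flat(const List& t) {
  FlatTree f;
  IntegerVector prod = t["prod"];
  List kids = t["children"];
  f.prod.assign(prod.begin(), prod.end());
  f.kids.resize(kids.size());
  for (int i = 0; i < kids.size(); ++i) {
    IntegerVector k = kids[i];
    f.kids[i].assign(k.begin(), k.end());
  }
  return f;
}

static double delta(int i, int j, const FlatTree& a, const FlatTree& b,
                    double lambda, std::vector<double>& memo, int nb) {
  double& m = memo[(size_t)i * nb + j];
  if (m >= 0.0) return m;
  if (a.prod[i] != b.prod[j]) return m = 0.0;
  const std::vector<int>& ca = a.kids[i];
  const std::vector<int>& cb = b.kids[j];
  if (ca.empty()) return m = lambda;          // preterminal production
  double v = lambda;
  for (size_t k = 0; k < ca.size(); ++k) {
    v *= 1.0 + delta(ca[k], cb[k], a, b, lambda, memo, nb);
  }
  return m = v;
}

static double ctk_flat(const FlatTree& a, const FlatTree& b, double lambda) {
  int na = (int)a.prod.size(), nb = (int)b.prod.size();
  if (na == 0 || nb == 0) return 0.0;
  std::vector<double> memo((size_t)na * nb, -1.0);
  double s = 0.0;
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j)
      s += delta(i, j, a, b, lambda, memo, nb);
  return s;
}

// [[Rcpp::export(name = ".cpp_ctk_pair")]]
double cpp_ctk_pair(List t1, List t2, double lambda) {
  FlatTree a = as_flat(t1), b = as_flat(t2);
  return ctk_flat(a, b, lambda);
}

// [[Rcpp::export(name = ".cpp_ctk_gram")]]
NumericMatrix cpp_ctk_gram(List trees, double lambda, bool normalize) {
  int n = trees.size();
  std::vector<FlatTree> flat(n);
  for (int i = 0; i < n; ++i) flat[i] = as_flat(trees[i]);
  NumericVector self(n);
  for (int i = 0; i < n; ++i) self[i] = ctk_flat(flat[i], flat[i], lambda);
  NumericMatrix K(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double v = (i == j) ? self[i] : ctk_flat(flat[i], flat[j], lambda);
      if (normalize) {
        double d = self[i] * self[j];
        v = (d > 0.0) ? v / std::sqrt(d) : 0.0;
        if (i == j) v = (self[i] > 0.0) ? 1.0 : 0.0;
      }
      K(i, j) = v;
      K(j, i) = v;
    }
  }
  return K;
}

// ---------------------------------------------------------------------------
// Kuhn-Munkres (Hungarian) maximum-weight bipartite matching.
//
// Shortest-augmenting-path O(n^3) formulation on the cost matrix
// c = max(W) - W after padding to square with zeros; with nonnegative
// weights a maximum assignment of the padded square matrix restricted to
// real rows/columns is a maximum-weight matching.
// ---------------------------------------------------------------------------

static void hungarian_square(const std::vector<double>& cost, int n,
                             std::vector<int>& row_of_col) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double d = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost[(size_t)(i0 - 1) * n + (j - 1)] - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < d) { d = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += d; v[j] -= d; }
        else minv[j] -= d;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  row_of_col.assign(n + 1, 0);
  for (int j = 1; j <= n; ++j) row_of_col[j] = p[j];
}

// Returns list(rows, cols, total): 1-based index pairs of the matching
// restricted to strictly positive real cells, plus the total weight.
// [[Rcpp::export(name = ".cpp_munkres")]]
List cpp_munkres(NumericMatrix W) {
  int m = W.nrow(), ncol = W.ncol();
  if (m == 0 || ncol == 0) {
    return List::create(_["rows"] = IntegerVector(0),
                        _["cols"] = IntegerVector(0), _["total"] = 0.0);
  }
  int n = std::max(m, ncol);
  double wmax = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < ncol; ++j)
      if (W(i, j) > wmax) wmax = W(i, j);
  std::vector<double> cost((size_t)n * n, wmax); // pad cells cost = wmax - 0
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < ncol; ++j)
      cost[(size_t)i * n + j] = wmax - W(i, j);
  std::vector<int> row_of_col;
  hungarian_square(cost, n, row_of_col);
  std::vector<int> rr, cc;
  double total = 0.0;
  for (int j = 1; j <= n; ++j) {
    int i = row_of_col[j];
    if (i >= 1 && i <= m && j <= ncol && W(i - 1, j - 1) > 0.0) {
      rr.push_back(i); cc.push_back(j);
      total += W(i - 1, j - 1);
    }
  }
  return List::create(_["rows"] = wrap(rr), _["cols"] = wrap(cc),
                      _["total"] = total);
}

// Context-similarity Gram: contexts are integer vectors indexing a shared
// vocabulary similarity matrix S (sim of word i vs word j). Entry (a, b) is
// munkres_total(S[ctx_a, ctx_b]) / max(|ctx_a|, |ctx_b|); 0 if either empty.
// [[Rcpp::export(name = ".cpp_context_gram")]]
NumericMatrix cpp_context_gram(List contexts, NumericMatrix S) {
  int n = contexts.size();
  std::vector<std::vector<int> > ctx(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = contexts[i];
    ctx[i].assign(v.begin(), v.end());
  }
  NumericMatrix K(n, n);
  for (int a = 0; a < n; ++a) {
    for (int b = a; b < n; ++b) {
      int m = (int)ctx[a].size(), q = (int)ctx[b].size();
      double val = 0.0;
      if (m > 0 && q > 0) {
        NumericMatrix W(m, q);
        for (int i = 0; i < m; ++i)
          for (int j = 0; j < q; ++j)
            W(i, j) = S(ctx[a][i] - 1, ctx[b][j] - 1);
        List res = cpp_munkres(W);
        double total = res["total"];
        val = total / (double)std::max(m, q);
      }
      K(a, b) = val;
      K(b, a) = val;
    }
  }
  return K;
}

// ---------------------------------------------------------------------------
// Deterministic SMO solver for the C-SVC dual with a precomputed kernel.
// Platt's SMO with the |E_i - E_j| second-choice heuristic; all scans are in
// fixed index order, so training is deterministic for fixed inputs.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_smo_train")]]
List cpp_smo_train(NumericMatrix K, NumericVector y, double C, double tol,
                   int max_passes) {
  int n = K.nrow();
  std::vector<double> alpha(n, 0.0), E(n);
  double b = 0.0;
  for (int i = 0; i < n; ++i) E[i] = -y[i];   // f(x_i) = 0 initially
  int passes = 0, iter = 0, max_iter = 200000;
  while (passes < max_passes && iter < max_iter) {
    int changed = 0;
    for (int i = 0; i < n; ++i) {
      double ri = E[i] * y[i];
      if (!((ri < -tol && alpha[i] < C) || (ri > tol && alpha[i] > 0))) continue;
      // second index: maximize |E_i - E_j|, deterministic tie-break (lowest j)
      int j = -1; double best = -1.0;
      for (int k = 0; k < n; ++k) {
        if (k == i) continue;
        double d = std::fabs(E[i] - E[k]);
        if (d > best + 1e-15) { best = d; j = k; }
      }
      if (j < 0) continue;
      double ai_old = alpha[i], aj_old = alpha[j];
      double L, H;
      if (y[i] != y[j]) {
        L = std::max(0.0, aj_old - ai_old);
        H = std::min(C, C + aj_old - ai_old);
      } else {
        L = std::max(0.0, ai_old + aj_old - C);
        H = std::min(C, ai_old + aj_old);
      }
      if (H - L < 1e-12) continue;
      double eta = 2.0 * K(i, j) - K(i, i) - K(j, j);
      if (eta >= -1e-12) continue;
      double aj = aj_old - y[j] * (E[i] - E[j]) / eta;
      aj = std::min(H, std::max(L, aj));
      if (std::fabs(aj - aj_old) < 1e-7) continue;
      double ai = ai_old + y[i] * y[j] * (aj_old - aj);
      alpha[i] = ai; alpha[j] = aj;
      double b1 = b - E[i] - y[i] * (ai - ai_old) * K(i, i)
                  - y[j] * (aj - aj_old) * K(i, j);
      double b2 = b - E[j] - y[i] * (ai - ai_old) * K(i, j)
                  - y[j] * (aj - aj_old) * K(j, j);
      double b_new;
      if (ai > 0 && ai < C) b_new = b1;
      else if (aj > 0 && aj < C) b_new = b2;
      else b_new = 0.5 * (b1 + b2);
      double db = b_new - b;
      b = b_new;
      for (int k = 0; k < n; ++k) {
        E[k] += y[i] * (ai - ai_old) * K(i, k)
              + y[j] * (aj - aj_old) * K(j, k) + db;
      }
      ++changed;
      ++iter;
    }
    passes = (changed == 0) ? passes + 1 : 0;
  }
  return List::create(_["alpha"] = wrap(alpha), _["b"] = b,
                      _["iterations"] = iter);
}
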