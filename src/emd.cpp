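// Exact solution of the discrete transportation problem (earth mover
// distance) by the transportation simplex (MODI / u-v method). The initial
// basic feasible solution uses the least-cost rule, completed to a spanning
// tree with zero-flow basics via union-find; the pivot loop maintains the
// basis adjacency incrementally. Sized for desk-scale clouds (a few
// thousand points); callers down-sample above that.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <numeric>
#include <limits>
using namespace Rcpp;

namespace {
struct DSU {
  std::vector<int> p;
  explicit DSU(int n) : p(n) { std::iota(p.begin(), p.end(), 0); }
  int find(int x) { while (p[x] != x) x = p[x] = p[p[x]]; return x; }
  bool unite(int x, int y) {
    x = find(x); y = find(y);
    if (x == y) return false;
    p[x] = y; return true;
  }
};
}

// [[Rcpp::export(name = ".emd_simplex")]]
List emd_simplex(NumericMatrix C, NumericVector a, NumericVector b,
                 int max_iter = 0, double tol = 1e-12) {
  const int n = C.nrow(), m = C.ncol();
  if (a.size() != n || b.size() != m) stop("marginal lengths must match cost");
  if (max_iter <= 0) max_iter = 200 * (n + m) + 1000;

  std::vector<double> A(a.begin(), a.end()), B(b.begin(), b.end());
  double sa = 0, sb = 0;
  for (double x : A) { if (x < 0) stop("negative weight"); sa += x; }
  for (double x : B) { if (x < 0) stop("negative weight"); sb += x; }
  if (sa <= 0 || sb <= 0) stop("weights must have positive sum");
  // normalize both sides to total mass 1
  for (double &x : A) x /= sa;
  for (double &x : B) x /= sb;

  std::vector<double> X((size_t)n * m, 0.0);
  std::vector<char> basic((size_t)n * m, 0);
  auto id = [m](int i, int j) { return (size_t)i * m + j; };

  std::vector<std::vector<int>> row_basics(n), col_basics(m);
  auto add_basic = [&](int i, int j) {
    basic[id(i, j)] = 1;
    row_basics[i].push_back(j);
    col_basics[j].push_back(i);
  };
  auto drop_basic = [&](int i, int j) {
    basic[id(i, j)] = 0;
    auto &rb = row_basics[i];
    rb.erase(std::find(rb.begin(), rb.end(), j));
    auto &cb = col_basics[j];
    cb.erase(std::find(cb.begin(), cb.end(), i));
  };

  // cells in ascending cost order (used by the least-cost initial solution
  // and by the union-find completion of a degenerate basis)
  std::vector<int> order((size_t)n * m);
  std::iota(order.begin(), order.end(), 0);
  std::sort(order.begin(), order.end(), [&](int x, int y) {
    return C(x / m, x % m) < C(y / m, y % m);
  });

  // least-cost-rule initial feasible solution; every allocation closes a
  // row or a column, so the positive cells form a forest
  {
    std::vector<double> ra(A), rb(B);
    std::vector<char> row_open(n, 1), col_open(m, 1);
    int open_rows = n, open_cols = m;
    DSU dsu(n + m);
    int basics = 0;
    for (int cell : order) {
      if (open_rows == 0 || open_cols == 0) break;
      int i = cell / m, j = cell % m;
      if (!row_open[i] || !col_open[j]) continue;
      double f = std::min(ra[i], rb[j]);
      X[id(i, j)] = f;
      add_basic(i, j);
      dsu.unite(i, n + j);
      ++basics;
      ra[i] -= f; rb[j] -= f;
      bool row_done = ra[i] <= 1e-15, col_done = rb[j] <= 1e-15;
      if (row_done && col_done) {
        // close only one line unless it is the final allocation, keeping
        // the basic count at n+m-1 in the nondegenerate case
        if (open_rows > 1) { row_open[i] = 0; --open_rows; }
        else { col_open[j] = 0; --open_cols; }
      } else if (row_done) { row_open[i] = 0; --open_rows; }
      else { col_open[j] = 0; --open_cols; }
    }
    // connect a degenerate (forest) basis into one spanning tree with
    // zero-flow basics, preferring cheap cells
    if (basics < n + m - 1) {
      for (int cell : order) {
        int i = cell / m, j = cell % m;
        if (!basic[id(i, j)] && dsu.unite(i, n + j)) {
          add_basic(i, j);
          if (++basics == n + m - 1) break;
        }
      }
    }
  }

  std::vector<double> u(n), v(m);
  std::vector<char> uset(n), vset(m);
  bool converged = false;
  int iter = 0;

  for (; iter < max_iter; ++iter) {
    // duals from u_i + v_j = c_ij on basic cells (BFS over the tree)
    std::fill(uset.begin(), uset.end(), 0);
    std::fill(vset.begin(), vset.end(), 0);
    std::queue<int> q;                 // nodes: rows 0..n-1, cols n..n+m-1
    u[0] = 0; uset[0] = 1; q.push(0);
    int done = 0;
    while (done < n + m) {
      if (q.empty()) {  // disconnected basis (shouldn't happen); seed next
        bool seeded = false;
        for (int i = 0; i < n && !seeded; ++i)
          if (!uset[i]) { u[i] = 0; uset[i] = 1; q.push(i); seeded = true; }
        for (int j = 0; j < m && !seeded; ++j)
          if (!vset[j]) { v[j] = 0; vset[j] = 1; q.push(n + j); seeded = true; }
        if (!seeded) break;
      }
      int node = q.front(); q.pop();
      ++done;
      if (node < n) {
        for (int j : row_basics[node]) if (!vset[j]) {
          v[j] = C(node, j) - u[node]; vset[j] = 1; q.push(n + j);
        }
      } else {
        int j = node - n;
        for (int i : col_basics[j]) if (!uset[i]) {
          u[i] = C(i, j) - v[j]; uset[i] = 1; q.push(i);
        }
      }
    }

    // most negative reduced cost among nonbasic cells
    int bi = -1, bj = -1; double best = -tol;
    for (int i = 0; i < n; ++i) {
      const double ui = u[i];
      for (int j = 0; j < m; ++j) {
        double d = C(i, j) - ui - v[j];
        if (d < best && !basic[id(i, j)]) { best = d; bi = i; bj = j; }
      }
    }
    if (bi < 0) { converged = true; break; }

    // unique path from column bj back to row bi through the basis tree
    std::vector<int> par((size_t)n + m, -2);
    std::queue<int> q2;
    par[bi] = -1; q2.push(bi);
    while (!q2.empty() && par[(size_t)n + bj] == -2) {
      int node = q2.front(); q2.pop();
      if (node < n) {
        for (int j : row_basics[node]) if (par[(size_t)n + j] == -2) {
          par[(size_t)n + j] = node; q2.push(n + j);
        }
      } else {
        int j = node - n;
        for (int i : col_basics[j]) if (par[i] == -2) {
          par[i] = node; q2.push(i);
        }
      }
    }
    if (par[(size_t)n + bj] == -2) stop("internal error: basis tree disconnected");

    // cycle cells: entering (bi,bj) is '+', then alternate along the path
    std::vector<std::pair<int,int>> cyc;   // (i,j) cells, alternating sign
    cyc.push_back(std::make_pair(bi, bj)); // +
    int node = n + bj;
    while (node != bi) {
      int p = par[node];
      if (node >= n) cyc.push_back(std::make_pair(p, node - n));  // row p -> col
      else cyc.push_back(std::make_pair(node, p - n));            // col p -> row
      node = p;
    }
    // signs: cyc[0] +, cyc[1] -, cyc[2] +, ...
    double theta = std::numeric_limits<double>::infinity();
    size_t leave = 1;
    for (size_t k = 1; k < cyc.size(); k += 2) {
      double f = X[id(cyc[k].first, cyc[k].second)];
      if (f < theta) { theta = f; leave = k; }
    }
    for (size_t k = 0; k < cyc.size(); ++k) {
      size_t cell = id(cyc[k].first, cyc[k].second);
      if (k % 2 == 0) X[cell] += theta; else X[cell] -= theta;
    }
    drop_basic(cyc[leave].first, cyc[leave].second);
    X[id(cyc[leave].first, cyc[leave].second)] = 0.0;
    add_basic(bi, bj);
  }

  double cost = 0;
  NumericMatrix flow(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double f = X[id(i, j)];
      if (f > 0) { cost += f * C(i, j); flow(i, j) = f; }
    }
  return List::create(_["cost"] = cost, _["flow"] = flow,
                      _["converged"] = converged, _["iterations"] = iter);
}
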