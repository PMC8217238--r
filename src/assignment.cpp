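#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Jonker-Volgenant style shortest-augmenting-path solver for the dense
// rectangular assignment problem (n rows <= m cols), minimising total cost.
// Returns, per row, the 1-based column index assigned to it.
static std::vector<int> lap_dense(const NumericMatrix& a) {
  const int n = a.nrow(), m = a.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<char> used(m + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= m; ++j) {
        if (used[j]) continue;
        double cur = a(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  std::vector<int> ans(n, 0);
  for (int j = 1; j <= m; ++j)
    if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}

// [[Rcpp::export]]
IntegerVector solve_lap_cpp(NumericMatrix cost) {
  if (cost.nrow() > cost.ncol())
    stop("cost matrix must have nrow <= ncol");
  std::vector<int> r = lap_dense(cost);
  return IntegerVector(r.begin(), r.end());
}

static inline long long cell_key(long long cx, long long cy) {
  return cx * 2000003LL + cy;
}

// All pairs (i in A, j in B) with Euclidean distance <= r, found via a
// uniform grid of cell size r.  Indices are 1-based.
// [[Rcpp::export]]
List cross_pairs_cpp(NumericVector ax, NumericVector ay,
                     NumericVector bx, NumericVector by, double r) {
  const int na = ax.size(), nb = bx.size();
  std::vector<int> oi, oj;
  std::vector<double> od;
  if (na == 0 || nb == 0 || r <= 0) {
    return List::create(_["i"] = IntegerVector(oi.begin(), oi.end()),
                        _["j"] = IntegerVector(oj.begin(), oj.end()),
                        _["dist"] = NumericVector(od.begin(), od.end()));
  }
  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(nb * 2);
  for (int j = 0; j < nb; ++j) {
    long long cx = (long long)std::floor(bx[j] / r);
    long long cy = (long long)std::floor(by[j] / r);
    grid[cell_key(cx, cy)].push_back(j);
  }
  const double r2 = r * r;
  for (int i = 0; i < na; ++i) {
    long long cx = (long long)std::floor(ax[i] / r);
    long long cy = (long long)std::floor(ay[i] / r);
    for (long long dx = -1; dx <= 1; ++dx) {
      for (long long dy = -1; dy <= 1; ++dy) {
        std::unordered_map<long long, std::vector<int> >::iterator it =
          grid.find(cell_key(cx + dx, cy + dy));
        if (it == grid.end()) continue;
        const std::vector<int>& cell = it->second;
        for (size_t k = 0; k < cell.size(); ++k) {
          int j = cell[k];
          double ddx = ax[i] - bx[j], ddy = ay[i] - by[j];
          double d2 = ddx * ddx + ddy * ddy;
          if (d2 <= r2) {
            oi.push_back(i + 1);
            oj.push_back(j + 1);
            od.push_back(std::sqrt(d2));
          }
        }
      }
    }
  }
  return List::create(_["i"] = IntegerVector(oi.begin(), oi.end()),
                      _["j"] = IntegerVector(oj.begin(), oj.end()),
                      _["dist"] = NumericVector(od.begin(), od.end()));
}

struct UnionFind {
  std::vector<int> parent;
  UnionFind(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[b] = a;
  }
};

// Sparse one-to-one assignment of nl "left" to nr "right" items, given
// candidate pairs (pi, pj, 1-based) with costs.  Each left item may stay
// unassigned at cost slack[i] (its gate, so a link is made only when
// cheaper than leaving both ends free).  Solved exactly per connected
// component by the dense LAP above with per-row dummy columns.
// Returns per left item the 1-based right index, or 0.
// [[Rcpp::export]]
IntegerVector link_assign_cpp(int nl, int nr,
                              IntegerVector pi, IntegerVector pj,
                              NumericVector cost, NumericVector slack) {
  const int np = pi.size();
  IntegerVector match(nl, 0);
  if (np == 0) return match;
  const double BIG = 1e9;
  UnionFind uf(nl + nr);
  for (int k = 0; k < np; ++k) uf.unite(pi[k] - 1, nl + pj[k] - 1);
  // group pairs by component root
  std::unordered_map<int, std::vector<int> > comp_pairs;
  for (int k = 0; k < np; ++k) comp_pairs[uf.find(pi[k] - 1)].push_back(k);
  for (std::unordered_map<int, std::vector<int> >::iterator it =
         comp_pairs.begin(); it != comp_pairs.end(); ++it) {
    const std::vector<int>& pk = it->second;
    // local row/col index maps (insertion-ordered by pair list)
    std::unordered_map<int, int> rmap, cmap;
    std::vector<int> rows, cols;
    for (size_t k = 0; k < pk.size(); ++k) {
      int i = pi[pk[k]] - 1, j = pj[pk[k]] - 1;
      if (rmap.find(i) == rmap.end()) { rmap[i] = rows.size(); rows.push_back(i); }
      if (cmap.find(j) == cmap.end()) { cmap[j] = cols.size(); cols.push_back(j); }
    }
    const int R = rows.size(), C = cols.size();
    NumericMatrix a(R, C + R);
    std::fill(a.begin(), a.end(), BIG);
    for (int r0 = 0; r0 < R; ++r0)
      a(r0, C + r0) = slack[rows[r0]];
    for (size_t k = 0; k < pk.size(); ++k) {
      int r0 = rmap[pi[pk[k]] - 1], c0 = cmap[pj[pk[k]] - 1];
      if (cost[pk[k]] < a(r0, c0)) a(r0, c0) = cost[pk[k]];
    }
    std::vector<int> sol = lap_dense(a);
    for (int r0 = 0; r0 < R; ++r0)
      if (sol[r0] >= 1 && sol[r0] <= C)
        match[rows[r0]] = cols[sol[r0] - 1] + 1;
  }
  return match;
}
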