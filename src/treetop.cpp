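#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// metric codes: 1 = L1 (Manhattan), 2 = L2 (Euclidean), 3 = angle
static inline double point_dist(const double* x, const double* y,
                                int d, int stride_x, int stride_y, int metric) {
  if (metric == 1) {
    double s = 0.0;
    for (int c = 0; c < d; ++c) s += std::fabs(x[c * stride_x] - y[c * stride_y]);
    return s;
  }
  if (metric == 2) {
    double s = 0.0;
    for (int c = 0; c < d; ++c) {
      double t = x[c * stride_x] - y[c * stride_y];
      s += t * t;
    }
    return std::sqrt(s);
  }
  double num = 0.0, na = 0.0, nb = 0.0;
  for (int c = 0; c < d; ++c) {
    double a = x[c * stride_x], b = y[c * stride_y];
    num += a * b; na += a * a; nb += b * b;
  }
  if (na == 0.0 || nb == 0.0)
    stop("angle distance is undefined for zero vectors");
  double cs = num / std::sqrt(na * nb);
  if (cs > 1.0) cs = 1.0;
  if (cs < -1.0) cs = -1.0;
  return std::acos(cs);
}

// [[Rcpp::export]]
NumericMatrix cross_dist_cpp(NumericMatrix X, NumericMatrix Y, int metric) {
  const int n = X.nrow(), m = Y.nrow(), d = X.ncol();
  if (Y.ncol() != d) stop("dimension mismatch");
  NumericMatrix D(n, m);
  const double* xp = X.begin();
  const double* yp = Y.begin();
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i)
      D(i, j) = point_dist(xp + i, yp + j, d, n, m, metric);
  return D;
}

// neighbour counts within radius sigma (self included); L1/L2 loops
// abandon a pair as soon as the partial sum exceeds the radius
// [[Rcpp::export]]
IntegerVector density_count_cpp(NumericMatrix X, double sigma, int metric) {
  const int n = X.nrow(), d = X.ncol();
  IntegerVector cnt(n, 1);
  const double* xp = X.begin();
  const double sig2 = sigma * sigma;
  for (int i = 0; i < n; ++i) {
    const double* xi = xp + i;
    for (int j = i + 1; j < n; ++j) {
      const double* xj = xp + j;
      bool within;
      if (metric == 1) {
        double s = 0.0;
        within = true;
        for (int c = 0; c < d; ++c) {
          s += std::fabs(xi[(R_xlen_t)c * n] - xj[(R_xlen_t)c * n]);
          if (s > sigma) { within = false; break; }
        }
      } else if (metric == 2) {
        double s = 0.0;
        within = true;
        for (int c = 0; c < d; ++c) {
          double t = xi[(R_xlen_t)c * n] - xj[(R_xlen_t)c * n];
          s += t * t;
          if (s > sig2) { within = false; break; }
        }
      } else {
        within = point_dist(xi, xj, d, n, n, metric) <= sigma;
      }
      if (within) { ++cnt[i]; ++cnt[j]; }
    }
  }
  return cnt;
}

// index (1-based) of nearest row of N for every row of X; ties -> lowest index
// [[Rcpp::export]]
IntegerVector nearest_node_cpp(NumericMatrix X, NumericMatrix N, int metric) {
  const int n = X.nrow(), k = N.nrow(), d = X.ncol();
  if (N.ncol() != d) stop("dimension mismatch");
  IntegerVector out(n);
  const double* xp = X.begin();
  const double* np = N.begin();
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int arg = 0;
    for (int j = 0; j < k; ++j) {
      double dd = point_dist(xp + i, np + j, d, n, k, metric);
      if (dd < best) { best = dd; arg = j; }
    }
    out[i] = arg + 1;
  }
  return out;
}

// Prim's algorithm on a dense symmetric distance matrix, starting at vertex 0.
// Ties broken toward the lowest vertex index, so the result is deterministic.
// Returns a (k-1) x 2 matrix of 1-based endpoints with i < j per row.
// [[Rcpp::export]]
IntegerMatrix prim_mst_cpp(NumericMatrix D) {
  const int k = D.nrow();
  if (D.ncol() != k) stop("distance matrix must be square");
  for (int i = 0; i < k * k; ++i)
    if (!R_finite(D[i])) stop("distance matrix contains non-finite entries");
  std::vector<bool> used(k, false);
  std::vector<double> key(k, R_PosInf);
  std::vector<int> parent(k, -1);
  key[0] = 0.0;
  IntegerMatrix edges(k - 1, 2);
  int n_edges = 0;
  for (int it = 0; it < k; ++it) {
    int u = -1;
    double best = R_PosInf;
    for (int v = 0; v < k; ++v)
      if (!used[v] && key[v] < best) { best = key[v]; u = v; }
    if (u < 0) stop("internal error in Prim's algorithm");
    used[u] = true;
    if (parent[u] >= 0) {
      int a = parent[u], b = u;
      if (a > b) std::swap(a, b);
      edges(n_edges, 0) = a + 1;
      edges(n_edges, 1) = b + 1;
      ++n_edges;
    }
    for (int v = 0; v < k; ++v) {
      if (!used[v] && D(u, v) < key[v]) { key[v] = D(u, v); parent[v] = u; }
    }
  }
  return edges;
}

// For every candidate node x, the consistency matrix B_x: the proportion of
// trees in which nodes i and j fall in the same connected component after
// node x (and its incident edges) is removed.  Returns a k x k x k cube,
// slice [,,x]; row/column x of slice x is meaningless and set to 0.
// edge_i, edge_j: n_trees x (k-1) matrices of 1-based endpoints per tree.
// [[Rcpp::export]]
NumericVector consistency_cube_cpp(IntegerMatrix edge_i, IntegerMatrix edge_j, int k) {
  const int n_trees = edge_i.nrow(), m = edge_i.ncol();
  if (m != k - 1) stop("each tree must have k-1 edges");
  // adjacency lists per tree
  std::vector<std::vector<std::vector<int> > > adj(
      n_trees, std::vector<std::vector<int> >(k));
  for (int t = 0; t < n_trees; ++t) {
    for (int e = 0; e < m; ++e) {
      int a = edge_i(t, e) - 1, b = edge_j(t, e) - 1;
      if (a < 0 || a >= k || b < 0 || b >= k) stop("edge endpoint out of range");
      adj[t][a].push_back(b);
      adj[t][b].push_back(a);
    }
  }
  NumericVector cube((R_xlen_t)k * k * k);
  std::vector<int> comp(k);
  std::vector<int> stack;
  std::vector<int> members;
  stack.reserve(k);
  members.reserve(k);
  const R_xlen_t kk = (R_xlen_t)k * k;
  for (int x = 0; x < k; ++x) {
    double* B = cube.begin() + kk * x;
    for (int t = 0; t < n_trees; ++t) {
      std::fill(comp.begin(), comp.end(), -1);
      comp[x] = -2;  // removed
      for (int s = 0; s < k; ++s) {
        if (comp[s] != -1) continue;
        members.clear();
        stack.clear();
        stack.push_back(s);
        comp[s] = s;
        while (!stack.empty()) {
          int u = stack.back();
          stack.pop_back();
          members.push_back(u);
          const std::vector<int>& nb = adj[t][u];
          for (size_t q = 0; q < nb.size(); ++q) {
            int v = nb[q];
            if (comp[v] == -1) { comp[v] = s; stack.push_back(v); }
          }
        }
        const size_t nm = members.size();
        for (size_t p = 0; p < nm; ++p) {
          int a = members[p];
          B[(R_xlen_t)a * k + a] += 1.0;
          for (size_t q = p + 1; q < nm; ++q) {
            int b = members[q];
            B[(R_xlen_t)a * k + b] += 1.0;
            B[(R_xlen_t)b * k + a] += 1.0;
          }
        }
      }
    }
    for (R_xlen_t i = 0; i < kk; ++i) B[i] /= n_trees;
  }
  cube.attr("dim") = IntegerVector::create(k, k, k);
  return cube;
}
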