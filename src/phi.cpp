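// Kernels for the pairwise homoplasy index: refined incompatibility of
// informative site pairs (cyclomatic number of the partition-intersection
// graph) and the permutation statistic over near pairs.

#include <Rcpp.h>
#include <vector>
#include <functional>
using namespace Rcpp;

// states: sites x taxa integer matrix, 1..4 observed, 0 missing.
static int pair_score(const IntegerMatrix &st, int i, int j) {
  const int ntax = st.ncol();
  // map observed states to vertex ids: up to 4 per site
  int map_i[5] = {-1, -1, -1, -1, -1}, map_j[5] = {-1, -1, -1, -1, -1};
  int ki = 0, kj = 0;
  bool edge[4][4] = {{false}};
  for (int t = 0; t < ntax; ++t) {
    int a = st(i, t), b = st(j, t);
    if (a == 0 || b == 0) continue;
    if (map_i[a] < 0) map_i[a] = ki++;
    if (map_j[b] < 0) map_j[b] = kj++;
    edge[map_i[a]][map_j[b]] = true;
  }
  int E = 0;
  for (int a = 0; a < ki; ++a)
    for (int b = 0; b < kj; ++b)
      if (edge[a][b]) E++;
  int V = ki + kj;
  if (V == 0) return 0;
  // connected components via union-find over <= 8 vertices
  int parent[8];
  for (int v = 0; v < V; ++v) parent[v] = v;
  std::function<int(int)> find = [&](int v) {
    while (parent[v] != v) { parent[v] = parent[parent[v]]; v = parent[v]; }
    return v;
  };
  for (int a = 0; a < ki; ++a)
    for (int b = 0; b < kj; ++b)
      if (edge[a][b]) {
        int ra = find(a), rb = find(ki + b);
        if (ra != rb) parent[ra] = rb;
      }
  int C = 0;
  for (int v = 0; v < V; ++v) if (find(v) == v) C++;
  return E - V + C;
}

// [[Rcpp::export]]
IntegerMatrix incompat_matrix_cpp(IntegerMatrix states) {
  int s = states.nrow();
  IntegerMatrix out(s, s);
  for (int i = 0; i < s; ++i)
    for (int j = i + 1; j < s; ++j) {
      int sc = pair_score(states, i, j);
      out(i, j) = sc; out(j, i) = sc;
    }
  return out;
}

// [[Rcpp::export]]
int pair_score_cpp(IntegerMatrix states) {
  // convenience: states has exactly 2 rows
  return pair_score(states, 0, 1);
}

// Observed phi plus permutation replicates. positions: alignment positions of
// the informative sites (same order as score matrix rows). perms: one row per
// permutation, each a permutation of 1..s assigning state vectors to position
// slots. Near pairs are position slots within w of each other.
// [[Rcpp::export]]
List phi_stats_cpp(IntegerMatrix scores, IntegerVector positions, int w,
                   IntegerMatrix perms) {
  int s = positions.size();
  std::vector<int> pa, pb;
  for (int i = 0; i < s; ++i)
    for (int j = i + 1; j < s; ++j)
      if (std::abs(positions[i] - positions[j]) <= w) { pa.push_back(i); pb.push_back(j); }
  int np = (int)pa.size();
  double obs = NA_REAL;
  if (np > 0) {
    double sum = 0;
    for (int p = 0; p < np; ++p) sum += scores(pa[p], pb[p]);
    obs = sum / np;
  }
  int R = perms.nrow();
  NumericVector rep(R);
  for (int r = 0; r < R; ++r) {
    double sum = 0;
    for (int p = 0; p < np; ++p)
      sum += scores(perms(r, pa[p]) - 1, perms(r, pb[p]) - 1);
    rep[r] = (np > 0) ? sum / np : NA_REAL;
  }
  return List::create(_["phi"] = obs, _["n_pairs"] = np, _["perm"] = rep);
}
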