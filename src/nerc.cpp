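#include <Rcpp.h>
using namespace Rcpp;

// Single-linkage-style allocation of unassigned sites to seeded clusters.
// labels0 holds 1-based cluster ids for seed sites and NA elsewhere.
// Ties in the global minimum are broken by lowest (unassigned, assigned)
// index pair, which the scan order below yields with a strict comparison.
// [[Rcpp::export]]
IntegerVector cpp_nerc_allocate(NumericMatrix d, IntegerVector labels0) {
  int n = d.nrow();
  IntegerVector lab = clone(labels0);
  std::vector<bool> assigned(n);
  int n_assigned = 0;
  for (int i = 0; i < n; ++i) {
    assigned[i] = (lab[i] != NA_INTEGER);
    if (assigned[i]) ++n_assigned;
  }
  while (n_assigned < n) {
    double best = R_PosInf;
    int bu = -1, ba = -1;
    for (int u = 0; u < n; ++u) {
      if (assigned[u]) continue;
      for (int a = 0; a < n; ++a) {
        if (!assigned[a]) continue;
        if (d(u, a) < best) { best = d(u, a); bu = u; ba = a; }
      }
    }
    lab[bu] = lab[ba];
    assigned[bu] = true;
    ++n_assigned;
  }
  return lab;
}

// Iterative reallocation: while any site has a strictly smaller average
// distance (by more than tol) to a foreign cluster than to its own
// (self excluded), move one such site, chosen uniformly at random among
// those whose departure leaves >= 2 members behind. Distances to clusters
// are recomputed after every single move. Caps at max_moves successful
// moves. converged is TRUE only when no site at all (guarded or not)
// still prefers a foreign cluster.
// [[Rcpp::export]]
List cpp_nerc_reallocate(NumericMatrix d, IntegerVector labels0, int k,
                         int max_moves, double tol) {
  int n = d.nrow();
  IntegerVector lab = clone(labels0);
  int moves = 0;
  bool converged = false, stalled = false;

  // s(i, c): summed distance from site i to the members of cluster c,
  // maintained incrementally across moves (a move touches one column pair).
  std::vector<int> size(k, 0);
  std::vector<double> s((size_t)n * k, 0.0);
  for (int i = 0; i < n; ++i) ++size[lab[i] - 1];
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      s[(size_t)i * k + (lab[j] - 1)] += d(i, j);

  std::vector<int> eligible, target(n);
  for (;;) {
    eligible.clear();
    bool any_improvable = false;
    for (int i = 0; i < n; ++i) {
      int own = lab[i] - 1;
      const double *si = &s[(size_t)i * k];
      double own_avg = si[own] / (size[own] - 1);  // d(i,i) = 0 contributes nothing
      double best_avg = R_PosInf;
      int best_c = -1;
      for (int c = 0; c < k; ++c) {
        if (c == own) continue;
        if (si[c] / size[c] < best_avg) { best_avg = si[c] / size[c]; best_c = c; }
      }
      if (best_c >= 0 && own_avg - best_avg > tol) {
        any_improvable = true;
        if (size[own] > 2) {  // departure must leave >= 2 members
          target[i] = best_c;
          eligible.push_back(i);
        }
      }
    }

    if (!any_improvable) { converged = true; break; }
    if (eligible.empty()) { stalled = true; break; }
    if (moves >= max_moves) break;

    int idx = (int)(unif_rand() * eligible.size());
    if (idx >= (int)eligible.size()) idx = eligible.size() - 1;
    int pick = eligible[idx];
    int from = lab[pick] - 1, to = target[pick];
    lab[pick] = to + 1;
    --size[from]; ++size[to];
    for (int i = 0; i < n; ++i) {
      s[(size_t)i * k + from] -= d(i, pick);
      s[(size_t)i * k + to] += d(i, pick);
    }
    ++moves;
  }

  return List::create(_["labels"] = lab,
                      _["reassignments"] = moves,
                      _["converged"] = converged,
                      _["stalled"] = stalled);
}

// Pooled mean of d over all unordered within-cluster pairs.
// [[Rcpp::export]]
double cpp_mean_within(NumericMatrix d, IntegerVector lab) {
  int n = d.nrow();
  double s = 0.0;
  long pairs = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (lab[i] == lab[j]) { s += d(i, j); ++pairs; }
  if (pairs == 0) return NA_REAL;
  return s / pairs;
}
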