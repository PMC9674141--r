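#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Shifted-Hill regulation term: lambda + (1 - lambda) / (1 + (x/x0)^n).
// Equals 1 at x = 0 and tends to lambda as x -> inf, for both inhibition
// (lambda < 1) and activation (lambda > 1).
static inline double shifted_hill_c(double x, double x0, int n, double lam) {
  double r = std::pow(x / x0, n);
  return lam + (1.0 - lam) / (1.0 + r);
}

// One forward-Euler window; returns false if the trajectory went
// non-finite. Levels are clipped at 0.
static bool euler_window(std::vector<double>& x, int n_nodes,
                         const std::vector<std::vector<int>>& in_edges,
                         const int* esrc, const double* lam, const int* hn,
                         const double* y0, const double* P, const double* D,
                         double dt, int steps) {
  std::vector<double> xn(n_nodes);
  for (int s = 0; s < steps; ++s) {
    for (int i = 0; i < n_nodes; ++i) {
      double prod = P[i];
      for (int k : in_edges[i])
        prod *= shifted_hill_c(x[esrc[k]], y0[k], hn[k], lam[k]);
      double xi = x[i] + dt * (prod - D[i] * x[i]);
      if (!std::isfinite(xi)) return false;
      xn[i] = xi < 0.0 ? 0.0 : xi;
    }
    x = xn;
  }
  return true;
}

static std::vector<std::vector<int>> build_in_edges(int n_nodes,
                                                    const IntegerVector& tgt) {
  std::vector<std::vector<int>> in_edges(n_nodes);
  for (int k = 0; k < tgt.size(); ++k) in_edges[tgt[k]].push_back(k);
  return in_edges;
}

// Random-parameter ensemble integration. Parameters are per (set, node)
// for P and D and per (set, edge) for lambda, hill n and threshold y0.
// Initial conditions are drawn uniformly on [0, 1.5 * P/D] per node inside
// the run loop, consuming R's RNG stream (reproducible via set.seed).
// [[Rcpp::export]]
List cpp_ode_ensemble(int n_nodes, IntegerVector edge_src,
                      IntegerVector edge_tgt, NumericMatrix P,
                      NumericMatrix D, NumericMatrix lambda,
                      IntegerMatrix hill_n, NumericMatrix y0, int n_ics,
                      double dt, int steps_per_window, int n_windows,
                      double cutoff) {
  const int n_sets = P.nrow(), n_edges = edge_src.size();
  const int n_runs = n_sets * n_ics;
  auto in_edges = build_in_edges(n_nodes, edge_tgt);
  NumericMatrix levels(n_runs, n_nodes);
  LogicalVector converged(n_runs);
  IntegerVector set_id(n_runs), ic_id(n_runs);
  std::vector<double> lam(n_edges), th(n_edges), Pv(n_nodes), Dv(n_nodes);
  std::vector<int> hn(n_edges);
  std::vector<double> x(n_nodes), xprev(n_nodes);
  int row = 0;
  for (int s = 0; s < n_sets; ++s) {
    for (int i = 0; i < n_nodes; ++i) { Pv[i] = P(s, i); Dv[i] = D(s, i); }
    for (int k = 0; k < n_edges; ++k) {
      lam[k] = lambda(s, k); hn[k] = hill_n(s, k); th[k] = y0(s, k);
    }
    for (int ic = 0; ic < n_ics; ++ic, ++row) {
      for (int i = 0; i < n_nodes; ++i)
        x[i] = unif_rand() * 1.5 * Pv[i] / Dv[i];
      bool conv = false, ok = true;
      for (int w = 0; w < n_windows && ok && !conv; ++w) {
        xprev = x;
        ok = euler_window(x, n_nodes, in_edges, edge_src.begin(), lam.data(),
                          hn.data(), th.data(), Pv.data(), Dv.data(), dt,
                          steps_per_window);
        if (ok) {
          double md = 0.0;
          for (int i = 0; i < n_nodes; ++i)
            md = std::max(md, std::fabs(x[i] - xprev[i]));
          conv = md < cutoff;
        }
      }
      converged[row] = conv && ok;
      set_id[row] = s + 1; ic_id[row] = ic + 1;
      for (int i = 0; i < n_nodes; ++i) levels(row, i) = x[i];
    }
  }
  return List::create(_["levels"] = levels, _["converged"] = converged,
                      _["set"] = set_id, _["ic"] = ic_id);
}

// Single-trajectory integration from a given initial condition.
// [[Rcpp::export]]
List cpp_integrate_single(int n_nodes, IntegerVector edge_src,
                          IntegerVector edge_tgt, NumericVector P,
                          NumericVector D, NumericVector lambda,
                          IntegerVector hill_n, NumericVector y0,
                          NumericVector ic, double dt, int steps_per_window,
                          int n_windows, double cutoff) {
  auto in_edges = build_in_edges(n_nodes, edge_tgt);
  std::vector<int> hn(hill_n.begin(), hill_n.end());
  std::vector<double> lam(lambda.begin(), lambda.end()),
      th(y0.begin(), y0.end()), Pv(P.begin(), P.end()),
      Dv(D.begin(), D.end()), x(ic.begin(), ic.end()), xprev;
  bool conv = false, ok = true;
  for (int w = 0; w < n_windows && ok && !conv; ++w) {
    xprev = x;
    ok = euler_window(x, n_nodes, in_edges, edge_src.begin(), lam.data(),
                      hn.data(), th.data(), Pv.data(), Dv.data(), dt,
                      steps_per_window);
    if (ok) {
      double md = 0.0;
      for (int i = 0; i < n_nodes; ++i)
        md = std::max(md, std::fabs(x[i] - xprev[i]));
      conv = md < cutoff;
    }
  }
  return List::create(_["converged"] = conv && ok,
                      _["state"] = NumericVector(x.begin(), x.end()));
}

// Threshold update of node i: weighted sum of inputs, spins {-1,+1}
// (ising) or raw {0,1} (literal01); > 0 -> 1, < 0 -> 0, tie -> hold.
static inline int update_node(const std::vector<int>& s, int i,
                              const std::vector<std::vector<int>>& in_edges,
                              const int* esrc, const double* w, bool ising) {
  double sum = 0.0;
  for (int k : in_edges[i])
    sum += w[k] * (ising ? 2 * s[esrc[k]] - 1 : s[esrc[k]]);
  if (sum > 0) return 1;
  if (sum < 0) return 0;
  return s[i];
}

static bool is_fixed_point(const std::vector<int>& s, int n_nodes,
                           const std::vector<std::vector<int>>& in_edges,
                           const int* esrc, const double* w, bool ising) {
  for (int i = 0; i < n_nodes; ++i)
    if (update_node(s, i, in_edges, esrc, w, ising) != s[i]) return false;
  return true;
}

// Asynchronous threshold simulation for a batch of random initial
// conditions. One uniformly chosen node is updated per step; fixedness is
// tested every n_nodes steps (and at entry), so a run stops as soon as a
// fixed point is reached within that resolution.
// [[Rcpp::export]]
List cpp_boolean_ensemble(int n_nodes, IntegerVector edge_src,
                          IntegerVector edge_tgt, NumericVector weight,
                          int n_ics, int max_steps, bool ising) {
  auto in_edges = build_in_edges(n_nodes, edge_tgt);
  IntegerMatrix states(n_ics, n_nodes);
  LogicalVector converged(n_ics);
  std::vector<int> s(n_nodes);
  const double* w = weight.begin();
  const int* esrc = edge_src.begin();
  for (int run = 0; run < n_ics; ++run) {
    for (int i = 0; i < n_nodes; ++i) s[i] = unif_rand() < 0.5 ? 0 : 1;
    bool fixed = is_fixed_point(s, n_nodes, in_edges, esrc, w, ising);
    for (int step = 0; step < max_steps && !fixed; ++step) {
      int i = (int)(unif_rand() * n_nodes);
      if (i == n_nodes) i = n_nodes - 1;
      s[i] = update_node(s, i, in_edges, esrc, w, ising);
      if ((step + 1) % n_nodes == 0)
        fixed = is_fixed_point(s, n_nodes, in_edges, esrc, w, ising);
    }
    if (!fixed) fixed = is_fixed_point(s, n_nodes, in_edges, esrc, w, ising);
    converged[run] = fixed;
    for (int i = 0; i < n_nodes; ++i) states(run, i) = s[i];
  }
  return List::create(_["states"] = states, _["converged"] = converged);
}

// Count distinct converged states per parameter set: states whose maximum
// node-wise absolute difference from an already-seen representative is
// below tol are merged with it. Rows must be grouped by `set` (1-based).
// [[Rcpp::export]]
IntegerVector cpp_distinct_counts(NumericMatrix levels, IntegerVector set,
                                  LogicalVector converged, int n_sets,
                                  double tol) {
  IntegerVector counts(n_sets);
  const int n = levels.ncol();
  std::vector<std::vector<double>> reps;
  int cur = -1;
  for (int r = 0; r < levels.nrow(); ++r) {
    if (set[r] - 1 != cur) { cur = set[r] - 1; reps.clear(); }
    if (!converged[r]) continue;
    bool merged = false;
    for (auto& rep : reps) {
      double md = 0.0;
      for (int i = 0; i < n; ++i)
        md = std::max(md, std::fabs(levels(r, i) - rep[i]));
      if (md < tol) { merged = true; break; }
    }
    if (!merged) {
      std::vector<double> rep(n);
      for (int i = 0; i < n; ++i) rep[i] = levels(r, i);
      reps.push_back(rep);
      counts[cur] += 1;
    }
  }
  return counts;
}

// Single asynchronous trajectory from a given initial condition.
// [[Rcpp::export]]
List cpp_boolean_single(int n_nodes, IntegerVector edge_src,
                        IntegerVector edge_tgt, NumericVector weight,
                        IntegerVector ic, int max_steps, bool ising) {
  auto in_edges = build_in_edges(n_nodes, edge_tgt);
  std::vector<int> s(ic.begin(), ic.end());
  const double* w = weight.begin();
  const int* esrc = edge_src.begin();
  bool fixed = is_fixed_point(s, n_nodes, in_edges, esrc, w, ising);
  int step = 0;
  for (; step < max_steps && !fixed; ++step) {
    int i = (int)(unif_rand() * n_nodes);
    if (i == n_nodes) i = n_nodes - 1;
    s[i] = update_node(s, i, in_edges, esrc, w, ising);
    if ((step + 1) % n_nodes == 0)
      fixed = is_fixed_point(s, n_nodes, in_edges, esrc, w, ising);
  }
  if (!fixed) fixed = is_fixed_point(s, n_nodes, in_edges, esrc, w, ising);
  return List::create(_["converged"] = fixed,
                      _["state"] = IntegerVector(s.begin(), s.end()),
                      _["steps"] = step);
}
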