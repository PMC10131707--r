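#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <limits>
#include <climits>

using namespace Rcpp;

// Exact solver for the daily assignment subproblem of the rostering ILP.
//
// Because no constraint couples two dates (coverage is per location-day,
// the one-location rule is per staff-day), the full binary program
// decomposes into one small subproblem per day:
//
//   choose, for each available staff member k, a location l or OFF, s.t.
//     sum_{k -> l} w_k >= d_l            for every location l
//   minimizing either the number of assignments, the total miles, or
//   (diagnostic mode) the total unmet demand.
//
// Depth-first branch and bound over staff in index order. Branching is
// restricted to locations whose residual demand is positive: in any
// minimal solution every assignment is necessary (a staff member sent to
// an already-covered location could be dropped, contradicting minimality),
// so this restriction never cuts off the optimum of a minimization
// objective, and it makes the search deterministic with first-found
// tie-breaking.

namespace {

struct DaySolver {
  int n, L;
  std::vector<int> w;          // capacity per staff (available staff only)
  std::vector<double> cost;    // n x L, row-major: miles to each location
  std::vector<int> resid;      // residual demand per location
  int objective;               // 0 = assignments, 1 = miles, 2 = shortfall
  int count_eq;                // if >= 0: require exactly this many assignments
  std::vector<int> assign, best_assign;
  double best;
  bool found;
  std::vector<long long> suffix_cap;  // total capacity of staff k..n-1
  std::vector<int> suffix_wmax;       // max capacity among staff k..n-1
  long long nodes, node_limit;
  bool aborted;

  double shortfall_total() const {
    long long s = 0;
    for (int l = 0; l < L; ++l) if (resid[l] > 0) s += resid[l];
    return (double)s;
  }

  // minimum number of further assignments needed to cover `rt` units of
  // residual demand spread over `nloc` locations, using staff k..n-1
  int lb_assignments(int k, long long rt, int nloc) const {
    if (rt <= 0) return 0;
    int wmax = suffix_wmax[k];
    if (wmax <= 0) return INT_MAX / 4;
    long long by_cap = (rt + wmax - 1) / wmax;
    return (int)std::max(by_cap, (long long)nloc);
  }

  void dfs(int k, int used, double cur_cost, long long rt) {
    if (aborted) return;
    if (++nodes > node_limit) { aborted = true; return; }

    if (rt <= 0 && objective != 2) {
      if (count_eq >= 0 && used != count_eq) return;
      double val = (objective == 0) ? (double)used : cur_cost;
      if (!found || val < best) { best = val; best_assign = assign; found = true; }
      return;
    }
    if (k == n) {
      if (objective == 2) {
        double val = shortfall_total();
        if (!found || val < best) { best = val; best_assign = assign; found = true; }
      }
      return;  // objectives 0/1: uncovered demand at the last staff => dead end
    }

    int nloc = 0;
    for (int l = 0; l < L; ++l) if (resid[l] > 0) ++nloc;

    if (objective != 2) {
      if (rt > suffix_cap[k]) return;  // relaxation: pooled capacity short
      int lb = lb_assignments(k, rt, nloc);
      if (count_eq >= 0 && (used > count_eq || used + lb > count_eq)) return;
      if (objective == 0 && found && used + lb >= best) return;
      if (objective == 1 && found) {
        // each uncovered location needs at least one further assignment
        // at no less than the cheapest remaining fare to it
        double lbc = 0.0;
        for (int l = 0; l < L; ++l) {
          if (resid[l] <= 0) continue;
          double m = std::numeric_limits<double>::infinity();
          for (int j = k; j < n; ++j) m = std::min(m, cost[(size_t)j * L + l]);
          lbc += m;
        }
        if (cur_cost + lbc >= best) return;
      }
    } else {
      double lbs = (double)std::max(0LL, rt - suffix_cap[k]);
      if (found && lbs >= best) return;
      if (found && best <= 0.0) return;
    }

    // candidate locations, cheapest first (stable, index tie-break)
    std::vector<int> cand;
    cand.reserve(L);
    for (int l = 0; l < L; ++l) if (resid[l] > 0) cand.push_back(l);
    std::stable_sort(cand.begin(), cand.end(), [&](int a, int b) {
      return cost[(size_t)k * L + a] < cost[(size_t)k * L + b];
    });

    for (int l : cand) {
      int old = resid[l];
      long long covered = std::min((long long)w[k], (long long)old);
      resid[l] = old - w[k];
      assign[k] = l;
      dfs(k + 1, used + 1, cur_cost + cost[(size_t)k * L + l], rt - covered);
      resid[l] = old;
      assign[k] = -1;
      if (aborted) return;
    }
    dfs(k + 1, used, cur_cost, rt);  // OFF
  }
};

}  // namespace

// [[Rcpp::export(name = ".solve_day_cpp")]]
List solve_day_cpp(IntegerVector capacity, NumericMatrix cost,
                   IntegerVector demand, int objective,
                   int count_eq = -1,
                   double node_limit = 5e7) {
  DaySolver s;
  s.n = capacity.size();
  s.L = demand.size();
  if (cost.nrow() != s.n || cost.ncol() != s.L)
    stop("cost matrix must be staff x locations");
  s.w.assign(capacity.begin(), capacity.end());
  s.cost.resize((size_t)s.n * s.L);
  for (int k = 0; k < s.n; ++k)
    for (int l = 0; l < s.L; ++l) {
      double c = cost(k, l);
      if (c < 0) stop("negative distance");
      s.cost[(size_t)k * s.L + l] = c;
    }
  s.resid.assign(demand.begin(), demand.end());
  s.objective = objective;
  s.count_eq = count_eq;
  s.assign.assign(s.n, -1);
  s.best_assign.assign(s.n, -1);
  s.best = std::numeric_limits<double>::infinity();
  s.found = false;
  s.nodes = 0;
  s.node_limit = (long long)node_limit;
  s.aborted = false;

  s.suffix_cap.assign(s.n + 1, 0);
  s.suffix_wmax.assign(s.n + 1, 0);
  for (int k = s.n - 1; k >= 0; --k) {
    s.suffix_cap[k] = s.suffix_cap[k + 1] + std::max(0, s.w[k]);
    s.suffix_wmax[k] = std::max(s.suffix_wmax[k + 1], s.w[k]);
  }

  long long rt = 0;
  for (int l = 0; l < s.L; ++l) rt += std::max(0, s.resid[l]);
  s.dfs(0, 0, 0.0, rt);

  IntegerVector out(s.n);
  for (int k = 0; k < s.n; ++k) out[k] = s.best_assign[k] + 1;  // 0 = OFF
  return List::create(_["feasible"] = s.found,
                      _["value"] = s.found ? s.best : NA_REAL,
                      _["assign"] = out,
                      _["nodes"] = (double)s.nodes,
                      _["aborted"] = s.aborted);
}
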