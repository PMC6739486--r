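#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Event-driven (Gillespie) core for neutral drift on a ring of n stem-cell
// sites, optionally punctuated by barrier edges with birth-death dynamics.
// All randomness comes from R's RNG stream: callers control reproducibility
// with set.seed() before invoking.

static inline int edge_dist(int a, int b, int n) {
  int d = std::abs(a - b);
  d %= n;
  return std::min(d, n - d);
}

// Maximal-spacing placement: among free edges, maximize the minimum circular
// distance to occupied edges; ties broken uniformly. Uniform over free edges
// when no barrier exists. Returns -1 when every edge is occupied.
static int place_barrier_impl(const std::vector<char>& bar, int n) {
  std::vector<int> free_edges;
  std::vector<int> occ;
  for (int e = 0; e < n; ++e) {
    if (bar[e]) occ.push_back(e); else free_edges.push_back(e);
  }
  if (free_edges.empty()) return -1;
  if (occ.empty()) {
    int k = (int)(unif_rand() * free_edges.size());
    if (k >= (int)free_edges.size()) k = (int)free_edges.size() - 1;
    return free_edges[k];
  }
  int best = -1;
  std::vector<int> ties;
  for (size_t i = 0; i < free_edges.size(); ++i) {
    int e = free_edges[i];
    int dmin = n;
    for (size_t j = 0; j < occ.size(); ++j)
      dmin = std::min(dmin, edge_dist(e, occ[j], n));
    if (dmin > best) { best = dmin; ties.clear(); ties.push_back(e); }
    else if (dmin == best) ties.push_back(e);
  }
  int k = (int)(unif_rand() * ties.size());
  if (k >= (int)ties.size()) k = (int)ties.size() - 1;
  return ties[k];
}

// [[Rcpp::export]]
int place_barrier_core(LogicalVector barrier_occupied) {
  int n = barrier_occupied.size();
  std::vector<char> bar(n);
  for (int e = 0; e < n; ++e) bar[e] = barrier_occupied[e] ? 1 : 0;
  int e = place_barrier_impl(bar, n);
  return e; // -1 signals "all occupied"
}

// Contiguity of the labeled set on the ring: at most two label/unlabeled
// boundaries (0 boundaries when empty or full).
static bool arc_cohesive(const std::vector<char>& lab, int n) {
  int trans = 0;
  for (int i = 0; i < n; ++i)
    if ((lab[i] > 0) != (lab[(i + 1) % n] > 0)) ++trans;
  return trans <= 2;
}

// [[Rcpp::export]]
List pnd_core(int n_sites, double lambda, double beta, double mu,
              NumericVector record_times, int n_rep,
              int init_mode,            // 0 = none, 1 = stationary, 2 = fixed
              IntegerVector fixed_barriers,
              int labeled_site,         // site index, -1 = uniform, -2 = none
              double recovery_beta, double recovery_end,
              double lambda_scale, double lw_start, double lw_end,
              bool record_edges) {
  const int n = n_sites;
  const int nt = record_times.size();
  NumericMatrix labeled_frac(n_rep, nt);
  IntegerMatrix barrier_count(n_rep, nt);
  LogicalMatrix cohesive(n_rep, nt);
  List edge_snaps(record_edges ? nt : 0);
  std::vector<LogicalMatrix> snaps;
  if (record_edges) {
    for (int j = 0; j < nt; ++j) snaps.push_back(LogicalMatrix(n_rep, n));
  }

  std::vector<char> lab(n), bar(n);
  // rate-change points for the piecewise-constant rates
  double changes[3] = {recovery_end, lw_start, lw_end};

  for (int r = 0; r < n_rep; ++r) {
    std::fill(lab.begin(), lab.end(), 0);
    std::fill(bar.begin(), bar.end(), 0);
    int nbar = 0;
    if (init_mode == 1) {
      int k;
      do { k = (int)R::rpois(mu > 0 ? beta / mu : 0.0); } while (k > n);
      for (int i = 0; i < k; ++i) {
        int e = place_barrier_impl(bar, n);
        if (e >= 0) { bar[e] = 1; ++nbar; }
      }
    } else if (init_mode == 2) {
      for (int i = 0; i < fixed_barriers.size(); ++i) {
        int e = fixed_barriers[i];
        if (!bar[e]) { bar[e] = 1; ++nbar; }
      }
    }
    int nlab = 0;
    if (labeled_site == -1) {
      int s = (int)(unif_rand() * n);
      if (s >= n) s = n - 1;
      lab[s] = 1; nlab = 1;
    } else if (labeled_site >= 0) {
      lab[labeled_site] = 1; nlab = 1;
    }

    double t = 0.0;
    // residual exponential "work" carried across record times and
    // piecewise-rate boundaries, so RNG consumption does not depend on
    // where the process is observed (exactness by memorylessness)
    double work = -1.0;
    for (int j = 0; j < nt; ++j) {
      const double target = record_times[j];
      while (t < target) {
        const double beta_eff = (t < recovery_end) ? recovery_beta : beta;
        const double lam_eff =
          (t >= lw_start && t < lw_end) ? lambda * lambda_scale : lambda;
        // fully labeled / extinct rings are absorbing for the label process
        const bool absorbed = (nlab == 0 || nlab == n);
        double drift_rate = 0.0;
        if (!absorbed && lam_eff > 0) {
          int nelig = 0;
          for (int i = 0; i < n; ++i)
            if (!bar[(i + n - 1) % n] || !bar[i]) ++nelig;
          drift_rate = lam_eff * nelig;
        }
        const double total = drift_rate + mu * nbar + beta_eff;
        // next change of any piecewise-constant rate after t
        double horizon = target;
        for (int c = 0; c < 3; ++c)
          if (changes[c] > t && changes[c] < horizon) horizon = changes[c];
        if (total <= 0) { t = horizon; continue; }
        if (work < 0) work = exp_rand();
        const double dt = work / total;
        if (t + dt > horizon) { work -= (horizon - t) * total; t = horizon; continue; }
        t += dt;
        work = -1.0;
        double u = unif_rand() * total;
        if (u < drift_rate) {
          // drift: uniformly chosen eligible cell dies; a same-segment
          // nearest neighbor (uniform among the accessible ones) replaces it
          int pick = (int)(u / lam_eff); // index among eligible cells
          int i = -1, seen = 0;
          for (int s = 0; s < n; ++s) {
            if (!bar[(s + n - 1) % n] || !bar[s]) {
              if (seen == pick) { i = s; break; }
              ++seen;
            }
          }
          if (i < 0) i = n - 1; // numeric guard
          const bool left_ok = !bar[(i + n - 1) % n];
          const bool right_ok = !bar[i];
          int nb;
          if (left_ok && right_ok)
            nb = (unif_rand() < 0.5) ? (i + n - 1) % n : (i + 1) % n;
          else if (left_ok) nb = (i + n - 1) % n;
          else nb = (i + 1) % n;
          if (lab[i] != lab[nb]) {
            nlab += (lab[nb] > 0) - (lab[i] > 0);
            lab[i] = lab[nb];
          }
        } else if (u < drift_rate + mu * nbar) {
          // barrier death: uniform over standing barriers
          int pick = (int)((u - drift_rate) / mu);
          int seen = 0;
          for (int e = 0; e < n; ++e) {
            if (bar[e]) {
              if (seen == pick) { bar[e] = 0; --nbar; break; }
              ++seen;
            }
          }
        } else {
          // barrier birth with maximal-spacing placement; discarded when
          // every edge is already occupied
          int e = place_barrier_impl(bar, n);
          if (e >= 0) { bar[e] = 1; ++nbar; }
        }
      }
      labeled_frac(r, j) = (double)nlab / n;
      barrier_count(r, j) = nbar;
      cohesive(r, j) = arc_cohesive(lab, n);
      if (record_edges)
        for (int e = 0; e < n; ++e) snaps[j](r, e) = bar[e] != 0;
    }
  }
  if (record_edges)
    for (int j = 0; j < nt; ++j) edge_snaps[j] = snaps[j];
  return List::create(_["labeled_fraction"] = labeled_frac,
                      _["barrier_count"] = barrier_count,
                      _["cohesive"] = cohesive,
                      _["barrier_edges"] = edge_snaps);
}
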