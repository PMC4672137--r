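// Variant ant-colony edge-confidence engine (selective pheromone updating).
// Ants random-walk the 8-connected pixel lattice of one slice, guided by
// tau^alpha * eta^beta; pheromone is frozen during local iterations and only
// changed at global updates: the best tour of the round is reinforced, all
// other pixels evaporate, and every value is clamped to [tau_min, tau_max].
// Uses R's RNG so results are reproducible under set.seed().
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {
const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

int sample_cum(const std::vector<double>& w, double total) {
  double u = unif_rand() * total, acc = 0.0;
  for (size_t k = 0; k < w.size(); ++k) {
    acc += w[k];
    if (u <= acc) return (int)k;
  }
  return (int)w.size() - 1;
}
}  // namespace

// [[Rcpp::export(name = ".aco_cpp")]]
List aco_cpp(NumericMatrix eta, double alpha, double beta, double tau0,
             double phi, double rho, double tau_min, double tau_max,
             int n_ants, int n_steps, int n_local, int n_global,
             bool trace) {
  const int nr = eta.nrow(), nc = eta.ncol(), n = nr * nc;
  if (n_ants <= 0 || n_steps <= 0) stop("n_ants and n_steps must be positive");
  if (n_local <= 0 || n_global <= 0) stop("n_local and n_global must be positive");
  RNGScope scope;
  NumericMatrix tau(nr, nc);
  double t0 = std::min(std::max(tau0, tau_min), tau_max);
  std::fill(tau.begin(), tau.end(), t0);

  List snapshots;
  CharacterVector stages;
  const int TABU = 8;

  for (int g = 0; g < n_global; ++g) {
    // per-ant best tour of the round; their union is reinforced at the
    // global update (a single short tour cannot trace a closed boundary)
    std::vector<double> best_mean(n_ants, -1.0);
    std::vector<std::vector<int> > best_tour(n_ants);
    for (int li = 0; li < n_local; ++li) {
      for (int ant = 0; ant < n_ants; ++ant) {
        int r = (int)(unif_rand() * nr); if (r >= nr) r = nr - 1;
        int c = (int)(unif_rand() * nc); if (c >= nc) c = nc - 1;
        std::vector<int> tour;
        tour.reserve(n_steps + 1);
        int tabu[TABU];
        int tabu_len = 0, tabu_pos = 0;
        double eta_sum = eta(r, c);
        tour.push_back(r + nr * c);
        tabu[tabu_pos] = r + nr * c;
        tabu_pos = (tabu_pos + 1) % TABU;
        tabu_len = 1;
        for (int st = 0; st < n_steps; ++st) {
          int cand_r[8], cand_c[8], m = 0;
          int free_r[8], free_c[8], fm = 0;
          for (int k = 0; k < 8; ++k) {
            int rr = r + DR[k], cc = c + DC[k];
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            free_r[fm] = rr; free_c[fm] = cc; ++fm;
            int id = rr + nr * cc;
            bool in_tabu = false;
            for (int t = 0; t < tabu_len; ++t)
              if (tabu[t] == id) { in_tabu = true; break; }
            if (in_tabu) continue;
            cand_r[m] = rr; cand_c[m] = cc; ++m;
          }
          int pick_r, pick_c;
          if (m > 0) {
            std::vector<double> w(m);
            double total = 0.0;
            for (int k = 0; k < m; ++k) {
              double e = eta(cand_r[k], cand_c[k]);
              w[k] = std::pow(tau(cand_r[k], cand_c[k]), alpha) *
                     (e > 0 ? std::pow(e, beta) : 0.0);
              total += w[k];
            }
            int k;
            if (total > 0) k = sample_cum(w, total);
            else { k = (int)(unif_rand() * m); if (k >= m) k = m - 1; }
            pick_r = cand_r[k]; pick_c = cand_c[k];
          } else {
            int k = (int)(unif_rand() * fm); if (k >= fm) k = fm - 1;
            pick_r = free_r[k]; pick_c = free_c[k];
          }
          r = pick_r; c = pick_c;
          int id = r + nr * c;
          tour.push_back(id);
          eta_sum += eta(r, c);
          tabu[tabu_pos] = id;
          tabu_pos = (tabu_pos + 1) % TABU;
          if (tabu_len < TABU) ++tabu_len;
        }
        double mean_eta = eta_sum / (double)(n_steps + 1);
        if (mean_eta > best_mean[ant]) {  // strict: ties keep the first found
          best_mean[ant] = mean_eta;
          best_tour[ant] = tour;
        }
      }
      if (trace) {
        snapshots.push_back(clone(tau));
        stages.push_back("local");
      }
    }
    // global update: reinforce the union of the ants' best tours (tours
    // with zero heuristic signal deposit nothing), evaporate everywhere
    // else, clamp to bounds
    std::vector<char> on_tour(n, 0);
    for (int ant = 0; ant < n_ants; ++ant)
      if (best_mean[ant] > 0.0)
        for (size_t k = 0; k < best_tour[ant].size(); ++k)
          on_tour[best_tour[ant][k]] = 1;
    for (int c2 = 0; c2 < nc; ++c2)
      for (int r2 = 0; r2 < nr; ++r2) {
        int id = r2 + nr * c2;
        double v = on_tour[id] ? (1.0 - rho) * tau(r2, c2) + rho * 1.0
                               : (1.0 - phi) * tau(r2, c2);
        if (v < tau_min) v = tau_min;
        if (v > tau_max) v = tau_max;
        tau(r2, c2) = v;
      }
    if (trace) {
      snapshots.push_back(clone(tau));
      stages.push_back("global");
    }
  }
  return List::create(_["tau"] = tau, _["snapshots"] = snapshots,
                      _["stages"] = stages);
}
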