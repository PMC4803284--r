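#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Model codes (shared with R/.model_code): 1P=0, 2P=1, 1M=2, 2M=3, BU=4, BS=5.
//
// Grids are passed as a flat 144-vector in R column-major order:
// cell (i, j) lives at i + 12*j (0-based). 1P/1M use the first 12 slots.
// Excluded cells are never read; the callers zero-fill them.

static const double LIK_FLOOR = 1e-12;

static inline int pcmod(int x) { return ((x % 12) + 12) % 12; }

// Expectancy of the final chord of one sequence (length 2..4, no immediate
// repetitions for models other than 1P).
static double seq_expectancy(const int *s, int len, int model,
                             const double *tv, double kappa, double theta) {
  const int tau = len - 1;          // 0-based index of the final chord
  const int cf = s[tau];
  switch (model) {
  case 0:                            // 1P: final pitch only
    return tv[cf];
  case 1:                            // 2P: raw pitch pair
    return tv[s[tau - 1] + 12 * cf];
  case 2:                            // 1M: final interval only
    return tv[pcmod(cf - s[tau - 1])];
  case 3: {                          // 2M: (interval two back, final interval)
    const int j = pcmod(cf - s[tau - 1]);
    if (len == 2) {                  // flat prior on the missing two-back chord
      double acc = 0.0;
      for (int i = 0; i < 12; ++i)
        if (i != j) acc += tv[i + 12 * j];
      return acc / 11.0;
    }
    const int i = pcmod(cf - s[len - 3]);
    return tv[i + 12 * j];
  }
  default: {                         // BU (4) / BS (5)
    double bel[12];
    const double off = (1.0 - kappa) / 11.0;
    for (int x = 0; x < 12; ++x) bel[x] = (x == s[0]) ? kappa : off;
    // belief updates for time steps 2 .. tau (1-based), i.e. chord pairs
    // (s[t-1], s[t]) for 0-based t = 1 .. tau-1
    for (int t = 1; t <= tau - 1; ++t) {
      const int cp = s[t - 1], cc = s[t];
      double post[12];
      double z = 0.0;
      for (int x = 0; x < 12; ++x) {
        double lik = tv[pcmod(cp - x) + 12 * pcmod(cc - x)];
        if (lik < LIK_FLOOR) lik = LIK_FLOOR;
        post[x] = lik * bel[x];
        z += post[x];
      }
      for (int x = 0; x < 12; ++x) post[x] /= z;
      if (model == 5 && t >= 2) {    // reset check from the third chord on
        double mx = 0.0;
        for (int x = 0; x < 12; ++x)
          if (post[x] > mx) mx = post[x];
        if (mx < theta) {            // re-anchor the prior on the previous chord
          z = 0.0;
          for (int x = 0; x < 12; ++x) {
            double lik = tv[pcmod(cp - x) + 12 * pcmod(cc - x)];
            if (lik < LIK_FLOOR) lik = LIK_FLOOR;
            const double prior = (x == cp) ? kappa : off;
            post[x] = lik * prior;
            z += post[x];
          }
          for (int x = 0; x < 12; ++x) post[x] /= z;
        }
      }
      for (int x = 0; x < 12; ++x) bel[x] = post[x];
    }
    const int cp = s[tau - 1];
    double e = 0.0;
    for (int x = 0; x < 12; ++x)
      e += tv[pcmod(cp - x) + 12 * pcmod(cf - x)] * bel[x];
    return e;
  }
  }
}

// [[Rcpp::export]]
NumericVector cpp_expectancies(IntegerMatrix seqs, IntegerVector lens,
                               int model, NumericVector tvec,
                               double kappa, double theta) {
  const int n = seqs.nrow();
  NumericVector out(n);
  std::vector<int> s(4);
  for (int r = 0; r < n; ++r) {
    for (int k = 0; k < lens[r]; ++k) s[k] = seqs(r, k);
    out[r] = seq_expectancy(s.data(), lens[r], model, tvec.begin(),
                            kappa, theta);
  }
  return out;
}

// Rating-weighted binary cross-entropy of a dataset under fixed parameters.
// aprime = rating / 10; E is clamped away from {0, 1} so that grid values of
// exactly 0 or 1 stay admissible.
static double dataset_cost(const IntegerMatrix &seqs, const IntegerVector &lens,
                           const NumericVector &aprime, int model,
                           const double *tv, double kappa, double theta) {
  const int n = seqs.nrow();
  int s[4];
  double h = 0.0;
  for (int r = 0; r < n; ++r) {
    for (int k = 0; k < lens[r]; ++k) s[k] = seqs(r, k);
    double e = seq_expectancy(s, lens[r], model, tv, kappa, theta);
    if (e < LIK_FLOOR) e = LIK_FLOOR;
    if (e > 1.0 - LIK_FLOOR) e = 1.0 - LIK_FLOOR;
    h += -(aprime[r] * std::log(e) + (1.0 - aprime[r]) * std::log(1.0 - e));
  }
  return h;
}

// [[Rcpp::export]]
double cpp_cost(IntegerMatrix seqs, IntegerVector lens, NumericVector aprime,
                int model, NumericVector tvec, double kappa, double theta) {
  return dataset_cost(seqs, lens, aprime, model, tvec.begin(), kappa, theta);
}

// ---- discrete coordinate descent -----------------------------------------
//
// Free parameters are described by two parallel integer vectors:
//   kind: 0 = grid entry (step 0.1, levels 0..10, value level/10)
//         1 = kappa      (step 1/12, levels 1..12, value level/12)
//         2 = theta      (step 0.05, levels 0..20, value level*0.05)
//   tidx: index into the flat 144-grid for kind 0, ignored otherwise.
//
// Each restart draws every level uniformly, then sweeps the parameters in a
// freshly shuffled order, moving a parameter to its best strict-improvement
// grid neighbour (one step up or down); it stops when a complete sweep makes
// no move. Randomness comes from R's RNG, so set.seed() governs the run.

static inline double level_value(int kind, int lvl) {
  switch (kind) {
  case 0: return lvl / 10.0;
  case 1: return lvl / 12.0;
  default: return lvl * 0.05;
  }
}

static inline int level_count(int kind) {
  switch (kind) {
  case 0: return 11;
  case 1: return 12;
  default: return 21;
  }
}

static inline int draw_level(int kind) {
  const int n = level_count(kind);
  int lvl = (int)std::floor(unif_rand() * n);
  if (lvl >= n) lvl = n - 1;
  return (kind == 1) ? lvl + 1 : lvl;   // kappa levels are 1..12
}

// [[Rcpp::export]]
List cpp_fit(IntegerMatrix seqs, IntegerVector lens, NumericVector aprime,
             int model, IntegerVector kind, IntegerVector tidx,
             int restarts, bool shuffle_each_sweep) {
  const int nfree = kind.size();
  std::vector<double> tv(144, 0.0);
  double kappa = 1.0, theta = 0.0;

  NumericVector restart_costs(restarts);
  List traces(restarts);
  std::vector<int> best_levels(nfree);
  double best_cost = R_PosInf;
  int best_restart = -1;

  std::vector<int> levels(nfree), order(nfree);

  for (int rs = 0; rs < restarts; ++rs) {
    // random initial point on the lattice
    for (int p = 0; p < nfree; ++p) levels[p] = draw_level(kind[p]);
    for (int p = 0; p < nfree; ++p) {
      const double v = level_value(kind[p], levels[p]);
      if (kind[p] == 0) tv[tidx[p]] = v;
      else if (kind[p] == 1) kappa = v;
      else theta = v;
    }
    double cost = dataset_cost(seqs, lens, aprime, model, tv.data(),
                               kappa, theta);
    for (int p = 0; p < nfree; ++p) order[p] = p;
    std::vector<double> trace;
    trace.push_back(cost);

    bool moved = true;
    while (moved) {
      moved = false;
      if (shuffle_each_sweep || trace.size() == 1) {
        for (int p = nfree - 1; p > 0; --p) {   // Fisher-Yates via R's RNG
          int q = (int)std::floor(unif_rand() * (p + 1));
          if (q > p) q = p;
          std::swap(order[p], order[q]);
        }
      }
      for (int oi = 0; oi < nfree; ++oi) {
        const int p = order[oi];
        const int k = kind[p];
        const int lo = (k == 1) ? 1 : 0;
        const int hi = (k == 1) ? 12 : level_count(k) - 1;
        int best_lvl = levels[p];
        double local_best = cost;
        for (int d = -1; d <= 1; d += 2) {
          const int cand = levels[p] + d;
          if (cand < lo || cand > hi) continue;
          const double v = level_value(k, cand);
          if (k == 0) tv[tidx[p]] = v;
          else if (k == 1) kappa = v;
          else theta = v;
          const double c = dataset_cost(seqs, lens, aprime, model, tv.data(),
                                        kappa, theta);
          if (c < local_best) {       // strict improvement only
            local_best = c;
            best_lvl = cand;
          }
        }
        if (best_lvl != levels[p]) {
          levels[p] = best_lvl;
          cost = local_best;
          moved = true;
        }
        const double v = level_value(k, levels[p]);  // restore/commit
        if (k == 0) tv[tidx[p]] = v;
        else if (k == 1) kappa = v;
        else theta = v;
      }
      trace.push_back(cost);
    }

    restart_costs[rs] = cost;
    traces[rs] = NumericVector(trace.begin(), trace.end());
    if (cost < best_cost) {
      best_cost = cost;
      best_restart = rs;
      best_levels = levels;
    }
  }

  NumericVector values(nfree);
  for (int p = 0; p < nfree; ++p)
    values[p] = level_value(kind[p], best_levels[p]);
  return List::create(_["values"] = values,
                      _["cost"] = best_cost,
                      _["restart_costs"] = restart_costs,
                      _["traces"] = traces,
                      _["best_restart"] = best_restart + 1);
}
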