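#include <Rcpp.h>
using namespace Rcpp;

// All randomness flows through R's RNG (unif_rand / R_unif_index), so a
// set.seed() on the R side makes every exported routine reproducible.

static inline int runif_index(int n) {
  return (int) R_unif_index((double) n);
}

// Shuffle the first k elements of idx (Fisher-Yates over the whole vector).
static void partial_shuffle(std::vector<int> &idx, int k) {
  int m = (int) idx.size();
  if (k > m) k = m;
  for (int i = 0; i < k; ++i) {
    int j = i + runif_index(m - i);
    std::swap(idx[i], idx[j]);
  }
}

static inline int tournament_count(double frac, int pool) {
  int k = (int) std::ceil(frac * pool);
  if (k < 1) k = 1;
  if (k > pool) k = pool;
  return k;
}

// Pick among the first k entries of elig: with probability |corr| the
// extreme given-energy candidate (max if corr > 0, min if corr < 0, ties
// broken uniformly), otherwise a uniform candidate. Returns the position
// (0..k-1) within elig.
static int choose_candidate(const std::vector<int> &elig, int k,
                            const double *g, double corr) {
  if (corr != 0.0 && unif_rand() < std::fabs(corr)) {
    bool want_max = corr > 0.0;
    double best = g[elig[0]];
    int best_pos = 0, ties = 1;
    for (int i = 1; i < k; ++i) {
      double gi = g[elig[i]];
      if ((want_max && gi > best) || (!want_max && gi < best)) {
        best = gi; best_pos = i; ties = 1;
      } else if (gi == best) {
        ++ties;
        if (runif_index(ties) == 0) best_pos = i;
      }
    }
    return best_pos;
  }
  return runif_index(k);
}

// One sharing phase: lucky agents act once each in a fresh random order;
// each transfers g[d] of its unit to a donee drawn from a tournament of
// currently eligible recipients (unlucky, energy <= min_energy). The donee
// pool is updated after every transfer (asynchronous update).
static void sharing_phase_impl(int n, const double *g, const double *c,
                               double *energy, const int *lucky,
                               double min_energy, double frac) {
  std::vector<int> donors, elig;
  donors.reserve(n); elig.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (lucky[i]) donors.push_back(i);
    else if (energy[i] <= min_energy) elig.push_back(i);
  }
  partial_shuffle(donors, (int) donors.size());
  for (size_t di = 0; di < donors.size(); ++di) {
    int m = (int) elig.size();
    if (m == 0) break;  // no needy recipients remain
    int d = donors[di];
    int k = tournament_count(frac, m);
    partial_shuffle(elig, k);
    int pos = choose_candidate(elig, k, g, c[d]);
    int donee = elig[pos];
    energy[d] -= g[d];
    energy[donee] += g[d];
    if (energy[donee] > min_energy) {  // sated: receives no further donations
      elig[pos] = elig.back();
      elig.pop_back();
    }
  }
}

// Generation boundary: fitness-biased imitation (asynchronous, fresh random
// order, strict improvement required) followed by an independent mutation
// pass. Fitness itself is left untouched; the caller resets it.
static void evolve_impl(int n, double *g, double *c, const int *fitness,
                        double strat_frac, double prob_mutation) {
  if (n > 1) {
    int k = tournament_count(strat_frac, n);
    if (k > n - 1) k = n - 1;  // the focal agent never samples itself
    std::vector<int> order(n), idx(n - 1);
    for (int i = 0; i < n; ++i) order[i] = i;
    partial_shuffle(order, n);
    for (int oi = 0; oi < n; ++oi) {
      int f = order[oi];
      int m = 0;
      for (int i = 0; i < n; ++i)
        if (i != f) idx[m++] = i;
      partial_shuffle(idx, k);
      int best = idx[0], ties = 1;
      for (int i = 1; i < k; ++i) {
        int cand = idx[i];
        if (fitness[cand] > fitness[best]) {
          best = cand; ties = 1;
        } else if (fitness[cand] == fitness[best]) {
          ++ties;
          if (runif_index(ties) == 0) best = cand;
        }
      }
      if (fitness[best] > fitness[f]) {
        g[f] = g[best];
        c[f] = c[best];
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    if (unif_rand() < prob_mutation) {
      g[i] = unif_rand();
      c[i] = 2.0 * unif_rand() - 1.0;
    }
  }
}

//' @noRd
// [[Rcpp::export]]
int cpp_select_donee(double correlation, NumericVector pool_given_energy,
                     double sharing_tournament_size) {
  int m = pool_given_energy.size();
  if (m == 0) return 0;
  std::vector<int> elig(m);
  for (int i = 0; i < m; ++i) elig[i] = i;
  int k = tournament_count(sharing_tournament_size, m);
  partial_shuffle(elig, k);
  int pos = choose_candidate(elig, k, REAL(pool_given_energy), correlation);
  return elig[pos] + 1;  // 1-based index into the pool
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_sharing_phase(NumericVector given_energy,
                                NumericVector correlation,
                                NumericVector energy, IntegerVector lucky,
                                double min_energy,
                                double sharing_tournament_size) {
  int n = given_energy.size();
  NumericVector out = clone(energy);
  sharing_phase_impl(n, REAL(given_energy), REAL(correlation), REAL(out),
                     INTEGER(lucky), min_energy, sharing_tournament_size);
  return out;
}

//' @noRd
// [[Rcpp::export]]
List cpp_evolve_generation(NumericVector given_energy,
                           NumericVector correlation, IntegerVector fitness,
                           double strategy_tournament_size,
                           double prob_mutation) {
  int n = given_energy.size();
  NumericVector g = clone(given_energy), c = clone(correlation);
  evolve_impl(n, REAL(g), REAL(c), INTEGER(fitness),
              strategy_tournament_size, prob_mutation);
  return List::create(_["given_energy"] = g, _["correlation"] = c);
}

//' @noRd
// [[Rcpp::export]]
List cpp_run_simulation(NumericVector g0, NumericVector c0,
                        double prob_resource, double min_energy,
                        double sharing_tournament_size,
                        double strategy_tournament_size,
                        double prob_mutation, int rounds_per_generation,
                        int n_generations) {
  int n = g0.size();
  std::vector<double> g(REAL(g0), REAL(g0) + n);
  std::vector<double> c(REAL(c0), REAL(c0) + n);
  std::vector<double> energy(n, 0.0);
  std::vector<int> fitness(n, 0), lucky(n, 0);
  NumericVector mean_g(n_generations), mean_c(n_generations);

  for (int gen = 0; gen < n_generations; ++gen) {
    // Strategies are constant within a generation; record the means that
    // hold for every period of this generation.
    double sg = 0.0, sc = 0.0;
    for (int i = 0; i < n; ++i) { sg += g[i]; sc += c[i]; }
    mean_g[gen] = sg / n;
    mean_c[gen] = sc / n;

    for (int r = 0; r < rounds_per_generation; ++r) {
      for (int i = 0; i < n; ++i) {
        lucky[i] = unif_rand() < prob_resource ? 1 : 0;
        energy[i] = lucky[i] ? 1.0 : 0.0;
      }
      sharing_phase_impl(n, g.data(), c.data(), energy.data(), lucky.data(),
                         min_energy, sharing_tournament_size);
      for (int i = 0; i < n; ++i)
        if (energy[i] > min_energy) ++fitness[i];
    }
    evolve_impl(n, g.data(), c.data(), fitness.data(),
                strategy_tournament_size, prob_mutation);
    std::fill(fitness.begin(), fitness.end(), 0);
  }

  return List::create(_["mean_given_energy"] = mean_g,
                      _["mean_correlation"] = mean_c,
                      _["final_given_energy"] = NumericVector(g.begin(), g.end()),
                      _["final_correlation"] = NumericVector(c.begin(), c.end()));
}
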