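// Compiled core of the one-dimensional refuge-to-forage group movement model.
//
// One self-contained xoshiro256++ stream per simulation run, seeded through
// splitmix64 from a 53-bit seed.  Fixed draw-consumption order per run:
//   1. n speed draws (agents 1..n),
//   2. per period: a Fisher-Yates shuffle of the not-yet-arrived agents
//      (k-1 draws for k active agents), then per agent at most one movement
//      draw and, under the nearest-neighbour rule, one tie-break draw when
//      several neighbours are exactly equidistant,
//   3. one focal-selection draw after termination.
// Arrived agents are frozen: they keep their position, stay visible to the
// social rules, and are dropped from the shuffle (their slot in a uniform
// permutation is unobservable, so the law of the trajectories is unchanged).

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on [0, 1)
  inline double unif() {
    return (next() >> 11) * 0x1.0p-53;
  }
  // uniform integer on {0, ..., m-1}
  inline int below(int m) {
    int r = static_cast<int>(unif() * m);
    return r >= m ? m - 1 : r;
  }
};

struct ModelParams {
  int n;
  double p_baseline;
  double omega_difference;
  double d_food;
  double threshold;
  double max_steps;
  int rule; // 0 non_social, 1 central, 2 nearest_neighbour, 3 majority
};

struct RunOutput {
  std::vector<double> speed, leave, arrival;
  double end_time;
  int focal; // 1-based
  std::vector<double> trajectory; // row-major (end_time + 1) x n when recorded
};

static void social_action(int i, int rule, int n,
                          std::vector<double> &d,
                          const std::vector<double> &s,
                          Xoshiro256pp &rng) {
  if (rule == 0) return; // non-social: stay put
  const double di = d[i];
  if (rule == 1) { // central: towards the mean position of the others
    double sum = 0.0;
    for (int j = 0; j < n; ++j) if (j != i) sum += d[j];
    const double target = sum / (n - 1);
    if (target > di) d[i] = di + s[i];
    else if (target < di) d[i] = di - s[i];
  } else if (rule == 2) { // nearest neighbour, random tie-break
    double best = R_PosInf;
    int ties = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dist = std::fabs(d[j] - di);
      if (dist < best) { best = dist; ties = 1; }
      else if (dist == best) ++ties;
    }
    if (best == 0.0) return; // nearest neighbour co-located: no move
    int pick = (ties > 1) ? rng.below(ties) : 0;
    double target = di;
    for (int j = 0, seen = 0; j < n; ++j) {
      if (j == i) continue;
      if (std::fabs(d[j] - di) == best && seen++ == pick) { target = d[j]; break; }
    }
    d[i] = di + ((target > di) ? s[i] : -s[i]);
  } else { // majority: strict counts either side; co-located count for neither
    int ahead = 0, behind = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (d[j] > di) ++ahead;
      else if (d[j] < di) ++behind;
    }
    if (ahead > behind) d[i] = di + s[i];
    else if (behind > ahead) d[i] = di - s[i];
  }
}

static RunOutput run_core(const ModelParams &pm, uint64_t seed, bool record) {
  const int n = pm.n;
  Xoshiro256pp rng(seed);

  std::vector<double> s(n), omega(n), p(n), d(n, 0.0);
  std::vector<double> leave(n, NA_REAL), arrival(n, NA_REAL);
  for (int i = 0; i < n; ++i) s[i] = 0.95 + 0.05 * rng.unif();
  for (int i = 0; i < n; ++i) { omega[i] = i * pm.omega_difference; p[i] = pm.p_baseline; }

  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;
  int n_active = n;

  RunOutput out;
  if (record) out.trajectory.insert(out.trajectory.end(), d.begin(), d.end());

  double t = 0.0;
  while (n_active > 0) {
    t += 1.0;
    if (t > pm.max_steps) {
      stop("simulation exceeded max_steps = %.0f before all individuals reached the foraging site",
           pm.max_steps);
    }
    // uniform random activation order over the active agents
    for (int k = n_active - 1; k >= 1; --k) {
      const int j = rng.below(k + 1);
      const int tmp = active[k]; active[k] = active[j]; active[j] = tmp;
    }
    for (int k = 0; k < n_active; ++k) {
      const int i = active[k];
      p[i] += omega[i];
      if (d[i] < 0.0) {
        d[i] += s[i]; // refuge lies between the agent and the food: forced outward
      } else {
        // active agents always satisfy 0 <= d < d_food here
        const double u = rng.unif();
        if (u < p[i]) d[i] += s[i];
        else social_action(i, pm.rule, n, d, s, rng);
      }
      if (ISNA(leave[i]) && d[i] >= pm.threshold) leave[i] = t;
      if (d[i] >= pm.d_food) arrival[i] = t;
    }
    // drop arrived agents at the end of the period
    int m = 0;
    for (int k = 0; k < n_active; ++k) {
      const int i = active[k];
      if (d[i] < pm.d_food) active[m++] = i;
    }
    n_active = m;
    if (record) out.trajectory.insert(out.trajectory.end(), d.begin(), d.end());
  }

  out.speed = s;
  out.leave = leave;
  out.arrival = arrival;
  out.end_time = t;
  out.focal = rng.below(n) + 1;
  return out;
}

static ModelParams as_params(int n, double p_baseline, double omega_difference,
                             double d_food, double threshold, double max_steps,
                             int rule) {
  ModelParams pm;
  pm.n = n; pm.p_baseline = p_baseline; pm.omega_difference = omega_difference;
  pm.d_food = d_food; pm.threshold = threshold; pm.max_steps = max_steps;
  pm.rule = rule;
  return pm;
}

static uint64_t as_seed(double seed) {
  if (!R_finite(seed) || seed < 0 || seed >= 9007199254740992.0)
    stop("seed must be a finite non-negative number below 2^53");
  return static_cast<uint64_t>(seed);
}

// [[Rcpp::export]]
List cpp_run_one(int n, double p_baseline, double omega_difference,
                 double d_food, double threshold, double max_steps,
                 int rule, double seed, bool record_trajectory) {
  const ModelParams pm = as_params(n, p_baseline, omega_difference, d_food,
                                   threshold, max_steps, rule);
  RunOutput out = run_core(pm, as_seed(seed), record_trajectory);
  List res = List::create(
    _["speed"] = NumericVector(out.speed.begin(), out.speed.end()),
    _["leave_time"] = NumericVector(out.leave.begin(), out.leave.end()),
    _["arrival_time"] = NumericVector(out.arrival.begin(), out.arrival.end()),
    _["end_time"] = out.end_time,
    _["focal"] = out.focal);
  if (record_trajectory) {
    const int rows = static_cast<int>(out.trajectory.size()) / n;
    NumericMatrix tr(rows, n);
    for (int r = 0; r < rows; ++r)
      for (int c = 0; c < n; ++c)
        tr(r, c) = out.trajectory[static_cast<size_t>(r) * n + c];
    res["trajectory"] = tr;
  }
  return res;
}

// [[Rcpp::export]]
List cpp_run_batch(int n, double p_baseline, double omega_difference,
                   double d_food, double threshold, double max_steps,
                   int rule, NumericVector seeds) {
  const ModelParams pm = as_params(n, p_baseline, omega_difference, d_food,
                                   threshold, max_steps, rule);
  const int runs = seeds.size();
  NumericMatrix speed(runs, n), leave(runs, n), arrival(runs, n);
  NumericVector end_time(runs);
  IntegerVector focal(runs);
  for (int r = 0; r < runs; ++r) {
    if ((r & 255) == 0) checkUserInterrupt();
    RunOutput out = run_core(pm, as_seed(seeds[r]), false);
    for (int i = 0; i < n; ++i) {
      speed(r, i) = out.speed[i];
      leave(r, i) = out.leave[i];
      arrival(r, i) = out.arrival[i];
    }
    end_time[r] = out.end_time;
    focal[r] = out.focal;
  }
  return List::create(_["speed"] = speed, _["leave_time"] = leave,
                      _["arrival_time"] = arrival, _["end_time"] = end_time,
                      _["focal"] = focal);
}

// Deterministic child-seed derivation: splitmix64 hash chain over the tuple
// (master_seed, rule_id, value_index, replicate_index), folded to 53 bits so
// the result is exactly representable as an R double.
// [[Rcpp::export]]
NumericVector cpp_derive_seed(double master_seed, IntegerVector rule_id,
                              IntegerVector value_index,
                              IntegerVector replicate_index) {
  const int m = rule_id.size();
  const uint64_t master = as_seed(master_seed);
  NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    uint64_t st = master;
    uint64_t h = splitmix64(st);
    st = h ^ (static_cast<uint64_t>(rule_id[k]) + 0x1000000ULL);
    h = splitmix64(st);
    st = h ^ (static_cast<uint64_t>(value_index[k]) + 0x2000000ULL);
    h = splitmix64(st);
    st = h ^ (static_cast<uint64_t>(replicate_index[k]) + 0x3000000ULL);
    h = splitmix64(st);
    out[k] = static_cast<double>(h >> 11);
  }
  return out;
}

// Expose the engine's Fisher-Yates shuffle for calibration tests.
// [[Rcpp::export]]
IntegerMatrix cpp_sample_permutations(int n, int times, double seed) {
  Xoshiro256pp rng(as_seed(seed));
  IntegerMatrix out(times, n);
  std::vector<int> idx(n);
  for (int r = 0; r < times; ++r) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int k = n - 1; k >= 1; --k) {
      const int j = rng.below(k + 1);
      const int tmp = idx[k]; idx[k] = idx[j]; idx[j] = tmp;
    }
    for (int i = 0; i < n; ++i) out(r, i) = idx[i] + 1;
  }
  return out;
}
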