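// Exact stochastic simulation (Gillespie direct method) for small
// mass-action reaction networks, plus a batched first-passage sampler.
//
// A self-contained counter-seeded RNG (splitmix64 -> xoshiro256++) is used
// instead of R's RNG so that trajectories are bit-identical across
// platforms and replicate streams can be derived deterministically from a
// single integer seed.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in (0, 1]
  double unif() {
    double u = (next() >> 11) * 0x1.0p-53;
    return 1.0 - u;
  }
};

inline uint64_t stream_seed(double seed, int stream) {
  uint64_t x = (uint64_t)(int64_t)seed;
  x ^= 0xD1B54A32D192ED03ULL * (uint64_t)(stream + 1);
  uint64_t y = x;
  return Xoshiro::splitmix64(y);
}

// mass-action propensity of reaction j at state x
inline double propensity(const NumericMatrix &react, const NumericVector &rate,
                         const std::vector<double> &x, int j) {
  double a = rate[j];
  if (a <= 0.0) return 0.0;
  const int S = react.nrow();
  for (int i = 0; i < S; ++i) {
    double m = react(i, j);
    if (m > 0.0) {
      double xi = x[i];
      for (int r = 0; r < (int)m; ++r) a *= (xi - r) / (r + 1.0);
      if (a <= 0.0) return 0.0;
    }
  }
  return a;
}

} // namespace

// Run one exact trajectory. Returns snapshots on `grid` (always includes the
// initial state if grid[0] == 0), an optional event log (times + channel,
// capped at max_record), the final state, and a status flag:
// 0 = horizon reached, 1 = exhausted (zero total propensity), 2 = event cap.
// [[Rcpp::export]]
List cpp_ssa_trajectory(NumericVector init, NumericMatrix react,
                        NumericMatrix nu, NumericVector rate,
                        double horizon, double seed, double max_events,
                        NumericVector grid, int max_record) {
  const int S = init.size(), R = rate.size();
  std::vector<double> x(init.begin(), init.end());
  Xoshiro rng(stream_seed(seed, 0));

  const int G = grid.size();
  NumericMatrix snaps(G, S);
  int gi = 0;
  std::vector<double> ev_t;
  std::vector<int> ev_c;
  if (max_record > 0) {
    ev_t.reserve(std::min((double)max_record, 1e6));
    ev_c.reserve(std::min((double)max_record, 1e6));
  }

  double t = 0.0;
  double n_events = 0.0;
  int status = 0;
  std::vector<double> a(R);

  for (;;) {
    double a0 = 0.0;
    for (int j = 0; j < R; ++j) {
      a[j] = propensity(react, rate, x, j);
      a0 += a[j];
    }
    double t_next = (a0 > 0.0) ? t - std::log(rng.unif()) / a0 : R_PosInf;

    while (gi < G && grid[gi] <= t_next && grid[gi] >= t) {
      if (grid[gi] > horizon) break;
      for (int i = 0; i < S; ++i) snaps(gi, i) = x[i];
      ++gi;
    }
    if (a0 <= 0.0) { status = 1; break; }
    if (t_next > horizon) { status = 0; t = horizon; break; }

    // channel selection proportional to propensity
    double u = rng.unif() * a0;
    int j = 0;
    double acc = a[0];
    while (acc < u && j < R - 1) acc += a[++j];

    t = t_next;
    for (int i = 0; i < S; ++i) x[i] += nu(i, j);
    n_events += 1.0;
    if ((double)ev_t.size() < (double)max_record) {
      ev_t.push_back(t);
      ev_c.push_back(j + 1);
    }
    if (n_events >= max_events) { status = 2; break; }
  }
  // fill remaining grid points with the final (frozen) state
  while (gi < G && grid[gi] <= horizon) {
    for (int i = 0; i < S; ++i) snaps(gi, i) = x[i];
    ++gi;
  }

  return List::create(
      _["snapshots"] = snaps, _["event_times"] = NumericVector(ev_t.begin(), ev_t.end()),
      _["event_channels"] = IntegerVector(ev_c.begin(), ev_c.end()),
      _["final_state"] = NumericVector(x.begin(), x.end()),
      _["t_final"] = t, _["n_events"] = n_events, _["status"] = status);
}

// First time the target species count reaches `threshold`, over `reps`
// independent replicates (replicate r uses a deterministic substream of
// `seed`). Censored replicates report the horizon with censored = TRUE.
// [[Rcpp::export]]
List cpp_first_passage(NumericVector init, NumericMatrix react,
                       NumericMatrix nu, NumericVector rate,
                       int target, double threshold, double horizon,
                       int reps, double seed, double max_events) {
  const int S = init.size(), R = rate.size();
  NumericVector times(reps);
  LogicalVector cens(reps);
  std::vector<double> a(R);

  for (int rep = 0; rep < reps; ++rep) {
    std::vector<double> x(init.begin(), init.end());
    Xoshiro rng(stream_seed(seed, rep));
    double t = 0.0, n_events = 0.0;
    bool hit = x[target - 1] >= threshold;
    while (!hit) {
      double a0 = 0.0;
      for (int j = 0; j < R; ++j) {
        a[j] = propensity(react, rate, x, j);
        a0 += a[j];
      }
      if (a0 <= 0.0) { t = horizon; break; }
      t -= std::log(rng.unif()) / a0;
      if (t > horizon) { t = horizon; break; }
      double u = rng.unif() * a0;
      int j = 0;
      double acc = a[0];
      while (acc < u && j < R - 1) acc += a[++j];
      for (int i = 0; i < S; ++i) x[i] += nu(i, j);
      if (x[target - 1] >= threshold) hit = true;
      if (++n_events >= max_events) { t = horizon; break; }
    }
    times[rep] = hit ? t : horizon;
    cens[rep] = !hit;
  }
  return List::create(_["times"] = times, _["censored"] = cens);
}
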