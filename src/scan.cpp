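#include <Rcpp.h>
#include <vector>
#include <climits>
#include <cmath>
using namespace Rcpp;

// Discrete-time walk of the PIC P-site. Event order within one step:
//   1. commitment check at the current position (AUG in the P-site),
//   2. dropoff,
//   3. eIF4E release (geometric; pre-sampled),
//   4. -1/0/+1 move with a reflecting floor (cap_offset while eIF4E-bound
//      under slot-in loading, 0 otherwise) and a runoff absorber at pmax.
// Dropoff and release times are pre-sampled from their geometric laws, which
// is equivalent in distribution to per-step Bernoulli draws and halves the
// RNG traffic. All randomness flows through R's RNG.

struct Walk {
  int len, entry, cap_offset, pmax, max_steps;
  bool bound0, tethered, slot_floor;
  double p_fwd, p_back, bound_mobility, release_rate, dropoff_rate;
  std::vector<double> commit; // per-position commitment probability
};

static int geom_steps(double p) {
  if (p <= 0.0) return INT_MAX;
  double g = R::rgeom(p); // failures before first success
  if (g > 2e9) return INT_MAX;
  return (int)g + 1;      // event occurs on this step
}

// simulate one trajectory; fills trace with the position occupied at each
// step (1-based step index -> trace[step-1]). Returns outcome: >=0 index of
// committed AUG in walk.commit? We return committed position; codes:
//  -1 dropoff, -2 runoff, -3 censored, >=0 committed at that position.
static int run_one(const Walk &w, std::vector<int> &trace, int &steps,
                   int &release_step) {
  int p = w.entry;
  bool bound = w.bound0;
  int drop_at = geom_steps(w.dropoff_rate);
  release_step = (bound && !w.tethered) ? geom_steps(w.release_rate) : INT_MAX;
  trace.clear();
  for (int t = 1; t <= w.max_steps; ++t) {
    trace.push_back(p);
    double r = w.commit[p];
    if (r > 0.0 && unif_rand() < r) { steps = t; return p; }
    if (t == drop_at) { steps = t; return -1; }
    if (bound && t >= release_step) bound = false;
    double mob = bound ? w.bound_mobility : 1.0; // cap tether restrains moves
    double u = unif_rand();
    int np = p;
    if (u < w.p_back * mob) {
      int floorpos = (bound && w.slot_floor) ? w.cap_offset : 0;
      np = (p - 1 >= floorpos) ? p - 1 : p;
    } else if (u < (w.p_back + w.p_fwd) * mob) {
      np = p + 1;
      if (np >= w.pmax) { steps = t; return -2; }
    }
    p = np;
  }
  steps = w.max_steps;
  return -3;
}

static Walk make_walk(int len, IntegerVector aug_pos, NumericVector aug_r,
                      int entry, bool bound0, bool tethered, bool slot_floor,
                      double p_fwd, double p_back, double bound_mobility,
                      double release_rate, double dropoff_rate,
                      int cap_offset, int pmax, int max_steps) {
  Walk w;
  w.len = len; w.entry = entry; w.cap_offset = cap_offset;
  w.pmax = pmax; w.max_steps = max_steps;
  w.bound0 = bound0; w.tethered = tethered; w.slot_floor = slot_floor;
  w.p_fwd = p_fwd; w.p_back = p_back; w.bound_mobility = bound_mobility;
  w.release_rate = release_rate; w.dropoff_rate = dropoff_rate;
  w.commit.assign(pmax + 1, 0.0);
  for (int i = 0; i < aug_pos.size(); ++i)
    if (aug_pos[i] >= 0 && aug_pos[i] < pmax) w.commit[aug_pos[i]] = aug_r[i];
  return w;
}

// [[Rcpp::export]]
List cpp_trajectories(int len, IntegerVector aug_pos, NumericVector aug_r,
                      int entry, bool bound0, bool tethered, bool slot_floor,
                      double p_fwd, double p_back, double bound_mobility,
                      double release_rate, double dropoff_rate,
                      int cap_offset, int pmax, int max_steps, int n_traj,
                      bool want_dwell, bool want_trace) {
  Walk w = make_walk(len, aug_pos, aug_r, entry, bound0, tethered, slot_floor,
                     p_fwd, p_back, bound_mobility, release_rate, dropoff_rate,
                     cap_offset, pmax, max_steps);
  IntegerVector outcome(n_traj), committed_at(n_traj), nsteps(n_traj);
  std::vector<double> dwell(want_dwell ? (size_t)pmax : 0, 0.0);
  std::vector<int> trace;
  IntegerVector first_trace;
  for (int k = 0; k < n_traj; ++k) {
    int steps = 0, rel = 0;
    int res = run_one(w, trace, steps, rel);
    if (res >= 0) { outcome[k] = 1; committed_at[k] = res; }
    else { outcome[k] = res; committed_at[k] = NA_INTEGER; }
    nsteps[k] = steps;
    if (want_dwell)
      for (size_t i = 0; i < trace.size(); ++i) dwell[trace[i]] += 1.0;
    if (want_trace && k == 0)
      first_trace = IntegerVector(trace.begin(), trace.end());
  }
  List out = List::create(_["outcome"] = outcome,
                          _["committed_at"] = committed_at,
                          _["steps"] = nsteps);
  if (want_dwell) out["dwell"] = NumericVector(dwell.begin(), dwell.end());
  if (want_trace) out["trace"] = first_trace;
  return out;
}

static inline int ilen(double m, double s) {
  int l = (int)std::lround(R::rnorm(m, s));
  return l < 3 ? 3 : l;
}

// [[Rcpp::export]]
List cpp_snapshot(int len, IntegerVector aug_pos, NumericVector aug_r,
                  int entry, bool bound0, bool tethered, bool slot_floor,
                  double p_fwd, double p_back, double bound_mobility,
                  double release_rate, double dropoff_rate,
                  int cap_offset, int pmax, int max_steps,
                  int phase_filter, // 0 = all, 1 = exclude 80S, 2 = 80S only
                  int snaps, int n_reads_target, int max_traj,
                  double cap_mean, double cap_sd,
                  double open_mean, double open_sd,
                  double closed_mean, double closed_sd, double p_open,
                  double up_frac,
                  double r80_mean, double r80_sd, int r80_offset,
                  int engage_dwell, int r80_dwell,
                  double osc_reach, double osc_sd, double noise_sd) {
  Walk w = make_walk(len, aug_pos, aug_r, entry, bound0, tethered, slot_floor,
                     p_fwd, p_back, bound_mobility, release_rate, dropoff_rate,
                     cap_offset, pmax, max_steps);
  std::vector<int> starts, ends, cls;
  starts.reserve(n_reads_target); ends.reserve(n_reads_target);
  cls.reserve(n_reads_target);
  std::vector<int> trace;
  int n_traj = 0;
  while ((int)starts.size() < n_reads_target && n_traj < max_traj) {
    ++n_traj;
    int steps = 0, release_step = 0;
    int res = run_one(w, trace, steps, release_step);
    bool committed = res >= 0;
    int committed_at = committed ? res : -1;
    if (phase_filter == 2 && !committed) continue;
    int life_scan = steps;
    long life_total;
    if (phase_filter == 2) life_total = 0; // unused
    else if (phase_filter == 1)
      life_total = life_scan + (committed ? engage_dwell : 0);
    else
      life_total = life_scan + (committed ? engage_dwell + r80_dwell : 0);
    for (int s = 0; s < snaps && (int)starts.size() < n_reads_target; ++s) {
      int s0 = 0, e0 = 0, c = 0;
      long t;
      if (phase_filter == 2) t = (long)life_scan + engage_dwell + 1; // 80S phase
      else t = 1 + (long)std::floor(unif_rand() * (double)life_total);
      if (phase_filter != 2 && t <= life_scan) {
        int p = trace[t - 1];
        bool bound_t = bound0 && (w.tethered || t < release_step);
        // the channel fragment presents the larger crosslinking surface, so
        // a bound complex yields its cap-side fragment in 1/3 of snapshots
        if (bound_t && unif_rand() < 1.0 / 3.0) {
          e0 = ilen(cap_mean, cap_sd); s0 = 0; c = 1;
        } else {
          int l = (unif_rand() < p_open) ? ilen(open_mean, open_sd)
                                         : ilen(closed_mean, closed_sd);
          int up = (int)std::floor(up_frac * l);
          s0 = p - up; e0 = s0 + l; c = 2;
        }
      } else if (phase_filter != 2 && t <= life_scan + engage_dwell) {
        // engaged at the start codon: oscillation excursions flank the
        // codon; their frequency scales with both eIF4A engagement (open
        // conformation) and backslide propensity -- no backward stepping,
        // no oscillation
        int l = (unif_rand() < p_open) ? ilen(open_mean, open_sd)
                                       : ilen(closed_mean, closed_sd);
        double p_exc = p_open * std::min(1.0, w.p_fwd > 0 ? w.p_back / w.p_fwd : 0.0);
        if (unif_rand() < p_exc) {
          int d = (int)std::lround(R::rnorm(osc_reach, osc_sd));
          if (d < 1) d = 1;
          if (unif_rand() < 0.5) { e0 = committed_at - d + 1; s0 = e0 - l; }
          else { s0 = committed_at + d; e0 = s0 + l; }
        } else {
          int up = (int)std::floor(up_frac * l);
          s0 = committed_at - up; e0 = s0 + l;
        }
        c = 2;
      } else { // 80S at the start codon
        int l = ilen(r80_mean, r80_sd);
        s0 = committed_at - r80_offset; e0 = s0 + l; c = 3;
      }
      // RNase boundary jitter, then clip; redraw degenerate reads
      for (int attempt = 0; attempt < 10; ++attempt) {
        int js = s0 + (int)std::lround(R::rnorm(0.0, noise_sd));
        int je = e0 + (int)std::lround(R::rnorm(0.0, noise_sd));
        if (js < 0) js = 0;
        if (je > len) je = len;
        if (je - js >= 1) {
          starts.push_back(js); ends.push_back(je); cls.push_back(c);
          break;
        }
      }
    }
  }
  return List::create(_["start"] = IntegerVector(starts.begin(), starts.end()),
                      _["end"] = IntegerVector(ends.begin(), ends.end()),
                      _["cls"] = IntegerVector(cls.begin(), cls.end()),
                      _["n_traj"] = n_traj);
}
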