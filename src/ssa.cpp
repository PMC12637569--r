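#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gillespie direct method for the coupled-subunit cluster.
//
// Per-subunit bookkeeping: expo[i] = delta * (ring-neighbour state sum)
// + sum of edge-weight * state over inter-channel contacts; gam[i] = exp(expo[i]). Opening propensity of a closed subunit is
// kfo * Ca * gam[i]; closing propensity of an open subunit is kb / gam[i].
// Because Ca = c0 + g * n_open multiplies every opening rate uniformly, the
// totals factorise: R_open = kfo * Ca * sum_{closed} gam and
// R_close = kb * sum_{open} 1/gam. A flip only changes the exponents of its
// <= 4 neighbours, so updates are O(neighbourhood); a change in n_open is an
// O(1) rescale through Ca. Running sums are resynchronised from scratch every
// 2^20 events to bound floating-point drift.
//
// All indices 0-based; inter_idx entries of -1 mean "no contact".
// Uses R's RNG: one uniform for the waiting time, one for event selection.

// [[Rcpp::export]]
List ssa_core(IntegerVector intra_prev, IntegerVector intra_next,
              IntegerMatrix inter_idx, NumericMatrix inter_w,
              IntegerVector channel_of, int n_channels,
              double kfo, double kb, double delta, double g, double c0,
              int open_min, int nc, double t_stop, double event_cap,
              bool stop_at_threshold, bool record, bool paranoid) {
  const int N = intra_prev.size();
  std::vector<int> s(N, -1);
  std::vector<double> expo(N), gam(N), invgam(N);
  std::vector<int> open_cnt(n_channels, 0), chan_open(n_channels, 0);
  int n_open = 0;

  auto raw_expo = [&](int i) {
    double e = delta * (s[intra_prev[i]] + s[intra_next[i]]);
    for (int j = 0; j < 2; ++j) {
      int b = inter_idx(i, j);
      if (b >= 0) e += inter_w(i, j) * s[b];
    }
    return e;
  };

  double sum_go = 0.0, sum_gc = 0.0;  // sum gam over closed / 1/gam over open
  auto resync = [&]() {
    sum_go = 0.0; sum_gc = 0.0;
    for (int i = 0; i < N; ++i) {
      expo[i] = raw_expo(i);
      gam[i] = std::exp(expo[i]);
      invgam[i] = 1.0 / gam[i];
      if (s[i] < 0) sum_go += gam[i]; else sum_gc += invgam[i];
    }
  };
  resync();

  double t = 0.0, n_events = 0.0, max_err = 0.0;
  long long since_resync = 0;
  bool fired = false, censored = false, capped = false, absorbing = false;
  std::vector<double> traj_t;
  std::vector<int> traj_n;
  if (record) { traj_t.push_back(0.0); traj_n.push_back(0); }

  for (;;) {
    if (paranoid) {
      double go = 0.0, gc = 0.0;
      for (int i = 0; i < N; ++i) {
        double e = raw_expo(i);
        if (s[i] < 0) go += std::exp(e); else gc += std::exp(-e);
      }
      // relative to the overall propensity scale so that an emptied pool
      // (exact value 0) with a ~1e-16 incremental residue is not flagged
      double scale = std::max(go + gc, 1e-300);
      double eo = std::abs(sum_go - go) / scale;
      double ec = std::abs(sum_gc - gc) / scale;
      if (eo > max_err) max_err = eo;
      if (ec > max_err) max_err = ec;
    }

    double ca = c0 + g * n_open;
    double r_open = kfo * ca * sum_go;
    double r_close = kb * sum_gc;
    double r_tot = r_open + r_close;
    if (r_tot <= 0.0) { absorbing = true; break; }

    t += -std::log(unif_rand()) / r_tot;
    if (t >= t_stop) { t = t_stop; censored = true; break; }

    double u = unif_rand() * r_tot;
    int k = -1;
    if (u < r_open) {
      double thr = u / (kfo * ca), acc = 0.0;
      int last = -1;
      for (int i = 0; i < N; ++i) {
        if (s[i] < 0) {
          last = i; acc += gam[i];
          if (acc >= thr) { k = i; break; }
        }
      }
      if (k < 0) k = last;
    } else {
      double thr = (u - r_open) / kb, acc = 0.0;
      int last = -1;
      for (int i = 0; i < N; ++i) {
        if (s[i] > 0) {
          last = i; acc += invgam[i];
          if (acc >= thr) { k = i; break; }
        }
      }
      if (k < 0) k = last;
    }

    int old = s[k];
    s[k] = -old;
    if (old < 0) { sum_go -= gam[k]; sum_gc += invgam[k]; }
    else         { sum_gc -= invgam[k]; sum_go += gam[k]; }

    int c = channel_of[k];
    open_cnt[c] += (old < 0) ? 1 : -1;
    int now = (open_cnt[c] >= open_min) ? 1 : 0;
    bool n_open_changed = false;
    if (now != chan_open[c]) {
      chan_open[c] = now;
      n_open += now ? 1 : -1;
      n_open_changed = true;
    }

    const double ds = s[k] - old;  // +/- 2; neighbour exponents shift by w*ds
    auto touch = [&](int m, double w) {
      expo[m] += w * ds;
      double ng = std::exp(expo[m]);
      if (s[m] < 0) sum_go += ng - gam[m];
      else          sum_gc += 1.0 / ng - invgam[m];
      gam[m] = ng; invgam[m] = 1.0 / ng;
    };
    touch(intra_prev[k], delta);
    touch(intra_next[k], delta);
    for (int j = 0; j < 2; ++j) {
      int b = inter_idx(k, j);
      if (b >= 0) touch(b, inter_w(k, j));
    }

    n_events += 1.0;
    if (record && n_open_changed) { traj_t.push_back(t); traj_n.push_back(n_open); }
    if (stop_at_threshold && n_open >= nc) { fired = true; break; }
    if (n_events >= event_cap) { capped = true; break; }
    if (++since_resync >= 1048576) {
      since_resync = 0;
      resync();
      checkUserInterrupt();
    }
  }

  return List::create(
    _["t"] = t, _["fired"] = fired, _["censored"] = censored,
    _["capped"] = capped, _["absorbing"] = absorbing,
    _["n_events"] = n_events, _["n_open"] = n_open,
    _["max_bookkeeping_err"] = max_err,
    _["traj_t"] = NumericVector(traj_t.begin(), traj_t.end()),
    _["traj_n"] = IntegerVector(traj_n.begin(), traj_n.end()));
}
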