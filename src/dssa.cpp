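#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Delayed product held on the waitlist until its absolute release time.
// `seq` breaks ties in insertion order so simultaneous releases are
// deterministic.
struct WaitEntry {
  double time;
  long seq;
  int species;
  int count;
};

struct WaitLater {
  bool operator()(const WaitEntry& a, const WaitEntry& b) const {
    if (a.time != b.time) return a.time > b.time;
    return a.seq > b.seq;
  }
};

// One reaction channel, precompiled in R to 0-based species indices.
struct Channel {
  std::vector<int> react_sp, react_n;
  std::vector<int> inst_sp, inst_n;
  std::vector<int> del_sp, del_n, del_kind; // kind: 0 constant, 1 gaussian
  std::vector<double> del_mean, del_sd;
  double rate;
};

static double channel_propensity(const Channel& ch, const std::vector<int>& x) {
  double h = 1.0;
  for (size_t i = 0; i < ch.react_sp.size(); ++i) {
    int n = x[ch.react_sp[i]];
    int m = ch.react_n[i];
    if (n < m) return 0.0;
    for (int k = 0; k < m; ++k) h *= (double)(n - k); // falling factorial
  }
  return ch.rate * h;
}

// Gaussian delays are redrawn (not clamped) when negative, keeping the
// delay distribution a proper truncated-free Gaussian restricted by
// rejection. Constant delays are used as-is.
static double draw_delay(int kind, double mean, double sd) {
  if (kind == 0 || sd <= 0.0) return mean;
  double d;
  do {
    d = R::rnorm(mean, sd);
  } while (d < 0.0);
  return d;
}

// Core delayed-SSA loop.
//
// Each cycle draws the next SSA reaction (waiting time Exp(a0), channel
// chosen proportionally to propensity) and races it against the earliest
// waitlist release. Ties go to the reaction. A release discards the drawn
// reaction (the draw is regenerated on the next cycle). Events strictly
// beyond t_end are never applied.
//
// RNG discipline (must match the R reference stepper exactly): when a0 > 0,
// one R::rexp and one unif_rand are consumed per cycle, then one R::rnorm
// per negative-delay rejection per Gaussian delayed product of an executed
// reaction, in product order.
//
// If `sample_times` (sorted ascending) is nonempty, the counts in effect at
// each sample time (state after all events with event time <= sample time)
// are recorded. If `record_events` the full event log is returned.
// [[Rcpp::export]]
List dssa_run_cpp(List reactions, IntegerVector init, double t_end,
                  bool record_events, NumericVector sample_times) {
  const int n_sp = init.size();
  const int n_rx = reactions.size();
  std::vector<Channel> chans(n_rx);
  for (int j = 0; j < n_rx; ++j) {
    List r = reactions[j];
    Channel& ch = chans[j];
    ch.react_sp = as<std::vector<int> >(r["react_sp"]);
    ch.react_n  = as<std::vector<int> >(r["react_n"]);
    ch.inst_sp  = as<std::vector<int> >(r["inst_sp"]);
    ch.inst_n   = as<std::vector<int> >(r["inst_n"]);
    ch.del_sp   = as<std::vector<int> >(r["del_sp"]);
    ch.del_n    = as<std::vector<int> >(r["del_n"]);
    ch.del_kind = as<std::vector<int> >(r["del_kind"]);
    ch.del_mean = as<std::vector<double> >(r["del_mean"]);
    ch.del_sd   = as<std::vector<double> >(r["del_sd"]);
    ch.rate     = as<double>(r["rate"]);
  }

  std::vector<int> x(n_sp);
  for (int i = 0; i < n_sp; ++i) {
    if (init[i] < 0) stop("initial counts must be nonnegative");
    x[i] = init[i];
  }

  std::priority_queue<WaitEntry, std::vector<WaitEntry>, WaitLater> wl;
  long seq = 0;

  std::vector<double> ev_time;
  std::vector<int> ev_kind;   // 1..n_rx reaction, 0 waitlist release
  std::vector<int> ev_counts; // row-major snapshots, n_sp per event

  const int n_samp = sample_times.size();
  IntegerMatrix samp(n_samp, n_sp);
  int k_samp = 0;

  double t = 0.0;
  const double INF = R_PosInf;
  std::vector<double> a(n_rx);

  RNGScope scope;

  for (;;) {
    double a0 = 0.0;
    for (int j = 0; j < n_rx; ++j) {
      a[j] = channel_propensity(chans[j], x);
      a0 += a[j];
    }

    double t_react = INF;
    int j_next = -1;
    if (a0 > 0.0) {
      double dt = R::rexp(1.0 / a0);
      double u = unif_rand();
      double cum = 0.0, target = u * a0;
      for (int j = 0; j < n_rx; ++j) {
        cum += a[j];
        if (target <= cum) { j_next = j; break; }
      }
      if (j_next < 0) j_next = n_rx - 1; // guard against roundoff
      t_react = t + dt;
    }
    double t_min = wl.empty() ? INF : wl.top().time;

    if (j_next >= 0 && t_react <= t_min) {
      if (t_react > t_end) break;
      while (k_samp < n_samp && sample_times[k_samp] < t_react) {
        for (int i = 0; i < n_sp; ++i) samp(k_samp, i) = x[i];
        ++k_samp;
      }
      t = t_react;
      const Channel& ch = chans[j_next];
      for (size_t i = 0; i < ch.react_sp.size(); ++i) x[ch.react_sp[i]] -= ch.react_n[i];
      for (size_t i = 0; i < ch.inst_sp.size(); ++i) x[ch.inst_sp[i]] += ch.inst_n[i];
      for (size_t i = 0; i < ch.del_sp.size(); ++i) {
        double d = draw_delay(ch.del_kind[i], ch.del_mean[i], ch.del_sd[i]);
        WaitEntry e; e.time = t + d; e.seq = seq++; e.species = ch.del_sp[i]; e.count = ch.del_n[i];
        wl.push(e);
      }
      if (record_events) {
        ev_time.push_back(t);
        ev_kind.push_back(j_next + 1);
        for (int i = 0; i < n_sp; ++i) ev_counts.push_back(x[i]);
      }
    } else if (t_min < INF) {
      if (t_min > t_end) break;
      while (k_samp < n_samp && sample_times[k_samp] < t_min) {
        for (int i = 0; i < n_sp; ++i) samp(k_samp, i) = x[i];
        ++k_samp;
      }
      WaitEntry e = wl.top(); wl.pop();
      t = e.time;
      x[e.species] += e.count;
      if (record_events) {
        ev_time.push_back(t);
        ev_kind.push_back(0);
        for (int i = 0; i < n_sp; ++i) ev_counts.push_back(x[i]);
      }
    } else {
      break; // no open channel and empty waitlist
    }
  }

  while (k_samp < n_samp) {
    for (int i = 0; i < n_sp; ++i) samp(k_samp, i) = x[i];
    ++k_samp;
  }

  List out;
  out["final_counts"] = IntegerVector(x.begin(), x.end());
  out["final_time"] = t;
  if (record_events) {
    const int ne = (int)ev_time.size();
    IntegerMatrix cm(ne, n_sp);
    for (int e = 0; e < ne; ++e)
      for (int i = 0; i < n_sp; ++i) cm(e, i) = ev_counts[(size_t)e * n_sp + i];
    out["time"] = NumericVector(ev_time.begin(), ev_time.end());
    out["event"] = IntegerVector(ev_kind.begin(), ev_kind.end());
    out["counts"] = cm;
  }
  if (n_samp > 0) out["samples"] = samp;
  return out;
}
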