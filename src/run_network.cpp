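// Euler integration of a network of quadratic integrate-and-fire neurons,
// pulse-coupled through exponentially decaying synaptic drives, with
// on-spike STDP weight updates (asymmetric Hebbian for excitatory
// pre-synaptic neurons, symmetric Hebbian / anti-Hebbian for inhibitory
// ones) and tanh soft-bounded weight dynamics.
//
// All randomness goes through R's RNG so that set.seed() in R makes runs
// bit-reproducible. Draw order within a step: one N(0,1) per
// non-refractory neuron, in neuron index order.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct StdpClassPars {
  // asymmetric rule (excitatory)
  double A_plus, A_minus, tau_plus, tau_minus;
  // symmetric rule (inhibitory)
  double A, tau;
  double f;
};

// Plasticity kernel value for pre-synaptic class q (0=e, 1=hi, 2=ai),
// dt = t_post - t_pre.
inline double kernel_value(int q, double dt, const StdpClassPars &p) {
  if (q == 0) {
    if (dt >= 0.0)
      return p.A_plus * std::exp(-dt / p.tau_plus) -
             p.A_minus * std::exp(-4.0 * dt / p.tau_plus) - p.f;
    return p.A_plus * std::exp(4.0 * dt / p.tau_minus) -
           p.A_minus * std::exp(dt / p.tau_minus) - p.f;
  }
  double x = dt / p.tau;
  double ricker = p.A * (1.0 - x * x) * std::exp(-0.5 * x * x);
  if (q == 1) return ricker - p.f;   // symmetric Hebbian
  return -ricker + p.f;              // symmetric anti-Hebbian
}

// Soft-bounded weight increment (learning rate applied by the caller).
// Excitatory weights live in [0,1], inhibitory in [-1,0].
inline double soft_bound_dw(int q, double w, double lam, double slope) {
  double lp = lam > 0.0 ? lam : 0.0;
  double lm = lam < 0.0 ? lam : 0.0;
  if (q == 0)
    return std::tanh(slope * (1.0 - w)) * lp + std::tanh(slope * w) * lm;
  // inhibitory: potentiation/depression kernels exchanged and sign flipped,
  // anchors 0 (upper) and -1 (lower)
  return -(std::tanh(slope * (0.0 - w)) * lm +
           std::tanh(slope * (w + 1.0)) * lp);
}

inline double clamp_class(int q, double w) {
  if (q == 0) {
    if (w < 0.0) return 0.0;
    if (w > 1.0) return 1.0;
  } else {
    if (w < -1.0) return -1.0;
    if (w > 0.0) return 0.0;
  }
  return w;
}

struct SpikeEvent {
  double t;
  int id;
};

} // namespace

// [[Rcpp::export]]
List run_network_cpp(NumericMatrix w_in, IntegerVector class_of,
                     NumericVector eta, NumericVector V0, List pars,
                     List stdp, bool plasticity, NumericMatrix epochs,
                     List epoch_targets, double duration,
                     Nullable<LogicalMatrix> mask_in, List record) {
  const int N = w_in.nrow();
  if (w_in.ncol() != N) stop("weight matrix must be square");
  if (class_of.size() != N || eta.size() != N || V0.size() != N)
    stop("class_of, eta and V0 must have length N");

  NumericMatrix w = clone(w_in);
  const bool has_mask = mask_in.isNotNull();
  LogicalMatrix mask;
  if (has_mask) mask = LogicalMatrix(mask_in);

  const double tau_m = as<double>(pars["tau_m"]);
  const double dt = as<double>(pars["dt"]);
  const double tau_de = as<double>(pars["tau_de"]);
  const double tau_di = as<double>(pars["tau_di"]);
  const double ge = as<double>(pars["ge"]);
  const double ghi = as<double>(pars["ghi"]);
  const double gai = as<double>(pars["gai"]);
  const double Vp = as<double>(pars["Vp"]);
  const double Vr = as<double>(pars["Vr"]);
  const double noise_sigma = as<double>(pars["noise_sigma"]);
  const std::string noise_mode = as<std::string>(pars["noise_mode"]);
  const bool noise_em = noise_mode == "em";
  const bool noise_pc = noise_mode == "pc";
  const double refractory_scale = as<double>(pars["refractory_scale"]);

  int Ne = 0, Nhi = 0, Nai = 0;
  for (int i = 0; i < N; ++i) {
    if (class_of[i] == 0) ++Ne;
    else if (class_of[i] == 1) ++Nhi;
    else if (class_of[i] == 2) ++Nai;
    else stop("class_of entries must be 0 (e), 1 (hi) or 2 (ai)");
  }

  StdpClassPars sp[3];
  {
    List se = stdp["e"], shi = stdp["hi"], sai = stdp["ai"];
    sp[0].A_plus = as<double>(se["A_plus"]);
    sp[0].A_minus = as<double>(se["A_minus"]);
    sp[0].tau_plus = as<double>(se["tau_plus"]);
    sp[0].tau_minus = as<double>(se["tau_minus"]);
    sp[0].A = 0.0; sp[0].tau = 1.0;
    sp[0].f = as<double>(se["f"]);
    for (int q = 1; q <= 2; ++q) {
      List s = (q == 1) ? shi : sai;
      sp[q].A = as<double>(s["A"]);
      sp[q].tau = as<double>(s["tau"]);
      sp[q].f = as<double>(s["f"]);
      sp[q].A_plus = sp[q].A_minus = 0.0;
      sp[q].tau_plus = sp[q].tau_minus = 1.0;
    }
  }
  const double gamma_l = as<double>(stdp["gamma_l"]);
  const double slope = as<double>(stdp["lambda"]);
  const bool do_plast = plasticity && gamma_l != 0.0;

  // recorders
  NumericVector snapshot_times = record.containsElementNamed("snapshot_times")
                                     ? as<NumericVector>(record["snapshot_times"])
                                     : NumericVector(0);
  const double k_dt = record.containsElementNamed("k_dt")
                          ? as<double>(record["k_dt"]) : 0.0;
  const double stats_dt = record.containsElementNamed("stats_dt")
                              ? as<double>(record["stats_dt"]) : 0.0;
  IntegerVector stats_module(0);
  if (stats_dt > 0.0) {
    if (!record.containsElementNamed("stats_module"))
      stop("stats_dt recording needs a stats_module assignment vector");
    stats_module = as<IntegerVector>(record["stats_module"]);
    if (stats_module.size() != N) stop("stats_module must have length N");
  }
  IntegerVector drive_neurons(0);
  double drive_dt = 0.0;
  if (record.containsElementNamed("drive_neurons")) {
    drive_neurons = as<IntegerVector>(record["drive_neurons"]); // 0-based
    drive_dt = as<double>(record["drive_dt"]);
  }

  // state
  std::vector<double> V(N), refrac_until(N, -1e300), last_spike(N, NA_REAL);
  std::vector<bool> ever_spiked(N, false);
  std::vector<double> Se(N, 0.0), Shi(N, 0.0), Sai(N, 0.0);
  for (int i = 0; i < N; ++i) V[i] = V0[i];

  const double dec_e = std::exp(-dt / tau_de);
  const double dec_i = std::exp(-dt / tau_di);
  const double noise_scale =
      noise_em ? noise_sigma * std::sqrt(dt) / tau_m : noise_sigma * dt / tau_m;
  // "pc" mode: xi held piecewise-constant over tau_m, redrawn for all
  // neurons every tau_m/dt steps
  const long pc_every = std::max(1L, (long)std::llround(tau_m / dt));
  std::vector<double> pc_noise;
  if (noise_pc) pc_noise.assign(N, 0.0);

  const long n_steps = (long)std::llround(duration / dt);
  const int n_epochs = epochs.nrow();
  std::vector<std::vector<int>> targets(n_epochs);
  for (int k = 0; k < n_epochs; ++k) {
    IntegerVector tv = epoch_targets[k]; // 0-based
    targets[k] = std::vector<int>(tv.begin(), tv.end());
  }
  std::vector<double> Istim(N, 0.0);
  int epoch_idx = 0;
  bool epoch_active = false;

  std::vector<double> raster_t;
  std::vector<int> raster_id;
  raster_t.reserve(1 << 16);
  raster_id.reserve(1 << 16);

  List snapshots;
  std::vector<double> snap_taken_at;
  int snap_idx = 0;

  std::vector<double> k_times, k_values;
  NumericMatrix w_prev;
  if (k_dt > 0.0) w_prev = clone(w);
  double next_k = k_dt;

  std::vector<double> stats_times;
  std::vector<std::array<double, 12>> stats_rows;
  double next_stats = 0.0;

  std::vector<double> drive_times;
  std::vector<std::vector<double>> drive_rows;
  double next_drive = 0.0;

  std::vector<SpikeEvent> step_spikes;

  RNGScope rng_scope;

  auto record_stats = [&](double tnow) {
    // mean weights split by pre-synaptic class (E/H/A), post-synaptic type
    // (E vs I) and intra- vs inter-module, in fixed column order
    double sum[12] = {0}; long cnt[12] = {0};
    for (int j = 0; j < N; ++j) {
      int mj = stats_module[j];
      if (mj < 0) continue;
      int q = class_of[j];
      for (int i = 0; i < N; ++i) {
        if (i == j) continue;
        int mi = stats_module[i];
        if (mi < 0) continue;
        if (has_mask && !mask(i, j)) continue;
        int post_i = class_of[i] == 0 ? 0 : 1;
        int col = q * 4 + post_i * 2 + (mi == mj ? 0 : 1);
        sum[col] += w(i, j);
        ++cnt[col];
      }
    }
    stats_times.push_back(tnow);
    std::array<double, 12> row;
    for (int c = 0; c < 12; ++c)
      row[c] = cnt[c] ? sum[c] / cnt[c] : NA_REAL;
    stats_rows.push_back(row);
  };

  if (stats_dt > 0.0) record_stats(0.0);

  for (long step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    const double t_next = t + dt;

    // stimulus bookkeeping (epochs sorted, non-overlapping)
    if (epoch_active && t >= epochs(epoch_idx, 1)) {
      for (int id : targets[epoch_idx]) Istim[id] = 0.0;
      epoch_active = false;
      ++epoch_idx;
    }
    if (!epoch_active && epoch_idx < n_epochs && t >= epochs(epoch_idx, 0) &&
        t < epochs(epoch_idx, 1)) {
      for (int id : targets[epoch_idx]) Istim[id] = epochs(epoch_idx, 2);
      epoch_active = true;
    }

    // membrane update + spike detection
    if (noise_pc && noise_sigma > 0.0 && step % pc_every == 0)
      for (int i = 0; i < N; ++i) pc_noise[i] = noise_sigma * norm_rand();
    step_spikes.clear();
    for (int i = 0; i < N; ++i) {
      if (t < refrac_until[i]) { V[i] = Vr; continue; }
      double input = eta[i] + ge * Se[i] + ghi * Shi[i] + gai * Sai[i] + Istim[i];
      if (noise_pc) input += pc_noise[i];
      double v = V[i];
      v += dt / tau_m * (v * v + input);
      if (!noise_pc && noise_sigma > 0.0) v += noise_scale * norm_rand();
      if (v >= Vp) {
        double ts = t_next + tau_m / v; // corrected firing time
        step_spikes.push_back({ts, i});
        refrac_until[i] = t_next + refractory_scale * tau_m / v;
        v = Vr;
      }
      if (!std::isfinite(v))
        stop("membrane potential diverged (non-finite V) at t=%f, neuron %d",
             t, i + 1);
      V[i] = v;
    }

    // synaptic drive decay
    for (int i = 0; i < N; ++i) {
      Se[i] *= dec_e;
      Shi[i] *= dec_i;
      Sai[i] *= dec_i;
    }

    if (!step_spikes.empty()) {
      std::sort(step_spikes.begin(), step_spikes.end(),
                [](const SpikeEvent &a, const SpikeEvent &b) {
                  return a.t < b.t || (a.t == b.t && a.id < b.id);
                });

      // plasticity: each spike updates all incident synapses whose partner
      // has fired at least once, using last-spike pairing
      if (do_plast) {
        for (const SpikeEvent &ev : step_spikes) {
          const int s = ev.id;
          const double ts = ev.t;
          const int qs = class_of[s];
          const StdpClassPars &ps = sp[qs];
          for (int k = 0; k < N; ++k) {
            if (k == s || !ever_spiked[k]) continue;
            const double tk = last_spike[k];
            // s as post-synaptic, k pre-synaptic: w(s,k)
            if (!has_mask || mask(s, k)) {
              int qk = class_of[k];
              double lam = kernel_value(qk, ts - tk, sp[qk]);
              double wv = w(s, k) + gamma_l * soft_bound_dw(qk, w(s, k), lam, slope);
              w(s, k) = clamp_class(qk, wv);
            }
            // s as pre-synaptic, k post-synaptic: w(k,s)
            if (!has_mask || mask(k, s)) {
              double lam = kernel_value(qs, tk - ts, ps);
              double wv = w(k, s) + gamma_l * soft_bound_dw(qs, w(k, s), lam, slope);
              w(k, s) = clamp_class(qs, wv);
            }
          }
          last_spike[s] = ts;
          ever_spiked[s] = true;
        }
      } else {
        for (const SpikeEvent &ev : step_spikes) {
          last_spike[ev.id] = ev.t;
          ever_spiked[ev.id] = true;
        }
      }

      // drive increments and raster
      for (const SpikeEvent &ev : step_spikes) {
        const int j = ev.id;
        const int q = class_of[j];
        raster_t.push_back(ev.t);
        raster_id.push_back(j);
        if (q == 0) {
          const double inv = 1.0 / Ne;
          for (int i = 0; i < N; ++i) Se[i] += w(i, j) * inv;
        } else if (q == 1) {
          const double inv = 1.0 / Nhi;
          for (int i = 0; i < N; ++i) Shi[i] += w(i, j) * inv;
        } else {
          const double inv = 1.0 / Nai;
          for (int i = 0; i < N; ++i) Sai[i] += w(i, j) * inv;
        }
      }
    }

    // recorders
    while (snap_idx < snapshot_times.size() &&
           t_next >= snapshot_times[snap_idx] - 1e-9) {
      snapshots.push_back(clone(w));
      snap_taken_at.push_back(snapshot_times[snap_idx]);
      ++snap_idx;
    }
    if (k_dt > 0.0 && t_next >= next_k - 1e-9) {
      double acc = 0.0;
      for (int j = 0; j < N; ++j)
        for (int i = 0; i < N; ++i)
          if (i != j) acc += w(i, j) - w_prev(i, j);
      k_times.push_back(t_next);
      k_values.push_back(acc / k_dt / ((double)N * (N - 1)));
      std::copy(w.begin(), w.end(), w_prev.begin());
      next_k += k_dt;
    }
    if (stats_dt > 0.0 && t_next >= next_stats + stats_dt - 1e-9) {
      record_stats(t_next);
      next_stats += stats_dt;
    }
    if (drive_dt > 0.0 && t_next >= next_drive + drive_dt - 1e-9) {
      std::vector<double> row;
      row.reserve(1 + 3 * drive_neurons.size());
      row.push_back(t_next);
      for (int k = 0; k < drive_neurons.size(); ++k) {
        int i = drive_neurons[k];
        row.push_back(Se[i]);
        row.push_back(Shi[i]);
        row.push_back(Sai[i]);
      }
      drive_times.push_back(t_next);
      drive_rows.push_back(row);
      next_drive += drive_dt;
    }

    if (step % 50000 == 0) checkUserInterrupt();
  }

  NumericMatrix raster(raster_t.size(), 2);
  for (size_t r = 0; r < raster_t.size(); ++r) {
    raster(r, 0) = raster_t[r];
    raster(r, 1) = raster_id[r] + 1; // 1-based ids for R
  }

  NumericMatrix stats_out(stats_rows.size(), 13);
  for (size_t r = 0; r < stats_rows.size(); ++r) {
    stats_out(r, 0) = stats_times[r];
    for (int c = 0; c < 12; ++c) stats_out(r, c + 1) = stats_rows[r][c];
  }

  NumericMatrix drives_out(drive_rows.size(),
                           drive_rows.empty() ? 0 : drive_rows[0].size());
  for (size_t r = 0; r < drive_rows.size(); ++r)
    for (size_t c = 0; c < drive_rows[r].size(); ++c)
      drives_out(r, c) = drive_rows[r][c];

  NumericVector Vout(N), last_out(N);
  for (int i = 0; i < N; ++i) {
    Vout[i] = V[i];
    last_out[i] = ever_spiked[i] ? last_spike[i] : NA_REAL;
  }

  return List::create(
      _["raster"] = raster, _["weights"] = w, _["V"] = Vout,
      _["last_spike"] = last_out, _["snapshots"] = snapshots,
      _["snapshot_times"] = wrap(snap_taken_at),
      _["k_times"] = wrap(k_times), _["k_values"] = wrap(k_values),
      _["stats"] = stats_out, _["drives"] = drives_out);
}
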