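// Event-driven core of the spiking network simulator.
//
// One call simulates the presentation of a single sample: Poisson input
// spikes (or an injected spike schedule) drive a layer of LIF neurons with
// exponential decay; the self-firing dopaminergic unit is handled as a
// separately scheduled event because it fires in the absence of input.
// All state is cloned on entry, so callers see R copy semantics.

#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List cpp_present(NumericMatrix W_in, NumericVector dopw_in,
                 NumericVector theta_in, NumericVector rates_in, List cfg,
                 bool frozen, bool plastic, bool use_dopamine, bool use_theta,
                 bool escalate, bool capture, NumericVector inj_times,
                 IntegerVector inj_ch) {
  const double v_th = cfg["v_th"];
  const double tau_mem = cfg["tau_mem"];
  const double tau_pre = cfg["tau_pre"];
  const double alpha_base = cfg["alpha_base"];
  const double alpha_boost = cfg["alpha_boost"];
  const double w_cap = cfg["w_cap"];
  const double tau_d = cfg["tau_d"];
  const double dop_vrest = cfg["dopamine_v_rest"];
  const double dop_vth = cfg["dopamine_v_th"];
  const double dop_inhibit = cfg["dopamine_inhibit"];
  const double eta = cfg["eta"];
  const double kappa = cfg["kappa"];
  const double recog_time = cfg["recognize_time"];
  const int recog_spikes = cfg["recognize_spikes"];
  const double esc_factor = cfg["escalation_factor"];
  const int esc_max = cfg["escalation_max"];
  const double theta_plus = cfg["theta_plus"];
  const double tau_theta = cfg["tau_theta"];
  const bool inhibit_hard = cfg["inhibition_hard"];
  const double inhibit_amount = cfg["inhibition_amount"];

  NumericMatrix W = clone(W_in);
  NumericVector dopw = clone(dopw_in);
  NumericVector theta = clone(theta_in);
  NumericVector rates = clone(rates_in);

  const int N = W.nrow();
  const int d = W.ncol();
  const bool injected = inj_times.size() > 0;
  const bool have_dopw = dopw.size() == N;
  const bool have_theta = use_theta && theta.size() == N;

  double sumr = 0.0;
  for (int i = 0; i < d; ++i) {
    if (rates[i] < 0) stop("negative input rate");
    sumr += rates[i];
  }
  if (!injected && sumr <= 0 && !(use_dopamine && !frozen))
    stop("stall: no positive input rates and dopamine disabled");

  std::vector<double> v(N, 0.0), tr(d, 0.0);
  std::vector<bool> boosted(N, false);
  double dop_v = 0.0;
  double t = 0.0, window_start = 0.0;
  int esc_steps = 0, total_out = 0, dop_fires = 0;
  bool fallback = false;
  IntegerVector spike_counts(N);
  std::vector<int> winners;
  std::vector<double> ev_t;
  std::vector<int> ev_kind, ev_id; // kind: 0 input, 1 output, 2 dopamine

  int inj_idx = 0;

  auto advance = [&](double dt) {
    if (dt <= 0) return;
    double fm = std::exp(-dt / tau_mem);
    for (int j = 0; j < N; ++j) v[j] *= fm;
    double fp = std::exp(-dt / tau_pre);
    for (int i = 0; i < d; ++i) tr[i] *= fp;
    if (use_dopamine && !frozen)
      dop_v = dop_vrest - (dop_vrest - dop_v) * std::exp(-dt / tau_d);
    if (have_theta && !frozen) {
      double ft = std::exp(-dt / tau_theta);
      for (int j = 0; j < N; ++j) theta[j] *= ft;
    }
    t += dt;
  };

  auto eff_th = [&](int j) {
    return have_theta ? v_th + theta[j] : v_th;
  };

  auto handle_fire = [&](int j) {
    if (capture) { ev_t.push_back(t); ev_kind.push_back(1); ev_id.push_back(j + 1); }
    ++total_out;
    ++spike_counts[j];
    winners.push_back(j + 1);
    double tr_sum = 0.0;
    for (int i = 0; i < d; ++i) tr_sum += tr[i];
    // no pre-synaptic evidence (fully silent input): nothing to learn from,
    // keep the weights rather than letting the update erase them
    if (plastic && !frozen && tr_sum > 0) {
      double a = boosted[j] ? alpha_boost : alpha_base;
      double ss = 0.0;
      for (int i = 0; i < d; ++i) {
        double w = W(j, i) + a * (tr[i] / tau_pre - W(j, i));
        if (w < 0) w = 0; else if (w > w_cap) w = w_cap;
        W(j, i) = w;
        ss += w * w;
      }
      if (ss <= 0) stop("degenerate weights after STDP update");
      double inv = 1.0 / std::sqrt(ss);
      for (int i = 0; i < d; ++i) W(j, i) *= inv;
    }
    boosted[j] = false;
    // lateral inhibition of the rest of the layer
    for (int k = 0; k < N; ++k) {
      if (k == j) continue;
      if (inhibit_hard) v[k] = 0.0;
      else v[k] -= inhibit_amount;
      boosted[k] = false;
    }
    v[j] = 0.0; // reset after fire
    if (use_dopamine && !frozen) dop_v -= dop_inhibit;
    if (have_dopw && !frozen) {
      dopw[j] *= (1.0 - eta);
      double ss = 0.0;
      for (int k = 0; k < N; ++k) ss += dopw[k] * dopw[k];
      double inv = 1.0 / std::sqrt(ss);
      for (int k = 0; k < N; ++k) dopw[k] *= inv;
    }
    if (have_theta && !frozen) theta[j] += theta_plus;
  };

  const long max_events = 50000000L;
  long n_events = 0;

  while (true) {
    if (++n_events > max_events) stop("event budget exceeded (runaway simulation)");

    // next input spike
    double dt_in = INF;
    int ch = -1;
    if (injected) {
      if (inj_idx >= inj_times.size()) break; // schedule exhausted
      dt_in = inj_times[inj_idx] - t;
      if (dt_in < 0) stop("injected spike times must be non-decreasing");
      ch = inj_ch[inj_idx] - 1;
    } else if (sumr > 0) {
      dt_in = exp_rand() / sumr;
      double u = unif_rand() * sumr, acc = 0.0;
      ch = d - 1;
      for (int i = 0; i < d; ++i) {
        acc += rates[i];
        if (u <= acc) { ch = i; break; }
      }
    }

    double dt_dop = INF;
    if (use_dopamine && !frozen) {
      dt_dop = (dop_v >= dop_vth)
                   ? 0.0
                   : tau_d * std::log((dop_vrest - dop_v) / (dop_vrest - dop_vth));
    }

    double dt_next = std::min(dt_in, dt_dop);
    if (dt_next == INF) break; // injected stream exhausted, nothing scheduled

    // escalation window boundary (inference / baseline training only)
    if (escalate && !injected && total_out < recog_spikes &&
        t + dt_next >= window_start + recog_time) {
      advance(window_start + recog_time - t);
      ++esc_steps;
      if (esc_steps > esc_max) { fallback = true; break; }
      for (int i = 0; i < d; ++i) rates[i] *= esc_factor;
      sumr *= esc_factor;
      window_start = t;
      continue; // redraw with the escalated rates (memoryless)
    }

    if (dt_dop < dt_in) {
      // dopaminergic self-fire: novelty signal
      advance(dt_dop);
      ++dop_fires;
      if (capture) { ev_t.push_back(t); ev_kind.push_back(2); ev_id.push_back(0); }
      dop_v = 0.0;
      for (int j = 0; j < N; ++j) boosted[j] = true;
      double dmax = 0.0;
      for (int j = 0; j < N; ++j) if (dopw[j] > dmax) dmax = dopw[j];
      if (!(have_dopw && dmax > 0)) stop("dopamine fired without fan-out weights");
      double gain = kappa * v_th / dmax;
      // The stimulation ramps until the first neuron crosses threshold:
      // the winner needs the smallest fraction of the full increment,
      // i.e. minimizes (threshold - v_j) / (gain * d_j). Neurons whose
      // full increment cannot reach threshold do not fire.
      int winner = -1;
      double best = 1.0 + 1e-12;
      for (int j = 0; j < N; ++j) {
        double need = (eff_th(j) - v[j]) / (gain * dopw[j]);
        if (need < best) { best = need; winner = j; }
      }
      for (int j = 0; j < N; ++j) v[j] += gain * dopw[j];
      if (winner >= 0) {
        handle_fire(winner);
      }
      // if nobody reached threshold (kappa < 1), the potentials keep the
      // stimulation and the unit will self-fire again after its rise time
    } else {
      if (ch < 0) break;
      advance(dt_in);
      if (injected) ++inj_idx;
      tr[ch] += 1.0;
      if (capture) { ev_t.push_back(t); ev_kind.push_back(0); ev_id.push_back(ch + 1); }
      int winner = -1;
      for (int j = 0; j < N; ++j) {
        v[j] += W(j, ch);
        if (winner < 0 && v[j] >= eff_th(j)) winner = j; // lowest index wins
      }
      if (winner >= 0) handle_fire(winner);
    }

    if (!injected && total_out >= recog_spikes) break;
  }

  List out = List::create(
      _["weights"] = W, _["dop_weights"] = dopw, _["theta"] = theta,
      _["spike_counts"] = spike_counts, _["dop_fires"] = dop_fires,
      _["duration"] = t, _["esc_steps"] = esc_steps,
      _["winners"] = IntegerVector(winners.begin(), winners.end()),
      _["fallback"] = fallback, _["v_final"] = NumericVector(v.begin(), v.end()),
      _["traces_final"] = NumericVector(tr.begin(), tr.end()),
      _["dop_v_final"] = dop_v);
  if (capture) {
    out["events"] = List::create(
        _["time"] = NumericVector(ev_t.begin(), ev_t.end()),
        _["kind"] = IntegerVector(ev_kind.begin(), ev_kind.end()),
        _["id"] = IntegerVector(ev_id.begin(), ev_id.end()));
  }
  return out;
}
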