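#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Wrapped (3-term) Gaussian bump, unit peak at d = 0.
// |d| <= 0.5 on entry, so the k = -1, 0, 1 images capture the wrap to
// machine precision for the sigmas used here (sigma << 0.5).
static inline double wrapped_bump(double d, double sigma) {
  double s2 = 2.0 * sigma * sigma;
  double v = std::exp(-(d * d) / s2);
  double dm = d - 1.0, dp = d + 1.0;
  v += std::exp(-(dm * dm) / s2) + std::exp(-(dp * dp) / s2);
  return v;
}

static inline double wrap01(double x) {
  return x - std::floor(x);
}

static inline double circ_dist(double a, double b) {
  return wrap01(a - b + 0.5) - 0.5;
}

// Single-threaded simulation engine for the multi-layer feedforward ring
// network. One call = one uninterrupted simulation (warm-up + main loop).
//
// Layers are indexed 0..n_layers-1; block b holds the edges from layer b
// (pre) to layer b+1 (post). Edge arrays are 0-based and grouped by block
// via block_ptr (length n_blocks + 1). Rates are in Hz, times in ms.
//
// Dynamics per timestep (dt ms):
//   r_j(t) = r_j(t - dt) * exp(-dt / tau_m) + (dt / tau_m) * I_j(t)
//   I_j(t) = (1000 / dt) * sum_i W_ji * S_i(t - t_delay)
// so that a presynaptic population firing at rate r through weights summing
// to one drives a steady-state rate of approximately r.
//
// STDP bookkeeping: kernA[k], k = 0..KA-1, is the kernel value for a post
// spike now paired with a pre spike k steps ago (effective timing difference
// (k - delay_steps) * dt). kernB[k-1], k = 1..KB, is the value for a pre
// spike now paired with a post spike k steps ago (difference (-k -
// delay_steps) * dt). The k = 0 pre/post-now pair lives in kernA only, so
// no pair is counted twice. Spike histories are kept as per-step index
// lists, so all plasticity work scales with the number of spikes, not with
// the number of neurons.
//
// The growth ceiling (w_cap per block) is enforced as a standing constraint:
// weights are clamped to [0, cap] after every STDP update and after every
// normalization event.
// [[Rcpp::export]]
List run_network_cpp(int n_neurons, int n_layers,
                     IntegerVector edge_pre, IntegerVector edge_post,
                     IntegerVector block_ptr,
                     NumericVector w_start, NumericVector w_cap,
                     int n_steps, int warmup_steps,
                     int stim_kind, double stim_pos0, double stim_vel,
                     double stim_onset, double stim_offset, double stim_amp,
                     double r_b, double sigma_p, double dt, double tau_m,
                     int delay_steps,
                     bool plastic, double lr_max, int ramp_steps,
                     double norm_prob,
                     NumericVector kernA, NumericVector kernB,
                     bool record_spikes, bool record_rates,
                     int snapshot_every,
                     Nullable<IntegerMatrix> forced_spikes_) {
  const int n_blocks = n_layers - 1;
  const int KA = kernA.size();
  const int KB = kernB.size();
  const int H = std::max(KA, delay_steps + 1);  // history depth, steps
  const double decay = std::exp(-dt / tau_m);
  const double a = dt / tau_m;
  const double i_scale = 1000.0 / dt;
  const double p_scale = dt / 1000.0;  // Hz -> spike probability per step

  std::vector<double> w(w_start.begin(), w_start.end());

  // incoming-edge index per postsynaptic neuron (CSR) and outgoing-edge
  // index per presynaptic neuron (CSC), per block, over global edge ids
  std::vector<std::vector<int> > in_ptr(n_blocks), in_edge(n_blocks);
  std::vector<std::vector<int> > out_ptr(n_blocks), out_edge(n_blocks);
  for (int b = 0; b < n_blocks; ++b) {
    std::vector<int> cin(n_neurons + 1, 0), cout(n_neurons + 1, 0);
    for (int e = block_ptr[b]; e < block_ptr[b + 1]; ++e) {
      ++cin[edge_post[e] + 1];
      ++cout[edge_pre[e] + 1];
    }
    for (int i = 0; i < n_neurons; ++i) {
      cin[i + 1] += cin[i];
      cout[i + 1] += cout[i];
    }
    in_ptr[b] = cin;
    out_ptr[b] = cout;
    in_edge[b].resize(block_ptr[b + 1] - block_ptr[b]);
    out_edge[b].resize(block_ptr[b + 1] - block_ptr[b]);
    std::vector<int> pin(cin.begin(), cin.end() - 1),
        pout(cout.begin(), cout.end() - 1);
    for (int e = block_ptr[b]; e < block_ptr[b + 1]; ++e) {
      in_edge[b][pin[edge_post[e]]++] = e;
      out_edge[b][pout[edge_pre[e]]++] = e;
    }
  }

  // per-block max starting weight, for the growth-ceiling ratio
  std::vector<double> w_max_init(n_blocks, 0.0);
  for (int b = 0; b < n_blocks; ++b)
    for (int e = block_ptr[b]; e < block_ptr[b + 1]; ++e)
      if (w[e] > w_max_init[b]) w_max_init[b] = w[e];

  bool forced = forced_spikes_.isNotNull();
  IntegerMatrix forced_spikes;
  if (forced) {
    forced_spikes = IntegerMatrix(forced_spikes_);
    if (forced_spikes.nrow() != n_layers * n_neurons ||
        forced_spikes.ncol() < n_steps)
      stop("forced_spikes must be (n_layers * n_neurons) x n_steps");
  }

  // spike history: per layer, H slots of spiking-neuron index lists
  std::vector<std::vector<std::vector<int> > > hist(
      n_layers, std::vector<std::vector<int> >(H));

  std::vector<std::vector<double> > rates(n_layers,
                                          std::vector<double>(n_neurons, 0.0));
  for (int i = 0; i < n_neurons; ++i) rates[0][i] = r_b;

  std::vector<double> I(n_neurons, 0.0);
  std::vector<double> u_pre(n_neurons, 0.0), v_post(n_neurons, 0.0);
  std::vector<double> sums(n_neurons, 0.0);

  std::vector<int> spike_layer, spike_neuron, spike_step;
  std::vector<int> norm_steps;
  List rate_list(record_rates ? n_layers : 0);
  std::vector<NumericMatrix> rate_mats;
  if (record_rates)
    for (int l = 0; l < n_layers; ++l)
      rate_mats.push_back(NumericMatrix(n_neurons, n_steps));

  List snaps;
  std::vector<int> snap_steps;

  double max_ratio = 1.0;  // starting weights themselves give ratio 1
  std::vector<double> inv_wmax(n_blocks);
  for (int b = 0; b < n_blocks; ++b)
    inv_wmax[b] = w_max_init[b] > 0 ? 1.0 / w_max_init[b] : 0.0;

  RNGScope rng_scope;

  for (int s = -warmup_steps; s < n_steps; ++s) {
    const int u = s + warmup_steps;       // absolute step counter >= 0
    const int slot = u % H;
    const double t = s * dt;              // ms, main-loop-relative

    // --- input-layer rates from the stimulus
    bool on = (stim_kind != 0) && s >= 0 && t >= stim_onset && t < stim_offset;
    double pos = 0.0;
    if (on) pos = wrap01(stim_pos0 + stim_vel * t / 1000.0);
    for (int i = 0; i < n_neurons; ++i) {
      double r = r_b;
      if (on) {
        double d = circ_dist(static_cast<double>(i) / n_neurons, pos);
        r += stim_amp * wrapped_bump(d, sigma_p);
      }
      rates[0][i] = r;
    }

    // --- higher layers: integrate the delayed spikes of the layer below
    const int du = u - delay_steps;
    for (int b = 0; b < n_blocks; ++b) {
      std::fill(I.begin(), I.end(), 0.0);
      if (du >= 0) {
        const std::vector<int>& dsp = hist[b][du % H];
        for (size_t si = 0; si < dsp.size(); ++si) {
          int i = dsp[si];
          for (int k = out_ptr[b][i]; k < out_ptr[b][i + 1]; ++k) {
            int e = out_edge[b][k];
            I[edge_post[e]] += w[e];
          }
        }
      }
      std::vector<double>& r = rates[b + 1];
      for (int j = 0; j < n_neurons; ++j)
        r[j] = r[j] * decay + a * i_scale * I[j];
    }

    // --- spikes (written into this step's history slot)
    for (int l = 0; l < n_layers; ++l) {
      std::vector<int>& sl = hist[l][slot];
      sl.clear();
      if (forced && s >= 0) {
        for (int i = 0; i < n_neurons; ++i)
          if (forced_spikes(l * n_neurons + i, s) != 0) sl.push_back(i);
      } else {
        for (int i = 0; i < n_neurons; ++i) {
          double p = rates[l][i] * p_scale;
          if (p > 1.0) p = 1.0;
          if (unif_rand() < p) sl.push_back(i);
        }
      }
      if (record_spikes && s >= 0)
        for (size_t si = 0; si < sl.size(); ++si) {
          spike_layer.push_back(l + 1);
          spike_neuron.push_back(sl[si] + 1);
          spike_step.push_back(s + 1);
        }
    }

    if (record_rates && s >= 0)
      for (int l = 0; l < n_layers; ++l)
        for (int i = 0; i < n_neurons; ++i)
          rate_mats[l](i, s) = rates[l][i];

    // --- plasticity
    if (plastic && s >= 0) {
      double p_t = lr_max;
      if (ramp_steps > 0 && s < ramp_steps)
        p_t = lr_max * (static_cast<double>(s) / ramp_steps);
      if (p_t > 0) {
        for (int b = 0; b < n_blocks; ++b) {
          const std::vector<int>& post_now = hist[b + 1][slot];
          const std::vector<int>& pre_now = hist[b][slot];
          if (post_now.empty() && pre_now.empty()) continue;
          double cap = w_cap[b];

          if (!post_now.empty()) {
            // pre-history convolution (includes this step's pre spikes, k=0)
            std::fill(u_pre.begin(), u_pre.end(), 0.0);
            int kmax = std::min(KA - 1, u);
            for (int k = 0; k <= kmax; ++k) {
              double kv = kernA[k];
              if (kv == 0.0) continue;
              const std::vector<int>& sp = hist[b][(u - k) % H];
              for (size_t si = 0; si < sp.size(); ++si) u_pre[sp[si]] += kv;
            }
            for (size_t ji = 0; ji < post_now.size(); ++ji) {
              int j = post_now[ji];
              for (int k = in_ptr[b][j]; k < in_ptr[b][j + 1]; ++k) {
                int e = in_edge[b][k];
                double du_w = u_pre[edge_pre[e]];
                if (du_w != 0.0) {
                  double nw = w[e] + p_t * du_w;
                  if (nw < 0.0) nw = 0.0;
                  if (nw > cap) nw = cap;
                  w[e] = nw;
                  double ratio = nw * inv_wmax[b];
                  if (ratio > max_ratio) max_ratio = ratio;
                }
              }
            }
          }
          if (!pre_now.empty()) {
            // post-history convolution (strictly past post spikes, k >= 1)
            std::fill(v_post.begin(), v_post.end(), 0.0);
            int kmax = std::min(KB, u);
            for (int k = 1; k <= kmax; ++k) {
              double kv = kernB[k - 1];
              if (kv == 0.0) continue;
              const std::vector<int>& sp = hist[b + 1][(u - k) % H];
              for (size_t si = 0; si < sp.size(); ++si) v_post[sp[si]] += kv;
            }
            for (size_t ii = 0; ii < pre_now.size(); ++ii) {
              int i = pre_now[ii];
              for (int k = out_ptr[b][i]; k < out_ptr[b][i + 1]; ++k) {
                int e = out_edge[b][k];
                double dv = v_post[edge_post[e]];
                if (dv != 0.0) {
                  double nw = w[e] + p_t * dv;
                  if (nw < 0.0) nw = 0.0;
                  if (nw > cap) nw = cap;
                  w[e] = nw;
                  double ratio = nw * inv_wmax[b];
                  if (ratio > max_ratio) max_ratio = ratio;
                }
              }
            }
          }
        }
      }

      // --- stochastic multiplicative normalization (one event, all blocks)
      if (unif_rand() < norm_prob) {
        norm_steps.push_back(s + 1);
        for (int b = 0; b < n_blocks; ++b) {
          std::fill(sums.begin(), sums.end(), 0.0);
          for (int e = block_ptr[b]; e < block_ptr[b + 1]; ++e)
            sums[edge_post[e]] += w[e];
          double cap = w_cap[b];
          for (int e = block_ptr[b]; e < block_ptr[b + 1]; ++e) {
            double sm = sums[edge_post[e]];
            if (sm > 0) {
              double nw = w[e] / sm;
              if (nw > cap) nw = cap;
              w[e] = nw;
              double ratio = nw * inv_wmax[b];
              if (ratio > max_ratio) max_ratio = ratio;
            }
          }
        }
      }
    }

    if (snapshot_every > 0 && s >= 0 && ((s + 1) % snapshot_every) == 0) {
      snaps.push_back(NumericVector(w.begin(), w.end()));
      snap_steps.push_back(s + 1);
    }
  }

  IntegerMatrix spikes(spike_layer.size(), 3);
  for (size_t r = 0; r < spike_layer.size(); ++r) {
    spikes(r, 0) = spike_layer[r];
    spikes(r, 1) = spike_neuron[r];
    spikes(r, 2) = spike_step[r];
  }
  colnames(spikes) = CharacterVector::create("layer", "neuron", "step");

  if (record_rates)
    for (int l = 0; l < n_layers; ++l) rate_list[l] = rate_mats[l];

  NumericMatrix final_rates(n_layers, n_neurons);
  for (int l = 0; l < n_layers; ++l)
    for (int i = 0; i < n_neurons; ++i) final_rates(l, i) = rates[l][i];

  return List::create(
      _["weights"] = NumericVector(w.begin(), w.end()),
      _["max_ratio"] = max_ratio,
      _["w_max_init"] = NumericVector(w_max_init.begin(), w_max_init.end()),
      _["spikes"] = spikes,
      _["norm_steps"] = IntegerVector(norm_steps.begin(), norm_steps.end()),
      _["snapshots"] = snaps,
      _["snapshot_steps"] = IntegerVector(snap_steps.begin(), snap_steps.end()),
      _["rates"] = rate_list,
      _["final_rates"] = final_rates);
}
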