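// Clock-driven simulator of the current-based LIF recurrent network with
// delayed delta-pulse synapses, independent Poisson external drive, and
// homeostatic structural plasticity on the excitatory-to-excitatory block:
// per-neuron calcium traces drive continuous axonal/dendritic element
// counters; every rewiring interval, negative elements delete randomly
// chosen contacts and free elements are randomly paired into new contacts.
//
// Neuron indexing (0-based internally): excitatory 0..n_e-1, inhibitory
// n_e..n_e+n_i-1, readout neurons appended after the network (they receive
// input but project nowhere).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <utility>
#include "rng.h"

using namespace Rcpp;

namespace {

struct EEGraph {
  int n_e;
  std::vector<std::vector<std::pair<int, int>>> out;  // per pre: (post, count)
  std::vector<std::vector<std::pair<int, int>>> in;   // per post: (pre, count)
  std::vector<int> k_out, k_in;
  std::vector<int> group;                 // block label per E neuron (0-based)
  std::vector<std::vector<double>> bsum;  // block contact totals

  void init(int n, const std::vector<int> &grp, int n_blocks) {
    n_e = n;
    out.assign(n, {});
    in.assign(n, {});
    k_out.assign(n, 0);
    k_in.assign(n, 0);
    group = grp;
    bsum.assign(n_blocks, std::vector<double>(n_blocks, 0.0));
  }

  void add(int pre, int post, int count) {
    bool found = false;
    for (auto &pr : out[pre])
      if (pr.first == post) { pr.second += count; found = true; break; }
    if (!found) out[pre].push_back({post, count});
    found = false;
    for (auto &pr : in[post])
      if (pr.first == pre) { pr.second += count; found = true; break; }
    if (!found) in[post].push_back({pre, count});
    k_out[pre] += count;
    k_in[post] += count;
    bsum[group[pre]][group[post]] += count;
  }

  void remove_one(int pre, int post) {
    for (size_t m = 0; m < out[pre].size(); ++m)
      if (out[pre][m].first == post) {
        if (--out[pre][m].second == 0) {
          out[pre][m] = out[pre].back();
          out[pre].pop_back();
        }
        break;
      }
    for (size_t m = 0; m < in[post].size(); ++m)
      if (in[post][m].first == pre) {
        if (--in[post][m].second == 0) {
          in[post][m] = in[post].back();
          in[post].pop_back();
        }
        break;
      }
    --k_out[pre];
    --k_in[post];
    bsum[group[pre]][group[post]] -= 1.0;
  }

  // delete one uniformly chosen outgoing contact of `pre`
  void delete_out(int pre, XoshiroRNG &rng) {
    int r = (int)rng.bounded((uint32_t)k_out[pre]);
    for (auto &pr : out[pre]) {
      if (r < pr.second) { remove_one(pre, pr.first); return; }
      r -= pr.second;
    }
  }

  void delete_in(int post, XoshiroRNG &rng) {
    int r = (int)rng.bounded((uint32_t)k_in[post]);
    for (auto &pr : in[post]) {
      if (r < pr.second) { remove_one(pr.first, post); return; }
      r -= pr.second;
    }
  }
};

// One structural-plasticity update: contact deletions driven by negative
// elements (axonal first, then dendritic; quotas fixed at entry, clipped to
// the contacts actually present), then uniform random pairing of all free
// elements, with self-pairings rejected and redrawn.
void rewire(EEGraph &g, std::vector<double> &a, std::vector<double> &d,
            XoshiroRNG &rng) {
  int n = g.n_e;
  std::vector<int> afloor(n), dfloor(n), aminus(n), dminus(n);
  for (int i = 0; i < n; ++i) {
    afloor[i] = (int)std::floor(a[i]);
    dfloor[i] = (int)std::floor(d[i]);
    aminus[i] = std::max(g.k_out[i] - afloor[i], 0);
    dminus[i] = std::max(g.k_in[i] - dfloor[i], 0);
  }
  for (int i = 0; i < n; ++i) {
    int ndel = std::min(aminus[i], g.k_out[i]);
    for (int k = 0; k < ndel; ++k) g.delete_out(i, rng);
  }
  for (int i = 0; i < n; ++i) {
    int ndel = std::min(dminus[i], g.k_in[i]);
    for (int k = 0; k < ndel; ++k) g.delete_in(i, rng);
  }
  std::vector<int> axons, dends;
  for (int i = 0; i < n; ++i) {
    int ap = std::max(afloor[i] - g.k_out[i], 0);
    int dp = std::max(dfloor[i] - g.k_in[i], 0);
    for (int k = 0; k < ap; ++k) axons.push_back(i);
    for (int k = 0; k < dp; ++k) dends.push_back(i);
  }
  rng.shuffle(axons);
  rng.shuffle(dends);
  size_t npair = std::min(axons.size(), dends.size());
  if (npair == 0) return;
  std::vector<size_t> cand;
  for (size_t k = 0; k < npair; ++k) {
    // self-pairings are rejected and redrawn uniformly among the
    // not-yet-consumed elements of the other owner (dendritic side first,
    // axonal side as fallback), so no element is ever used twice; a
    // pairing is dropped only when every remaining element belongs to the
    // same neuron
    if (axons[k] == dends[k]) {
      cand.clear();
      for (size_t m = k; m < dends.size(); ++m)
        if (dends[m] != axons[k]) cand.push_back(m);
      if (!cand.empty()) {
        std::swap(dends[k], dends[cand[rng.bounded((uint32_t)cand.size())]]);
      } else {
        for (size_t m = k; m < axons.size(); ++m)
          if (axons[m] != dends[k]) cand.push_back(m);
        if (!cand.empty())
          std::swap(axons[k],
                    axons[cand[rng.bounded((uint32_t)cand.size())]]);
      }
    }
    if (axons[k] == dends[k]) continue;  // irreducible self-pairing dropped
    g.add(axons[k], dends[k], 1);
  }
}

}  // namespace

// [[Rcpp::export]]
List rewire_step_cpp(IntegerMatrix ee, int n_e, NumericVector a,
                     NumericVector d, int seed) {
  XoshiroRNG rng((uint64_t)seed);
  EEGraph g;
  std::vector<int> grp(n_e, 0);
  g.init(n_e, grp, 1);
  for (int k = 0; k < ee.nrow(); ++k)
    g.add(ee(k, 0) - 1, ee(k, 1) - 1, ee(k, 2));
  std::vector<double> av(a.begin(), a.end()), dv(d.begin(), d.end());
  rewire(g, av, dv, rng);
  long ncon = 0;
  for (int j = 0; j < n_e; ++j) ncon += (long)g.out[j].size();
  IntegerMatrix out((int)ncon, 3);
  int row = 0;
  for (int j = 0; j < n_e; ++j)
    for (auto &pr : g.out[j]) {
      out(row, 0) = j + 1;
      out(row, 1) = pr.first + 1;
      out(row, 2) = pr.second;
      ++row;
    }
  return List::create(_["ee"] = out,
                      _["k_in"] = IntegerVector(g.k_in.begin(), g.k_in.end()),
                      _["k_out"] = IntegerVector(g.k_out.begin(), g.k_out.end()));
}

// [[Rcpp::export]]
List sim_network_cpp(int n_e, int n_i, List lif, IntegerMatrix static_syn,
                     IntegerMatrix ee_syn, List plast, NumericMatrix episodes,
                     IntegerVector stim_group, double dt, List init,
                     List record, List readouts, int seed_drive,
                     int seed_rewire) {
  const double tau_m = as<double>(lif["tau_m_ms"]);
  const double v_th = as<double>(lif["v_th_mv"]);
  const double v_r = as<double>(lif["v_r_mv"]);
  const double t_ref = as<double>(lif["t_ref_ms"]);
  const double delay = as<double>(lif["delay_ms"]);
  const double J = as<double>(lif["j_mv"]);
  const double g_rel = as<double>(lif["g"]);
  const double nu_ext = as<double>(lif["nu_ext_hz"]);

  const int delay_steps = (int)std::llround(delay / dt);
  if (std::fabs(delay_steps * dt - delay) > 1e-9 || delay_steps < 1)
    stop("time step must divide the synaptic delay exactly");
  if (dt > t_ref + 1e-12) stop("time step must not exceed the refractory period");
  const int t_ref_steps = (int)std::llround(t_ref / dt);
  const double decay = std::exp(-dt / tau_m);

  const bool plastic_any = as<bool>(plast["enabled"]);
  const double tau_ca_s = as<double>(plast["tau_ca_s"]);
  const double beta_a = as<double>(plast["beta_a"]);
  const double beta_d = as<double>(plast["beta_d"]);
  const double nu_target = as<double>(plast["nu_target_hz"]);
  const double rewire_every = as<double>(plast["rewire_every_ms"]);
  const int rewire_steps = std::max(1, (int)std::llround(rewire_every / dt));
  const double dt_s = dt * 1e-3;
  const double ca_decay = std::exp(-dt_s / tau_ca_s);

  const int n_net = n_e + n_i;
  // readout wiring: flattened (pre -> readout, count) adjacency
  const int n_ro = readouts.size();
  const int n_tot = n_net + n_ro;
  std::vector<std::vector<std::pair<int, int>>> ro_adj(n_net);
  for (int rdx = 0; rdx < n_ro; ++rdx) {
    IntegerMatrix w = readouts[rdx];
    for (int k = 0; k < w.nrow(); ++k)
      ro_adj[w(k, 0) - 1].push_back({n_net + rdx, w(k, 1)});
  }

  // static adjacency in CSR form
  std::vector<int> sptr(n_net + 1, 0);
  for (int k = 0; k < static_syn.nrow(); ++k) sptr[static_syn(k, 0)]++;
  for (int j = 0; j < n_net; ++j) sptr[j + 1] += sptr[j];
  std::vector<int> stgt(static_syn.nrow()), scnt(static_syn.nrow());
  {
    std::vector<int> fill(sptr.begin(), sptr.end() - 1);
    for (int k = 0; k < static_syn.nrow(); ++k) {
      int j = static_syn(k, 0) - 1;
      stgt[fill[j]] = static_syn(k, 1) - 1;
      scnt[fill[j]] = static_syn(k, 2);
      ++fill[j];
    }
  }

  // plastic EE graph and block bookkeeping
  IntegerVector cgrp = record["conn_group"];
  int n_blocks = 0;
  std::vector<int> grp(n_e);
  for (int i = 0; i < n_e; ++i) {
    grp[i] = cgrp[i] - 1;
    n_blocks = std::max(n_blocks, cgrp[i]);
  }
  EEGraph g;
  g.init(n_e, grp, n_blocks);
  for (int k = 0; k < ee_syn.nrow(); ++k)
    g.add(ee_syn(k, 0) - 1, ee_syn(k, 1) - 1, ee_syn(k, 2));

  XoshiroRNG rng_drive((uint64_t)seed_drive);
  XoshiroRNG rng_rew((uint64_t)seed_rewire);

  // neuron state
  std::vector<double> V(n_tot, 0.0), phi(n_e, 0.0);
  std::vector<double> a(n_e, 0.0), d(n_e, 0.0);
  std::vector<int> refr(n_tot, 0);
  if (init.containsElementNamed("v") && Rf_length(init["v"]) > 0) {
    NumericVector v0 = init["v"];
    for (int i = 0; i < std::min((int)v0.size(), n_tot); ++i) V[i] = v0[i];
  } else {
    for (int i = 0; i < n_tot; ++i)
      V[i] = v_r + (v_th - v_r) * rng_drive.runif();
  }
  if (init.containsElementNamed("phi") && Rf_length(init["phi"]) > 0) {
    NumericVector p0 = init["phi"];
    for (int i = 0; i < n_e; ++i) phi[i] = p0[i];
  }
  if (init.containsElementNamed("a") && Rf_length(init["a"]) > 0) {
    NumericVector a0 = init["a"], d0 = init["d"];
    for (int i = 0; i < n_e; ++i) { a[i] = a0[i]; d[i] = d0[i]; }
  }

  // ring buffer of delayed synaptic input
  std::vector<std::vector<double>> buf(delay_steps,
                                       std::vector<double>(n_tot, 0.0));

  // recorders
  const double conn_every = as<double>(record["conn_every_ms"]);
  const double rate_bin = as<double>(record["rate_bin_ms"]);
  NumericMatrix spike_windows = record["spike_windows"];
  const bool spikes_all_pops = as<bool>(record["spikes_all"]);
  double total_ms = 0.0;
  const int n_ep = episodes.nrow();
  for (int e = 0; e < n_ep; ++e) total_ms += episodes(e, 0);
  const long total_steps = (long)std::llround(total_ms / dt);
  const int conn_steps =
      conn_every > 0 ? (int)std::llround(conn_every / dt) : 0;
  const int rate_steps = std::max(1, (int)std::llround(rate_bin / dt));
  const long n_rate_bins = (total_steps + rate_steps - 1) / rate_steps;
  const long n_conn_rec = conn_steps > 0 ? total_steps / conn_steps + 1 : 1;

  std::vector<double> conn_times;
  std::vector<double> conn_series;  // row-major: time x (block x block)
  std::vector<double> ca_series;    // time x block
  conn_times.reserve(n_conn_rec);
  std::vector<double> rate_counts((size_t)n_rate_bins * (n_blocks + 1), 0.0);
  std::vector<double> spk_t;
  std::vector<int> spk_id;
  std::vector<double> ro_spk_t;
  std::vector<int> ro_spk_id;
  IntegerMatrix ep_counts(n_tot, n_ep);  // per-neuron spike count per episode

  std::vector<int> bcount(n_blocks, 0);
  for (int i = 0; i < n_e; ++i) ++bcount[grp[i]];

  auto snapshot = [&](double t_ms) {
    conn_times.push_back(t_ms);
    for (int b1 = 0; b1 < n_blocks; ++b1)
      for (int b2 = 0; b2 < n_blocks; ++b2)
        conn_series.push_back(
            g.bsum[b1][b2] / ((double)bcount[b1] * (double)bcount[b2]));
    std::vector<double> cm(n_blocks, 0.0);
    for (int i = 0; i < n_e; ++i) cm[grp[i]] += phi[i];
    for (int b = 0; b < n_blocks; ++b) ca_series.push_back(cm[b] / bcount[b]);
  };
  snapshot(0.0);

  int wdx = 0;  // active spike-recording window
  const int n_win = spike_windows.nrow();

  long step = 0;
  std::vector<int> spikes_now;
  spikes_now.reserve(256);

  for (int e = 0; e < n_ep; ++e) {
    const long ep_steps = (long)std::llround(episodes(e, 0) / dt);
    const bool plastic_now = plastic_any && episodes(e, 1) > 0.5;
    const int n_g = episodes.ncol() - 2;
    // per-stim-group Poisson parameters for this episode
    std::vector<double> lam(n_g), exp_neg(n_g);
    for (int gi = 0; gi < n_g; ++gi) {
      lam[gi] = nu_ext * episodes(e, 2 + gi) * dt_s;
      exp_neg[gi] = std::exp(-lam[gi]);
    }
    for (long k = 0; k < ep_steps; ++k) {
      const int cur = (int)(step % delay_steps);
      const double t_now = (step + 1) * dt;
      std::vector<double> &slot = buf[cur];
      spikes_now.clear();
      for (int i = 0; i < n_tot; ++i) {
        if (refr[i] > 0) {
          --refr[i];
          V[i] = v_r;
          slot[i] = 0.0;
          continue;
        }
        double inp = slot[i];
        slot[i] = 0.0;
        int sg = i < n_net ? stim_group[i] - 1 : 0;
        if (lam[sg] > 0.0)
          inp += J * rng_drive.rpois(exp_neg[sg]);
        V[i] = V[i] * decay + inp;
        if (V[i] >= v_th) {
          spikes_now.push_back(i);
          V[i] = v_r;
          refr[i] = t_ref_steps;
        }
      }
      // spike effects: calcium, recording, delayed delivery
      for (int j : spikes_now) {
        ++ep_counts(j, e);
        if (j >= n_net) {
          ro_spk_t.push_back(t_now);
          ro_spk_id.push_back(j - n_net + 1);
          continue;
        }
        if (j < n_e) phi[j] += 1.0 / tau_ca_s;
        if (n_win > 0) {
          while (wdx < n_win && t_now > spike_windows(wdx, 1)) ++wdx;
          if (wdx < n_win && t_now >= spike_windows(wdx, 0) &&
              (spikes_all_pops || j < n_e)) {
            spk_t.push_back(t_now);
            spk_id.push_back(j + 1);
          }
        }
        rate_counts[(step / rate_steps) * (n_blocks + 1) +
                    (j < n_e ? grp[j] : n_blocks)] += 1.0;
        const double w = j < n_e ? J : -g_rel * J;
        for (int m = sptr[j]; m < sptr[j + 1]; ++m)
          slot[stgt[m]] += w * scnt[m];
        if (j < n_e)
          for (auto &pr : g.out[j]) slot[pr.first] += J * pr.second;
        for (auto &pr : ro_adj[j]) slot[pr.first] += w * pr.second;
      }
      // homeostatic element growth
      if (plastic_now) {
        for (int i = 0; i < n_e; ++i) {
          phi[i] *= ca_decay;
          double drive = dt_s * (nu_target - phi[i]);
          a[i] += drive / beta_a;
          d[i] += drive / beta_d;
          if (a[i] < 0.0) a[i] = 0.0;
          if (d[i] < 0.0) d[i] = 0.0;
        }
      } else {
        for (int i = 0; i < n_e; ++i) phi[i] *= ca_decay;
      }
      ++step;
      if (plastic_now && step % rewire_steps == 0) rewire(g, a, d, rng_rew);
      if (conn_steps > 0 && step % conn_steps == 0) snapshot(step * dt);
    }
  }
  if (conn_steps == 0 || total_steps % conn_steps != 0)
    snapshot(total_steps * dt);

  long ncon = 0;
  for (int j = 0; j < n_e; ++j) ncon += (long)g.out[j].size();
  IntegerMatrix ee_out((int)ncon, 3);
  {
    int row = 0;
    for (int j = 0; j < n_e; ++j)
      for (auto &pr : g.out[j]) {
        ee_out(row, 0) = j + 1;
        ee_out(row, 1) = pr.first + 1;
        ee_out(row, 2) = pr.second;
        ++row;
      }
  }

  NumericMatrix rates((int)n_rate_bins, n_blocks + 1);
  for (long b = 0; b < n_rate_bins; ++b)
    for (int c = 0; c <= n_blocks; ++c)
      rates((int)b, c) = rate_counts[b * (n_blocks + 1) + c];

  int n_snap = (int)conn_times.size();
  NumericMatrix conn_mat(n_snap, n_blocks * n_blocks);
  NumericMatrix ca_mat(n_snap, n_blocks);
  for (int s = 0; s < n_snap; ++s) {
    for (int c = 0; c < n_blocks * n_blocks; ++c)
      conn_mat(s, c) = conn_series[(size_t)s * n_blocks * n_blocks + c];
    for (int c = 0; c < n_blocks; ++c)
      ca_mat(s, c) = ca_series[(size_t)s * n_blocks + c];
  }

  NumericMatrix spikes((int)spk_t.size(), 2);
  for (int s = 0; s < (int)spk_t.size(); ++s) {
    spikes(s, 0) = spk_t[s];
    spikes(s, 1) = spk_id[s];
  }
  NumericMatrix ro_spikes((int)ro_spk_t.size(), 2);
  for (int s = 0; s < (int)ro_spk_t.size(); ++s) {
    ro_spikes(s, 0) = ro_spk_t[s];
    ro_spikes(s, 1) = ro_spk_id[s];
  }

  return List::create(
      _["v"] = NumericVector(V.begin(), V.end()),
      _["phi"] = NumericVector(phi.begin(), phi.end()),
      _["a"] = NumericVector(a.begin(), a.end()),
      _["d"] = NumericVector(d.begin(), d.end()),
      _["ee"] = ee_out,
      _["k_in"] = IntegerVector(g.k_in.begin(), g.k_in.end()),
      _["k_out"] = IntegerVector(g.k_out.begin(), g.k_out.end()),
      _["conn_time_ms"] = NumericVector(conn_times.begin(), conn_times.end()),
      _["conn_blocks"] = conn_mat,
      _["calcium_blocks"] = ca_mat,
      _["rate_counts"] = rates,
      _["rate_bin_ms"] = rate_bin,
      _["spikes"] = spikes,
      _["readout_spikes"] = ro_spikes,
      _["episode_counts"] = ep_counts,
      _["duration_ms"] = total_ms);
}
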