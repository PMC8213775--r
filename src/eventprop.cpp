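#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// Closed-form free dynamics of the LIF system:
//   tau_syn dI/dt = -I          => I(dt) = I0 * exp(-dt/tau_syn)
//   tau_mem dV/dt = -V + I      => V(dt) = (V0 - c) e^{-dt/tau_mem} + c e^{-dt/tau_syn}
// with c = I0 * tau_syn / (tau_syn - tau_mem).
static inline double v_closed(double v0, double i0, double dt,
                              double tau_mem, double tau_syn) {
  double c = i0 * tau_syn / (tau_syn - tau_mem);
  return (v0 - c) * std::exp(-dt / tau_mem) + c * std::exp(-dt / tau_syn);
}

// First up-crossing (sign change of V - theta, negative -> positive) of one
// neuron's closed-form membrane potential within (lo, hi], measured from the
// state (v0, i0) at local time 0. Returns NA when no bracket is found.
// Bracketing on a fixed grid; bisection to ~machine precision (the closed
// form is cheap and bisection is unconditionally robust for a bracketed
// sign change). Tangential touches produce no sign change and are treated
// as non-crossings, consistent with the transition requiring dV/dt != 0.
static double crossing_time(double v0, double i0, double lo, double hi,
                            double theta, double tau_mem, double tau_syn,
                            double grid) {
  if (hi <= lo) return NA_REAL;
  double a = lo;
  double fa = v_closed(v0, i0, a, tau_mem, tau_syn) - theta;
  while (a < hi) {
    double b = std::min(a + grid, hi);
    double fb = v_closed(v0, i0, b, tau_mem, tau_syn) - theta;
    if (fa < 0.0 && fb > 0.0) {
      for (int k = 0; k < 100; ++k) {
        double mid = 0.5 * (a + b);
        if (mid <= a || mid >= b) break;
        double fm = v_closed(v0, i0, mid, tau_mem, tau_syn) - theta;
        if (fm > 0.0) b = mid; else a = mid;
      }
      return 0.5 * (a + b);
    }
    a = b;
    fa = fb;
  }
  return NA_REAL;
}

// Event-driven forward pass. Input spikes (times ascending, 0-based
// channels) and detected threshold crossings are processed in time order;
// at numerically equal times inputs are applied first, then crossings in
// ascending neuron index with independently cached pre-transition currents.
// [[Rcpp::export]]
List cpp_simulate(NumericMatrix w_rec, NumericMatrix w_in,
                  LogicalVector firing,
                  double tau_mem, double tau_syn, double theta,
                  double t_end,
                  NumericVector in_times, IntegerVector in_chan,
                  double grid, double spike_cap, bool record_traj) {
  const int n = w_rec.nrow();
  const int n_in = in_times.size();

  std::vector<double> v(n, 0.0), i_cur(n, 0.0);
  double t = 0.0;
  int ptr = 0;

  // per-neuron crossing cache: absolute crossing time (inf = none found in
  // (t, searched_until]); invalidated whenever the neuron's state jumps
  std::vector<double> cross_t(n, std::numeric_limits<double>::infinity());
  std::vector<double> searched(n, 0.0);
  std::vector<bool> dirty(n, true);

  std::vector<double> rec_t, rec_im, rec_vd;
  std::vector<int> rec_n;
  std::vector<double> traj_t;
  std::vector<double> traj_v, traj_i;  // row-major n per event
  int n_crit = 0;

  // does column c of a matrix touch neuron j? precompute nonzero pattern of
  // w_rec columns to limit cache invalidation
  std::vector<std::vector<int> > rec_targets(n);
  for (int c = 0; c < n; ++c)
    for (int r = 0; r < n; ++r)
      if (w_rec(r, c) != 0.0) rec_targets[c].push_back(r);
  const int m = w_in.ncol();
  std::vector<std::vector<int> > in_targets(m);
  for (int c = 0; c < m; ++c)
    for (int r = 0; r < n; ++r)
      if (w_in(r, c) != 0.0) in_targets[c].push_back(r);

  if (record_traj) {
    traj_t.push_back(0.0);
    for (int j = 0; j < n; ++j) { traj_v.push_back(0.0); traj_i.push_back(0.0); }
  }

  for (;;) {
    double horizon = (ptr < n_in) ? std::min(in_times[ptr], t_end) : t_end;

    // refresh crossing caches up to the horizon
    double t_cross = std::numeric_limits<double>::infinity();
    int n_cross = -1;
    for (int j = 0; j < n; ++j) {
      if (!firing[j]) continue;
      if (dirty[j]) {
        cross_t[j] = std::numeric_limits<double>::infinity();
        searched[j] = t;
        dirty[j] = false;
      }
      if (!std::isfinite(cross_t[j]) && searched[j] < horizon) {
        double tc = crossing_time(v[j], i_cur[j], searched[j] - t, horizon - t,
                                  theta, tau_mem, tau_syn, grid);
        searched[j] = horizon;
        if (!ISNA(tc)) cross_t[j] = t + tc;
      }
      if (cross_t[j] < t_cross) { t_cross = cross_t[j]; n_cross = j; }
    }

    double t_next = std::min(t_cross, horizon);

    // advance all neurons with the exact closed form
    {
      double dt = t_next - t;
      double em = std::exp(-dt / tau_mem), es = std::exp(-dt / tau_syn);
      double fac = tau_syn / (tau_syn - tau_mem);
      for (int j = 0; j < n; ++j) {
        double c = i_cur[j] * fac;
        v[j] = (v[j] - c) * em + c * es;
        i_cur[j] = i_cur[j] * es;
      }
      t = t_next;
    }

    // 1) input spikes at exactly this time
    bool any_event = false;
    while (ptr < n_in && in_times[ptr] == t) {
      int c = in_chan[ptr];
      for (size_t k = 0; k < in_targets[c].size(); ++k) {
        int j = in_targets[c][k];
        i_cur[j] += w_in(j, c);
        dirty[j] = true;
      }
      ++ptr;
      any_event = true;
    }

    // 2) coincident threshold crossings, ascending neuron index, with
    //    pre-transition currents
    std::vector<int> crossers;
    for (int j = 0; j < n; ++j)
      if (firing[j] && std::fabs(v[j] - theta) <= 1e-10 &&
          (i_cur[j] - v[j]) > 0.0)
        crossers.push_back(j);
    // any cached crossing at or before the current time is now stale
    // (either consumed above or invalidated by a coincident input)
    for (int j = 0; j < n; ++j)
      if (std::isfinite(cross_t[j]) && cross_t[j] <= t) dirty[j] = true;
    if (!crossers.empty()) {
      std::vector<double> i_pre(i_cur);
      for (size_t s = 0; s < crossers.size(); ++s) {
        int nn = crossers[s];
        double im = i_pre[nn];
        double vd = (-theta + im) / tau_mem;
        if (std::fabs(vd) < 1e-8) ++n_crit;
        v[nn] = 0.0;
        for (size_t k = 0; k < rec_targets[nn].size(); ++k) {
          int j = rec_targets[nn][k];
          i_cur[j] += w_rec(j, nn);
          dirty[j] = true;
        }
        dirty[nn] = true;  // reset invalidates its own cache
        rec_t.push_back(t);
        rec_n.push_back(nn);
        rec_im.push_back(im);
        rec_vd.push_back(vd);
      }
      if ((double)rec_t.size() > spike_cap)
        stop("spike cap exceeded: runaway activity (%d spikes)",
             (int)rec_t.size());
      any_event = true;
    }

    if (record_traj && (any_event || t >= t_end)) {
      traj_t.push_back(t);
      for (int j = 0; j < n; ++j) {
        traj_v.push_back(v[j]);
        traj_i.push_back(i_cur[j]);
      }
    }

    if (t >= t_end) break;
  }

  int ne = traj_t.size();
  NumericMatrix tv(ne, n), ti(ne, n);
  if (record_traj) {
    for (int r = 0; r < ne; ++r)
      for (int j = 0; j < n; ++j) {
        tv(r, j) = traj_v[(size_t)r * n + j];
        ti(r, j) = traj_i[(size_t)r * n + j];
      }
  }

  return List::create(
      _["times"] = NumericVector(rec_t.begin(), rec_t.end()),
      _["neurons"] = IntegerVector(rec_n.begin(), rec_n.end()),
      _["i_minus"] = NumericVector(rec_im.begin(), rec_im.end()),
      _["vdot_minus"] = NumericVector(rec_vd.begin(), rec_vd.end()),
      _["traj_times"] = NumericVector(traj_t.begin(), traj_t.end()),
      _["traj_v"] = tv, _["traj_i"] = ti,
      _["v_end"] = NumericVector(v.begin(), v.end()),
      _["i_end"] = NumericVector(i_cur.begin(), i_cur.end()),
      _["n_crit"] = n_crit);
}

// Reverse sweep of the merged event queue. Adjoint free dynamics in
// reverse time s = T - t:
//   d lambda_V / ds = -lambda_V / tau_mem
//   d lambda_I / ds = (-lambda_I + lambda_V) / tau_syn
// Closed form over a reverse step ds:
//   lambda_V(ds) = lV0 e^{-ds/tau_mem}
//   lambda_I(ds) = (lI0 - k) e^{-ds/tau_syn} + k e^{-ds/tau_mem},
//   k = lV0 * tau_mem / (tau_mem - tau_syn).
//
// Event types, processed at equal times in this order (the reverse of the
// forward order, with voltage-loss jumps scheduled first):
//   0 = voltage-loss jump (lambda_V[n] += mag)
//   1 = recurrent spike k (adjoint jump of the firing neuron + gradient
//       accumulation g_rec[, n] -= tau_syn * lambda_I)
//   2 = input spike (g_in[, c] -= tau_syn * lambda_I)
// Coincident recurrent spikes use lambda values cached before any of the
// coincident jumps (independent application).
// [[Rcpp::export]]
List cpp_backward(NumericMatrix w_rec, NumericMatrix w_in,
                  double tau_mem, double tau_syn, double theta,
                  double t_end,
                  NumericVector sp_times, IntegerVector sp_neuron,
                  NumericVector sp_vdot, NumericVector dlp,
                  NumericVector in_times, IntegerVector in_chan,
                  NumericVector vj_times, IntegerVector vj_neuron,
                  NumericVector vj_mag,
                  bool keep_lambda) {
  const int n = w_rec.nrow();
  const int n_sp = sp_times.size();
  const int n_in = in_times.size();
  const int n_vj = vj_times.size();

  struct Ev { double t; int type; int idx; };
  std::vector<Ev> evs;
  evs.reserve(n_sp + n_in + n_vj);
  for (int k = 0; k < n_vj; ++k) evs.push_back({vj_times[k], 0, k});
  for (int k = 0; k < n_sp; ++k) evs.push_back({sp_times[k], 1, k});
  for (int k = 0; k < n_in; ++k) evs.push_back({in_times[k], 2, k});
  // descending time; ties: vjumps first, then spikes in descending neuron
  // index, then inputs
  std::stable_sort(evs.begin(), evs.end(), [&](const Ev& a, const Ev& b) {
    if (a.t != b.t) return a.t > b.t;
    if (a.type != b.type) return a.type < b.type;
    if (a.type == 1) return sp_neuron[a.idx] > sp_neuron[b.idx];
    return false;
  });

  std::vector<double> lV(n, 0.0), lI(n, 0.0);
  double t = t_end;
  NumericMatrix g_rec(n, n), g_in(n, w_in.ncol());
  const double kfac = tau_mem / (tau_mem - tau_syn);

  NumericMatrix lV_pre, lV_post, lI_pre, lI_post;
  if (keep_lambda) {
    lV_pre = NumericMatrix(n_sp, n); lV_post = NumericMatrix(n_sp, n);
    lI_pre = NumericMatrix(n_sp, n); lI_post = NumericMatrix(n_sp, n);
  }

  size_t e = 0;
  while (e < evs.size()) {
    double te = evs[e].t;
    // evolve adjoints backward from t to te
    double ds = t - te;
    if (ds > 0) {
      double em = std::exp(-ds / tau_mem), es = std::exp(-ds / tau_syn);
      for (int j = 0; j < n; ++j) {
        double k = lV[j] * kfac;
        lI[j] = (lI[j] - k) * es + k * em;
        lV[j] = lV[j] * em;
      }
      t = te;
    }

    // voltage-loss jumps at te
    while (e < evs.size() && evs[e].t == te && evs[e].type == 0) {
      lV[vj_neuron[evs[e].idx]] += vj_mag[evs[e].idx];
      ++e;
    }

    // coincident recurrent spikes at te: collect, then jump independently
    size_t first_sp = e;
    while (e < evs.size() && evs[e].t == te && evs[e].type == 1) ++e;
    if (e > first_sp) {
      std::vector<double> lV_plus(lV), lI_now(lI);
      for (size_t s = first_sp; s < e; ++s) {
        int k = evs[s].idx;
        int nn = sp_neuron[k];
        if (keep_lambda)
          for (int j = 0; j < n; ++j) {
            lV_pre(k, j) = lV_plus[j];  // "+" side (later forward time)
            lI_pre(k, j) = lI_now[j];
          }
        // gradient: spike from nn transmitted across column nn of w_rec
        // (the diagonal is not a parameter: no self-connections)
        for (int j = 0; j < n; ++j)
          if (j != nn) g_rec(j, nn) -= tau_syn * lI_now[j];
        // adjoint jump of the firing neuron (all other components and all
        // of lambda_I are continuous)
        double dot = 0.0;
        for (int mrow = 0; mrow < n; ++mrow)
          dot += w_rec(mrow, nn) * (lV_plus[mrow] - lI_now[mrow]);
        double jump = (theta * lV_plus[nn] + dot + dlp[k]) /
                      (tau_mem * sp_vdot[k]);
        lV[nn] = lV_plus[nn] + jump;
        if (keep_lambda)
          for (int j = 0; j < n; ++j) {
            lV_post(k, j) = lV[j];
            lI_post(k, j) = lI_now[j];
          }
      }
    }

    // input spikes at te
    while (e < evs.size() && evs[e].t == te && evs[e].type == 2) {
      int c = in_chan[evs[e].idx];
      for (int j = 0; j < n; ++j)
        g_in(j, c) -= tau_syn * lI[j];
      ++e;
    }
  }

  // evolve to t = 0 (no observable effect, but completes the sweep)
  if (t > 0) {
    double em = std::exp(-t / tau_mem), es = std::exp(-t / tau_syn);
    for (int j = 0; j < n; ++j) {
      double k = lV[j] * kfac;
      lI[j] = (lI[j] - k) * es + k * em;
      lV[j] = lV[j] * em;
    }
  }

  List out = List::create(
      _["g_rec"] = g_rec, _["g_in"] = g_in,
      _["lambda_v0"] = NumericVector(lV.begin(), lV.end()),
      _["lambda_i0"] = NumericVector(lI.begin(), lI.end()));
  if (keep_lambda) {
    out["lambda_v_pre"] = lV_pre; out["lambda_v_post"] = lV_post;
    out["lambda_i_pre"] = lI_pre; out["lambda_i_post"] = lI_post;
  }
  return out;
}
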