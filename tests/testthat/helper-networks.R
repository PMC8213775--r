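# Fixture builders used across the suite. All are deterministic in `seed`.

# Random small recurrent network (n firing neurons, m input channels) with
# weights scaled so that activity is present but bounded.
random_recurrent_net <- function(seed, n = 3, m = 2, t_end = 40) {
  set.seed(seed)
  w_rec <- matrix(rnorm(n * n, 0.4, 0.5), n, n)
  diag(w_rec) <- 0
  w_in <- matrix(rnorm(n * m, 2.5, 1.2), n, m)
  cfg <- lif_config(w_rec, w_in, t_end = t_end)
  inputs <- spike_train(runif(2 * m, 0, t_end / 2), sample(m, 2 * m, TRUE))
  list(cfg = cfg, inputs = inputs)
}

# Two-layer feed-forward net with firing outputs (spike-time readout).
# Weights are strong enough that hidden and output layers both fire for the
# standard encoded inputs.
ttfs_toy_net <- function(seed, n_hidden = 4, t_end = 60) {
  set.seed(seed)
  w_h <- matrix(rnorm(n_hidden * 5, 2.5, 0.8), n_hidden, 5)
  w_o <- matrix(rnorm(3 * n_hidden, 3.0, 0.5), 3, n_hidden)
  snn_classifier(w_h, w_o, readout_firing = TRUE, t_end = t_end)
}

# Two-layer net with non-firing voltage readouts.
vmax_toy_net <- function(seed, n_hidden = 3, n_class = 3, n_in = 3,
                         t_end = 60) {
  set.seed(seed)
  w_h <- matrix(rnorm(n_hidden * n_in, 4, 1.2), n_hidden, n_in)
  w_o <- matrix(rnorm(n_class * n_hidden, 1, 0.5), n_class, n_hidden)
  snn_classifier(w_h, w_o, readout_firing = FALSE, t_end = t_end)
}

# A generic input pattern on `m` channels.
toy_inputs <- function(seed, m, t_max = 25, n_spikes = max(3, m)) {
  set.seed(seed + 1000)
  spike_train(runif(n_spikes, 0, t_max), sample(m, n_spikes, TRUE))
}

# Independent re-implementation of the adjoint spike jump, term by term
# (used as the oracle for apply_adjoint_spike_jump): the firing neuron's
# new lambda_V is
#   (Vdot+/Vdot-) lambda_V+  +  [sum_{m} w_{mn}(lambda_V+ - lambda_I)_m
#                                + dlp] / (tau_mem Vdot-)
# with Vdot+/Vdot- = theta/(tau_mem Vdot-) + 1.
adjoint_jump_reference <- function(lv, li, n, vdot_minus, dlp, cfg) {
  factor <- cfg$threshold / (cfg$tau_mem * vdot_minus) + 1
  wsum <- 0
  for (mm in seq_len(cfg$n))
    if (mm != n) wsum <- wsum + cfg$w_rec[mm, n] * (lv[mm] - li[mm])
  lv_new <- lv
  lv_new[n] <- factor * lv[n] + (wsum + dlp) / (cfg$tau_mem * vdot_minus)
  lv_new
}

# Dense closed-form scan of one neuron's free membrane potential.
dense_v_scan <- function(v0, i0, cfg, t_hi, dt = 1e-5) {
  tt <- seq(0, t_hi, by = dt)
  em <- exp(-tt / cfg$tau_mem)
  es <- exp(-tt / cfg$tau_syn)
  cc <- i0 * cfg$tau_syn / (cfg$tau_syn - cfg$tau_mem)
  list(t = tt, v = (v0 - cc) * em + cc * es)
}
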