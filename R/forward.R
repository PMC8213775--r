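#' Exact free evolution of the LIF state
#'
#' Advances membrane potentials and synaptic currents by `dt` using the
#' closed-form solution of the free dynamics: `I` decays as a single
#' exponential with `tau_syn`, and `V` follows the double-exponential
#' solution of the driven leak equation. There is no time-stepping error.
#'
#' @param v,i Numeric vectors of membrane potentials and synaptic currents.
#' @param dt Time step (ms), `dt >= 0`.
#' @param cfg An [lif_config()] (only the time constants are used).
#' @return A list with updated `v` and `i`.
#' @examples
#' cfg <- lif_config(matrix(0, 1, 1), matrix(1, 1, 1))
#' evolve_free(1, 0, cfg$tau_mem, cfg)$v  # exp(-1)
#' @export
evolve_free <- function(v, i, dt, cfg) {
  stopifnot(dt >= 0)
  if (cfg$tau_mem == cfg$tau_syn)
    stop("tau_mem == tau_syn is unsupported")
  if (dt == 0) return(list(v = v, i = i))
  em <- exp(-dt / cfg$tau_mem)
  es <- exp(-dt / cfg$tau_syn)
  cc <- i * cfg$tau_syn / (cfg$tau_syn - cfg$tau_mem)
  list(v = (v - cc) * em + cc * es, i = i * es)
}

# membrane potential of one neuron dt ahead, closed form (internal)
v_closed <- function(v0, i0, dt, tau_mem, tau_syn) {
  cc <- i0 * tau_syn / (tau_syn - tau_mem)
  (v0 - cc) * exp(-dt / tau_mem) + cc * exp(-dt / tau_syn)
}

#' Earliest threshold crossing of the free dynamics
#'
#' Finds the earliest time in `(t, horizon]` at which some firing neuron's
#' closed-form membrane potential reaches the threshold from below with
#' positive slope. A bracket is declared only on a sign change of
#' `V - threshold` on a grid of step `cfg$grid`; tangential touches (the
#' membrane peaking exactly at threshold) are treated as non-crossings,
#' consistent with the transition condition requiring nonzero slope. The
#' bracketed root is refined by bisection to near machine precision.
#'
#' @param v,i State vectors at time `t`.
#' @param t Current time (ms).
#' @param horizon Absolute time up to which to search (ms).
#' @param cfg An [lif_config()].
#' @return `NULL` if no crossing occurs, else `list(time =, neuron =)`.
#'   Simultaneous crossings resolve to the lowest neuron index.
#' @export
next_threshold_crossing <- function(v, i, t, horizon, cfg) {
  if (horizon <= t) return(NULL)
  best_t <- Inf
  best_n <- NA_integer_
  for (n in seq_len(cfg$n)) {
    if (!cfg$firing[n]) next
    tc <- crossing_time_1(v[n], i[n], horizon - t, cfg)
    if (!is.na(tc) && t + tc < best_t) {
      best_t <- t + tc
      best_n <- n
    }
  }
  if (is.finite(best_t)) list(time = best_t, neuron = best_n) else NULL
}

# first up-crossing of threshold for one neuron within (0, span]; NA if none
crossing_time_1 <- function(v0, i0, span, cfg) {
  f <- function(dt) v_closed(v0, i0, dt, cfg$tau_mem, cfg$tau_syn) - cfg$threshold
  step <- cfg$grid
  a <- 0
  fa <- f(0)
  repeat {
    b <- min(a + step, span)
    fb <- f(b)
    if (fa < 0 && fb > 0) {
      # bisect to ~machine precision
      for (k in 1:100) {
        mid <- 0.5 * (a + b)
        if (mid == a || mid == b) break
        if (f(mid) > 0) b <- mid else a <- mid
      }
      return(0.5 * (a + b))
    }
    if (b >= span) return(NA_real_)
    a <- b
    fa <- fb
  }
}

#' Spike transition of the hybrid LIF system
#'
#' Applies the discrete state transition caused by a spike of neuron `n`:
#' the firing neuron's potential is reset to zero and every neuron's
#' synaptic current jumps by the corresponding entry of column `n` of the
#' recurrent weight matrix. When several neurons cross at the identical
#' time the transitions commute (currents simply add), so they may be
#' applied in any order.
#'
#' @param v,i State vectors at the spike time (with `v[n]` at threshold).
#' @param n Index of the firing neuron.
#' @param cfg An [lif_config()].
#' @return `list(v, i, vdot_minus, i_minus)` where `i_minus` is the firing
#'   neuron's current just before the jump and
#'   `vdot_minus = (-threshold + i_minus)/tau_mem` is the pre-reset slope.
#'   Emits a warning when `|vdot_minus| < cfg$eps_crit` (near-critical
#'   point; the adjoint jump would diverge).
#' @export
apply_spike_transition <- function(v, i, n, cfg) {
  i_minus <- i[n]
  vdot_minus <- (-cfg$threshold + i_minus) / cfg$tau_mem
  if (abs(vdot_minus) < cfg$eps_crit)
    warning(sprintf("near-critical spike of neuron %d: |dV/dt| = %g", n,
                    abs(vdot_minus)))
  v[n] <- 0
  i <- i + cfg$w_rec[, n]
  list(v = v, i = i, vdot_minus = vdot_minus, i_minus = i_minus)
}

#' Input spike transition
#'
#' A fixed pre-synaptic spike on input channel `channel` adds column
#' `channel` of the input weight matrix to the synaptic currents; membrane
#' potentials are unchanged. Simultaneous spikes on the same channel add.
#'
#' @param v,i State vectors.
#' @param channel Input channel index (1-based).
#' @param cfg An [lif_config()].
#' @return `list(v, i)`.
#' @export
apply_input_spike <- function(v, i, channel, cfg) {
  stopifnot(channel >= 1, channel <= cfg$m)
  list(v = v, i = i + cfg$w_in[, channel])
}

#' Event-driven simulation of a LIF network
#'
#' Runs the hybrid system from the parameter-independent initial condition
#' `V = I = 0` at `t = 0` to `t = t_end`, processing a merged queue of input
#' spikes and detected threshold crossings in time order. Events at
#' numerically equal times are processed input-spikes-first, then threshold
#' crossings in ascending neuron index (the current jumps commute, so the
#' state is order-independent; the rule makes replay deterministic).
#'
#' Every recorded spike caches the firing neuron's synaptic current just
#' before the reset and the pre-reset slope `vdot_minus`; together with the
#' spike times this is all the backward pass needs (memory scales with the
#' number of spikes, not with a dense state history).
#'
#' @param cfg An [lif_config()].
#' @param inputs A [spike_train()] (input spike times must lie in
#'   `[0, t_end]`).
#' @param record_trajectory If `TRUE`, additionally store the state at every
#'   event boundary so that `V`, `I` can be reconstructed anywhere in
#'   `[0, t_end]` (needed by voltage-based losses and plotting).
#' @param engine `"cpp"` (default, compiled event loop) or `"r"` (pure-R
#'   reference composed from [evolve_free()], [next_threshold_crossing()],
#'   [apply_spike_transition()] and [apply_input_spike()]; identical
#'   semantics, used for cross-checking).
#' @return An object of class `lif_sim`: list with `record` (data frame
#'   `time`, `neuron`, `i_minus`, `vdot_minus`), `trajectory` (or `NULL`),
#'   `v_end`, `i_end`, and `n_spikes`.
#' @examples
#' cfg <- lif_config(matrix(0, 1, 1), matrix(3, 1, 1), t_end = 50)
#' sim <- simulate(cfg, spike_train(0, 1))
#' sim$record
#' @export
simulate <- function(cfg, inputs = spike_train(),
                     record_trajectory = TRUE, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(cfg, "lif_config"))
  if (length(inputs$time) && any(inputs$time > cfg$t_end))
    stop("input spikes beyond the simulation horizon t_end")
  if (length(inputs$channel) && cfg$m > 0 && any(inputs$channel > cfg$m))
    stop("input channel out of range")
  if (engine == "cpp") {
    res <- cpp_simulate(cfg$w_rec, cfg$w_in, cfg$firing,
                        cfg$tau_mem, cfg$tau_syn, cfg$threshold,
                        cfg$t_end, as.numeric(inputs$time),
                        as.integer(inputs$channel) - 1L,
                        cfg$grid, cfg$spike_cap, record_trajectory)
    if (res$n_crit > 0)
      warning(sprintf("%d near-critical spike(s) (|dV/dt| < eps_crit)",
                      res$n_crit))
    record <- data.frame(time = res$times, neuron = res$neurons + 1L,
                         i_minus = res$i_minus, vdot_minus = res$vdot_minus)
    traj <- NULL
    if (record_trajectory)
      traj <- list(times = res$traj_times, v = res$traj_v, i = res$traj_i)
    out <- list(record = record, trajectory = traj,
                v_end = res$v_end, i_end = res$i_end,
                n_spikes = nrow(record))
  } else {
    out <- simulate_r(cfg, inputs, record_trajectory)
  }
  class(out) <- "lif_sim"
  out
}

#' @export
print.lif_sim <- function(x, ...) {
  cat(sprintf("<lif_sim> %d spikes", x$n_spikes))
  if (x$n_spikes > 0)
    cat(sprintf(" from %d neuron(s), t in [%.3f, %.3f] ms",
                length(unique(x$record$neuron)),
                min(x$record$time), max(x$record$time)))
  cat("\n")
  invisible(x)
}

# pure-R reference event loop (internal; same semantics as the C++ engine).
# Per event time: input spikes are applied first, then all coincident
# threshold crossings in ascending neuron index using the pre-transition
# currents (independent application; the jumps commute).
simulate_r <- function(cfg, inputs, record_trajectory) {
  v <- numeric(cfg$n)
  i <- numeric(cfg$n)
  t <- 0
  in_t <- inputs$time
  in_c <- inputs$channel
  ptr <- 1L
  rec_t <- numeric(); rec_n <- integer(); rec_im <- numeric(); rec_vd <- numeric()
  traj_t <- 0; traj_v <- list(v); traj_i <- list(i)
  repeat {
    horizon <- min(if (ptr <= length(in_t)) in_t[ptr] else Inf, cfg$t_end)
    cr <- next_threshold_crossing(v, i, t, horizon, cfg)
    t_next <- if (is.null(cr)) horizon else cr$time
    st <- evolve_free(v, i, t_next - t, cfg)
    v <- st$v; i <- st$i; t <- t_next
    while (ptr <= length(in_t) && in_t[ptr] == t) {
      st <- apply_input_spike(v, i, in_c[ptr], cfg)
      v <- st$v; i <- st$i
      ptr <- ptr + 1L
    }
    crossers <- which(cfg$firing & abs(v - cfg$threshold) <= 1e-10 &
                        (i - v) / cfg$tau_mem > 0)
    if (length(crossers)) {
      i_pre <- i
      for (nn in crossers) {  # ascending by construction of which()
        im <- i_pre[nn]
        vd <- (-cfg$threshold + im) / cfg$tau_mem
        if (abs(vd) < cfg$eps_crit)
          warning(sprintf("near-critical spike of neuron %d: |dV/dt| = %g",
                          nn, abs(vd)))
        v[nn] <- 0
        i <- i + cfg$w_rec[, nn]
        rec_t <- c(rec_t, t); rec_n <- c(rec_n, nn)
        rec_im <- c(rec_im, im); rec_vd <- c(rec_vd, vd)
      }
      if (length(rec_t) > cfg$spike_cap)
        stop("spike cap exceeded: runaway activity")
    }
    if (record_trajectory) {
      traj_t <- c(traj_t, t)
      traj_v <- c(traj_v, list(v)); traj_i <- c(traj_i, list(i))
    }
    if (t >= cfg$t_end) break
  }
  traj <- NULL
  if (record_trajectory)
    traj <- list(times = traj_t,
                 v = do.call(rbind, traj_v), i = do.call(rbind, traj_i))
  list(record = data.frame(time = rec_t, neuron = rec_n,
                           i_minus = rec_im, vdot_minus = rec_vd),
       trajectory = traj, v_end = v, i_end = i, n_spikes = length(rec_t))
}

#' Reconstruct the state anywhere along a simulated trajectory
#'
#' Uses the stored event-boundary states and the closed-form free dynamics
#' to evaluate `V(t)`, `I(t)` for any `t` in `[0, t_end]`. At an event time
#' the post-transition state is returned.
#'
#' @param sim An `lif_sim` with a recorded trajectory.
#' @param t Time (ms).
#' @param cfg The [lif_config()] used for the simulation.
#' @return `list(v, i)`.
#' @export
trajectory_state <- function(sim, t, cfg) {
  traj <- sim$trajectory
  if (is.null(traj)) stop("simulate() was run with record_trajectory = FALSE")
  stopifnot(t >= 0, t <= cfg$t_end + 1e-12)
  k <- findInterval(t, traj$times)  # last boundary <= t
  k <- max(1L, min(k, length(traj$times)))
  evolve_free(traj$v[k, ], traj$i[k, ], t - traj$times[k], cfg)
}
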