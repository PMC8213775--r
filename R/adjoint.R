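#' Exact free evolution of the adjoint state (reverse time)
#'
#' Between events the adjoint pair evolves (in reverse time, with the
#' voltage-loss density zero between events) as
#' \deqn{\tau_{mem} \lambda_V' = -\lambda_V, \qquad
#'       \tau_{syn} \lambda_I' = -\lambda_I + \lambda_V,}
#' where the prime is the reverse-time derivative. This advances the pair
#' backward in forward time by `dt` with the exact closed form of this
#' linear system: `lambda_V` decays with `tau_mem` and drives `lambda_I`.
#'
#' @param lv,li Adjoint vectors at forward time `t`.
#' @param dt Reverse step (ms), `dt >= 0`; the result is the state at
#'   forward time `t - dt`.
#' @param cfg An [lif_config()].
#' @return `list(lv, li)`.
#' @export
adjoint_evolve_free <- function(lv, li, dt, cfg) {
  stopifnot(dt >= 0)
  if (cfg$tau_mem == cfg$tau_syn)
    stop("tau_mem == tau_syn is unsupported")
  if (dt == 0) return(list(lv = lv, li = li))
  em <- exp(-dt / cfg$tau_mem)
  es <- exp(-dt / cfg$tau_syn)
  k <- lv * cfg$tau_mem / (cfg$tau_mem - cfg$tau_syn)
  list(lv = lv * em, li = (li - k) * es + k * em)
}

#' Adjoint jump at a recorded spike
#'
#' During the reverse sweep, the firing neuron's `lambda_V` jumps at its
#' spike time:
#' \deqn{(\lambda_V^-)_n = (\lambda_V^+)_n +
#'   \frac{1}{\tau_{mem} \dot V^-}\left[\vartheta (\lambda_V^+)_n +
#'   (W^\top(\lambda_V^+ - \lambda_I))_n + \partial l_p/\partial t^{post}_k
#'   \right],}
#' using the pre-reset slope `vdot_minus` cached by the forward pass. All
#' other components of `lambda_V`, and all of `lambda_I`, are continuous
#' across the event. (The voltage-loss boundary term vanishes here: both
#' supported loss heads have `l_V` continuous at recurrent spikes.)
#'
#' @param lv,li Adjoint vectors at the spike time (the "+" side, i.e. the
#'   values already computed for later forward times).
#' @param event One row of a simulation's `record` (fields `neuron`,
#'   `vdot_minus`).
#' @param dlp Sensitivity of the spike-time loss to this spike's time,
#'   `d l_p / d t_post` (0 if the loss does not use this spike).
#' @param cfg An [lif_config()].
#' @return `list(lv, li)` on the "-" side (earlier forward times).
#' @export
apply_adjoint_spike_jump <- function(lv, li, event, dlp, cfg) {
  n <- event$neuron
  vd <- event$vdot_minus
  if (abs(vd) < cfg$eps_crit)
    warning(sprintf("adjoint jump at a near-critical spike of neuron %d", n))
  err <- cfg$threshold * lv[n] +
    sum(cfg$w_rec[, n] * (lv - li)) + dlp
  lv[n] <- lv[n] + err / (cfg$tau_mem * vd)
  list(lv = lv, li = li)
}

#' Voltage-loss jump of the adjoint membrane variable
#'
#' A loss term sampling a membrane potential at a discrete time (a Dirac
#' delta in the voltage-loss density) causes `lambda_V` of that neuron to
#' jump by `magnitude` when the reverse sweep crosses the sampling time; a
#' unit delta contributes `1/tau_mem`, and loss heads supply
#' `magnitude = (dl/dV) / tau_mem`.
#'
#' @param lv Adjoint membrane vector.
#' @param neuron Neuron index.
#' @param magnitude Jump size.
#' @return Updated `lv`.
#' @export
apply_voltage_loss_jump <- function(lv, neuron, magnitude) {
  lv[neuron] <- lv[neuron] + magnitude
  lv
}

#' Accumulate the weight gradient at an event
#'
#' The gradient of the total loss with respect to a weight is
#' `-tau_syn * sum(lambda_I of the postsynaptic neuron at the spike times
#' transmitted across that weight)`. For a recurrent spike of neuron `i`
#' this updates column `i` of `g_rec` for every postsynaptic neuron; for a
#' fixed input spike on channel `c` it updates column `c` of `g_in`.
#'
#' @param acc `list(g_rec, g_in)` gradient accumulator.
#' @param type `"spike"` or `"input"`.
#' @param index Firing neuron (for `"spike"`) or input channel (for
#'   `"input"`).
#' @param li Adjoint current vector at the event time.
#' @param cfg An [lif_config()].
#' @return Updated accumulator.
#' @export
accumulate_gradient <- function(acc, type = c("spike", "input"), index, li,
                                cfg) {
  type <- match.arg(type)
  if (type == "spike") {
    # the diagonal is not a parameter (no self-connections)
    upd <- cfg$tau_syn * li
    upd[index] <- 0
    acc$g_rec[, index] <- acc$g_rec[, index] - upd
  } else {
    acc$g_in[, index] <- acc$g_in[, index] - cfg$tau_syn * li
  }
  acc
}

#' Exact loss gradient via the reverse event sweep
#'
#' Runs the event-driven forward pass, evaluates the loss head, then sweeps
#' the merged event queue (recurrent spikes, input spikes, voltage-loss jump
#' times) in reverse, interleaving the closed-form adjoint evolution, the
#' per-spike adjoint jumps, voltage-loss jumps, and gradient accumulation.
#' Only the spike record and the loss jump schedule are consumed — never a
#' dense state history — so backward memory scales with the number of
#' spikes.
#'
#' @param cfg An [lif_config()].
#' @param inputs A [spike_train()].
#' @param head A loss head (see [ttfs_head()], [max_voltage_head()],
#'   [spike_sum_head()]).
#' @param engine `"cpp"` (compiled sweep) or `"r"` (pure-R reference built
#'   from the exported adjoint operations).
#' @param keep_lambda If `TRUE`, also return the adjoint vectors immediately
#'   before and after every spike jump (diagnostics/testing).
#' @return List with `loss`, `g_rec`, `g_in` (shapes matching the weight
#'   matrices; the `g_rec` diagonal is exactly zero), the loss head's
#'   `aux` output (e.g. first-spike times), and `n_spikes`.
#' @examples
#' cfg <- lif_config(matrix(0, 1, 1), matrix(3, 1, 1), t_end = 50)
#' g <- eventprop_gradient(cfg, spike_train(0, 1), spike_sum_head(1))
#' g$loss; g$g_in
#' @export
eventprop_gradient <- function(cfg, inputs, head,
                               engine = c("cpp", "r"), keep_lambda = FALSE) {
  engine <- match.arg(engine)
  sim <- simulate(cfg, inputs,
                  record_trajectory = needs_trajectory(head), engine = engine)
  sens <- loss_sensitivities(head, sim, cfg)
  bw <- backward_sweep(cfg, inputs, sim, sens, engine, keep_lambda)
  c(list(loss = sens$value, aux = sens$aux, n_spikes = sim$n_spikes), bw)
}

# dispatch the reverse sweep (internal)
backward_sweep <- function(cfg, inputs, sim, sens, engine = "cpp",
                           keep_lambda = FALSE) {
  rec <- sim$record
  vj <- sens$voltage_jumps
  if (is.null(vj)) vj <- data.frame(time = numeric(), neuron = integer(),
                                    magnitude = numeric())
  dlp <- sens$dlp
  if (is.null(dlp)) dlp <- numeric(nrow(rec))
  stopifnot(length(dlp) == nrow(rec))
  if (engine == "cpp") {
    res <- cpp_backward(cfg$w_rec, cfg$w_in, cfg$tau_mem, cfg$tau_syn,
                        cfg$threshold, cfg$t_end,
                        rec$time, as.integer(rec$neuron) - 1L,
                        rec$vdot_minus, dlp,
                        as.numeric(inputs$time),
                        as.integer(inputs$channel) - 1L,
                        as.numeric(vj$time), as.integer(vj$neuron) - 1L,
                        as.numeric(vj$magnitude), keep_lambda)
    out <- list(g_rec = res$g_rec, g_in = res$g_in,
                lambda_v0 = res$lambda_v0, lambda_i0 = res$lambda_i0)
    if (keep_lambda)
      out <- c(out, res[c("lambda_v_pre", "lambda_v_post",
                          "lambda_i_pre", "lambda_i_post")])
    out
  } else {
    backward_sweep_r(cfg, inputs, sim, dlp, vj, keep_lambda)
  }
}

# pure-R reference reverse sweep, composed from the exported operations
backward_sweep_r <- function(cfg, inputs, sim, dlp, vj, keep_lambda = FALSE) {
  rec <- sim$record
  n_sp <- nrow(rec)
  ev <- rbind(
    if (nrow(vj)) data.frame(time = vj$time, type = 0L, idx = seq_len(nrow(vj))),
    if (n_sp) data.frame(time = rec$time, type = 1L, idx = seq_len(n_sp)),
    if (length(inputs$time))
      data.frame(time = inputs$time, type = 2L, idx = seq_along(inputs$time)))
  acc <- list(g_rec = matrix(0, cfg$n, cfg$n), g_in = matrix(0, cfg$n, cfg$m))
  lv <- numeric(cfg$n)  # boundary condition lambda(T) = 0
  li <- numeric(cfg$n)
  lam <- NULL
  if (keep_lambda)
    lam <- list(lambda_v_pre = matrix(0, n_sp, cfg$n),
                lambda_v_post = matrix(0, n_sp, cfg$n),
                lambda_i_pre = matrix(0, n_sp, cfg$n),
                lambda_i_post = matrix(0, n_sp, cfg$n))
  t <- cfg$t_end
  if (!is.null(ev) && nrow(ev)) {
    # reverse of the forward order: vjumps first, then spikes (descending
    # neuron index), then inputs
    key_n <- ifelse(ev$type == 1L, -rec$neuron[ev$idx], 0)
    o <- order(-ev$time, ev$type, key_n)
    ev <- ev[o, ]
    k <- 1L
    while (k <= nrow(ev)) {
      te <- ev$time[k]
      st <- adjoint_evolve_free(lv, li, t - te, cfg)
      lv <- st$lv; li <- st$li; t <- te
      # all spike jumps at this instant use the pre-jump lambda_V
      sp_here <- ev$idx[ev$time == te & ev$type == 1L]
      lv_plus <- lv
      while (k <= nrow(ev) && ev$time[k] == te) {
        type <- ev$type[k]; idx <- ev$idx[k]
        if (type == 0L) {
          lv <- apply_voltage_loss_jump(lv, vj$neuron[idx], vj$magnitude[idx])
          lv_plus <- lv
        } else if (type == 1L) {
          evt <- rec[idx, ]
          if (keep_lambda) {
            lam$lambda_v_pre[idx, ] <- lv_plus
            lam$lambda_i_pre[idx, ] <- li
          }
          acc <- accumulate_gradient(acc, "spike", evt$neuron, li, cfg)
          st <- apply_adjoint_spike_jump(lv_plus, li, evt, dlp[idx], cfg)
          lv[evt$neuron] <- st$lv[evt$neuron]
          if (keep_lambda) {
            lam$lambda_v_post[idx, ] <- lv
            lam$lambda_i_post[idx, ] <- li
          }
        } else {
          acc <- accumulate_gradient(acc, "input", inputs$channel[idx], li, cfg)
        }
        k <- k + 1L
      }
    }
  }
  st <- adjoint_evolve_free(lv, li, t, cfg)
  c(list(g_rec = acc$g_rec, g_in = acc$g_in,
         lambda_v0 = st$lv, lambda_i0 = st$li), lam)
}
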