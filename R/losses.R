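#' Loss heads
#'
#' A loss head evaluates a scalar loss from a forward simulation and
#' produces the sensitivities the backward pass consumes: a per-spike-event
#' derivative `d l_p / d t_post` and/or a schedule of voltage-loss jumps of
#' `lambda_V`. Three heads are provided:
#'
#' * `ttfs_head()` — first-spike-time cross-entropy with an exponential
#'   earliness regularizer: per sample
#'   \deqn{l = -\log \mathrm{softmax}(-t^{post}/\tau_0)_{label} +
#'         \alpha\,(e^{t^{post}_{label}/\tau_1} - 1),}
#'   averaged over the batch (the `1/N_batch` factor lives in the head via
#'   `n_batch`). The class assignment is the neuron with the earliest first
#'   spike. A neuron that never fires enters the softmax as
#'   `exp(-Inf) = 0` and receives no spike-time sensitivity; a sample whose
#'   *label* neuron is silent contributes the constant `missing_penalty`
#'   and zero gradient (flagged in the returned `aux`) — a documented
#'   heuristic for early-training quiescence, which non-quiescent
#'   initialization is meant to avoid.
#' * `max_voltage_head()` — cross-entropy over the softmax of each
#'   non-firing readout neuron's maximum-over-time membrane potential. The
#'   time of each maximum becomes a voltage-loss jump of `lambda_V` during
#'   the backward sweep, of size `(1[k = label] - softmax_k)/(tau_mem *
#'   n_batch)` (the sign is the backward-sweep convention: written forward
#'   in time the adjoint jump has the opposite sign).
#' * `spike_sum_head()` — weighted sum of all spike times of selected
#'   neurons, the classic gradient-verification loss.
#'
#' @param output_neurons,readout_neurons,neurons Ordered neuron indices
#'   (one per class for the classification heads).
#' @param label Correct class index (into `output_neurons` /
#'   `readout_neurons`), 1-based.
#' @param tau0 Softmax time constant (ms).
#' @param tau1 Regularizer time constant (ms).
#' @param alpha Regularization factor (dimensionless, `>= 0`).
#' @param n_batch Batch size the per-sample loss is averaged over.
#' @param missing_penalty Constant loss contributed by a sample whose label
#'   neuron never spikes.
#' @param weights Per-neuron coefficients for `spike_sum_head`.
#' @return A loss head object.
#' @name loss_heads
NULL

#' @rdname loss_heads
#' @export
ttfs_head <- function(output_neurons, label, tau0 = 0.5, tau1 = 6.4,
                      alpha = 3e-3, n_batch = 1, missing_penalty = 100) {
  stopifnot(tau0 > 0, tau1 > 0, alpha >= 0,
            label >= 1, label <= length(output_neurons))
  structure(list(output_neurons = as.integer(output_neurons),
                 label = as.integer(label), tau0 = tau0, tau1 = tau1,
                 alpha = alpha, n_batch = n_batch,
                 missing_penalty = missing_penalty),
            class = c("ttfs_head", "loss_head"))
}

#' @rdname loss_heads
#' @export
max_voltage_head <- function(readout_neurons, label, n_batch = 1) {
  stopifnot(label >= 1, label <= length(readout_neurons))
  structure(list(readout_neurons = as.integer(readout_neurons),
                 label = as.integer(label), n_batch = n_batch),
            class = c("max_voltage_head", "loss_head"))
}

#' @rdname loss_heads
#' @export
spike_sum_head <- function(neurons, weights = rep(1, length(neurons))) {
  stopifnot(length(neurons) == length(weights))
  structure(list(neurons = as.integer(neurons), weights = weights),
            class = c("spike_sum_head", "loss_head"))
}

#' Loss value and sensitivities from a forward simulation
#'
#' @param head A loss head.
#' @param sim An `lif_sim` from [simulate()].
#' @param cfg The [lif_config()] used.
#' @return List with `value`, `dlp` (per spike event), `voltage_jumps`
#'   (data frame `time`, `neuron`, `magnitude`), and head-specific `aux`.
#' @export
loss_sensitivities <- function(head, sim, cfg) UseMethod("loss_sensitivities")

# does the head need the reconstructed trajectory? (internal generic)
needs_trajectory <- function(head) UseMethod("needs_trajectory")

#' @export
needs_trajectory.loss_head <- function(head) FALSE

#' @export
needs_trajectory.max_voltage_head <- function(head) TRUE

#' First spike time per listed neuron
#'
#' @param record The `record` data frame of an `lif_sim`.
#' @param neurons Neuron indices.
#' @return Numeric vector of earliest spike times (ms), `NA` for neurons
#'   that never fired.
#' @export
first_spike_times <- function(record, neurons) {
  vapply(neurons, function(n) {
    tt <- record$time[record$neuron == n]
    if (length(tt)) min(tt) else NA_real_
  }, numeric(1))
}

#' First-spike-time cross-entropy loss (pure function)
#'
#' Evaluates the TTFS loss and its analytic derivative with respect to each
#' class's first spike time, given the table of first spike times.
#'
#' @param times First spike times per class (`NA` = silent neuron).
#' @param label Correct class index.
#' @param tau0,tau1,alpha,n_batch,missing_penalty See [ttfs_head()].
#' @return List with `value`, `grad` (same length as `times`; `NA` entries
#'   get zero), and `label_missing`.
#' @export
ttfs_loss <- function(times, label, tau0 = 0.5, tau1 = 6.4, alpha = 3e-3,
                      n_batch = 1, missing_penalty = 100) {
  k <- length(times)
  grad <- numeric(k)
  if (is.na(times[label]))
    return(list(value = missing_penalty / n_batch, grad = grad,
                label_missing = TRUE))
  z <- ifelse(is.na(times), -Inf, -times / tau0)
  zmax <- max(z)
  p <- exp(z - zmax)
  p <- p / sum(p)
  value <- -(z[label] - zmax - log(sum(exp(z - zmax)))) +
    alpha * (exp(times[label] / tau1) - 1)
  present <- !is.na(times)
  grad[present] <- (ifelse(seq_len(k) == label, 1, 0)[present] -
                      p[present]) / tau0
  grad[label] <- grad[label] + alpha / tau1 * exp(times[label] / tau1)
  list(value = value / n_batch, grad = grad / n_batch, label_missing = FALSE)
}

#' @export
loss_sensitivities.ttfs_head <- function(head, sim, cfg) {
  rec <- sim$record
  times <- first_spike_times(rec, head$output_neurons)
  ls <- ttfs_loss(times, head$label, head$tau0, head$tau1, head$alpha,
                  head$n_batch, head$missing_penalty)
  dlp <- numeric(nrow(rec))
  for (j in seq_along(head$output_neurons)) {
    if (is.na(times[j]) || ls$grad[j] == 0) next
    # sensitivity attaches to the neuron's FIRST spike only
    idx <- which(rec$neuron == head$output_neurons[j] &
                   rec$time == times[j])[1]
    dlp[idx] <- dlp[idx] + ls$grad[j]
  }
  list(value = ls$value, dlp = dlp, voltage_jumps = NULL,
       aux = list(first_spikes = times, label_missing = ls$label_missing))
}

#' @export
loss_sensitivities.spike_sum_head <- function(head, sim, cfg) {
  rec <- sim$record
  dlp <- numeric(nrow(rec))
  value <- 0
  for (j in seq_along(head$neurons)) {
    sel <- rec$neuron == head$neurons[j]
    value <- value + head$weights[j] * sum(rec$time[sel])
    dlp[sel] <- dlp[sel] + head$weights[j]
  }
  list(value = value, dlp = dlp, voltage_jumps = NULL, aux = NULL)
}

#' Maximum of the membrane potential over the simulation
#'
#' Computes the global maximum of the closed-form `V` of one neuron over
#' `[0, t_end]` from a recorded trajectory: per inter-event segment the
#' analytic extremum of the double exponential is compared with the segment
#' endpoints, then the per-segment maxima are compared. Ties resolve to the
#' earliest time.
#'
#' @param sim An `lif_sim` with a trajectory.
#' @param neuron Neuron index (typically a non-firing readout).
#' @param cfg The [lif_config()].
#' @return `list(t_star, v_max)`.
#' @export
voltage_max <- function(sim, neuron, cfg) {
  traj <- sim$trajectory
  if (is.null(traj)) stop("simulate() was run with record_trajectory = FALSE")
  tm <- cfg$tau_mem
  ts <- cfg$tau_syn
  bt <- traj$times
  best_v <- traj$v[1, neuron]
  best_t <- bt[1]
  consider <- function(t, v) {
    if (v > best_v + 1e-15 * max(1, abs(best_v))) {
      best_v <<- v
      best_t <<- t
    }
  }
  nseg <- length(bt) - 1
  for (s in seq_len(max(nseg, 0))) {
    t0 <- bt[s]
    seg <- bt[s + 1] - t0
    v0 <- traj$v[s, neuron]
    i0 <- traj$i[s, neuron]
    cc <- i0 * ts / (ts - tm)
    a <- v0 - cc
    b <- cc
    consider(t0, v0)
    # interior extremum of A e^{-dt/tm} + B e^{-dt/ts}
    ratio <- -(a * ts) / (b * tm)
    if (is.finite(ratio) && ratio > 0 && b != 0) {
      dt_star <- log(ratio) / (1 / tm - 1 / ts)
      if (dt_star > 0 && dt_star < seg)
        consider(t0 + dt_star,
                 a * exp(-dt_star / tm) + b * exp(-dt_star / ts))
    }
  }
  # final state at t_end
  last <- length(bt)
  consider(bt[last], traj$v[last, neuron])
  list(t_star = best_t, v_max = best_v)
}

#' Max-over-time voltage cross-entropy (pure function)
#'
#' @param vmax Voltage maxima per class.
#' @param label Correct class index.
#' @param n_batch Batch size.
#' @return List with `value` and `grad` (= `d value / d vmax`, summing to
#'   zero across classes).
#' @export
max_voltage_loss <- function(vmax, label, n_batch = 1) {
  z <- vmax - max(vmax)
  p <- exp(z) / sum(exp(z))
  value <- -(z[label] - log(sum(exp(z))))
  grad <- (p - ifelse(seq_along(vmax) == label, 1, 0))
  list(value = value / n_batch, grad = grad / n_batch)
}

#' @export
loss_sensitivities.max_voltage_head <- function(head, sim, cfg) {
  ks <- head$readout_neurons
  if (any(cfg$firing[ks]))
    stop("max_voltage_head requires non-firing readout neurons")
  vm <- lapply(ks, function(n) voltage_max(sim, n, cfg))
  vmax <- vapply(vm, `[[`, numeric(1), "v_max")
  tstar <- vapply(vm, `[[`, numeric(1), "t_star")
  ls <- max_voltage_loss(vmax, head$label, head$n_batch)
  # backward-sweep jump of lambda_V at each readout's own argmax time;
  # -(dL/dV)/tau_mem in the reverse-time convention
  vj <- data.frame(time = tstar, neuron = ks,
                   magnitude = -ls$grad / cfg$tau_mem)
  list(value = ls$value, dlp = numeric(nrow(sim$record)), voltage_jumps = vj,
       aux = list(v_max = vmax, t_star = tstar))
}
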