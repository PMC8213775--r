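#' Central-difference loss gradients
#'
#' Independent oracle for the event-driven adjoint gradient: perturbs one
#' weight at a time by `+eps` / `-eps`, reruns the full event-driven forward
#' pass and loss, and forms `(L(w+eps) - L(w-eps)) / (2 eps)`.
#'
#' Finite differences are only valid where the implicit-function-theorem
#' premise holds — away from the critical points in weight space where
#' spikes appear or disappear (there the true gradient diverges). A
#' mandatory guard therefore compares the per-neuron spike counts of both
#' perturbed runs with the base run; entries where they differ are flagged
#' `critical` and must not be compared against the adjoint gradient.
#'
#' @param cfg An [lif_config()].
#' @param inputs A [spike_train()].
#' @param head A loss head.
#' @param which_rec Two-column matrix of (row, col) indices into `w_rec` to
#'   differentiate (`NULL` for none).
#' @param which_in Two-column matrix of (row, col) indices into `w_in`.
#' @param eps Perturbation size; default `1e-4 * max(|w|, 1)` per weight.
#' @return Data frame with columns `matrix` ("rec"/"in"), `row`, `col`,
#'   `fd_grad`, `critical`.
#' @export
central_difference_gradient <- function(cfg, inputs, head,
                                        which_rec = NULL, which_in = NULL,
                                        eps = NULL) {
  base_counts <- spike_counts(simulate(cfg, inputs,
                                       record_trajectory = FALSE), cfg$n)
  loss_at <- function(cfg2) {
    sim <- simulate(cfg2, inputs, record_trajectory = needs_trajectory(head))
    list(value = loss_sensitivities(head, sim, cfg2)$value,
         counts = spike_counts(sim, cfg2$n))
  }
  one <- function(mat, r, c) {
    w0 <- if (mat == "rec") cfg$w_rec[r, c] else cfg$w_in[r, c]
    e <- if (is.null(eps)) 1e-4 * max(abs(w0), 1) else eps
    perturb <- function(delta) {
      cfg2 <- cfg
      if (mat == "rec") cfg2$w_rec[r, c] <- w0 + delta
      else cfg2$w_in[r, c] <- w0 + delta
      loss_at(cfg2)
    }
    up <- perturb(e)
    dn <- perturb(-e)
    crit <- !identical(up$counts, base_counts) ||
      !identical(dn$counts, base_counts)
    data.frame(matrix = mat, row = r, col = c,
               fd_grad = (up$value - dn$value) / (2 * e), critical = crit)
  }
  out <- list()
  if (!is.null(which_rec))
    for (j in seq_len(nrow(which_rec)))
      out <- c(out, list(one("rec", which_rec[j, 1], which_rec[j, 2])))
  if (!is.null(which_in))
    for (j in seq_len(nrow(which_in)))
      out <- c(out, list(one("in", which_in[j, 1], which_in[j, 2])))
  do.call(rbind, out)
}

# per-neuron spike counts of a simulation (internal)
spike_counts <- function(sim, n) {
  tabulate(sim$record$neuron, nbins = n)
}

#' Compare adjoint and finite-difference gradients
#'
#' Runs [eventprop_gradient()] once and [central_difference_gradient()] for
#' the selected weights and tabulates both with their relative error —
#' the gradient-check report.
#'
#' @inheritParams central_difference_gradient
#' @return Data frame with columns `matrix`, `row`, `col`,
#'   `eventprop_grad`, `fd_grad`, `rel_error`, `critical`.
#' @export
gradient_check <- function(cfg, inputs, head, which_rec = NULL,
                           which_in = NULL, eps = NULL) {
  ep <- eventprop_gradient(cfg, inputs, head)
  fd <- central_difference_gradient(cfg, inputs, head, which_rec, which_in,
                                    eps)
  fd$eventprop_grad <- NA_real_
  is_rec <- fd$matrix == "rec"
  fd$eventprop_grad[is_rec] <-
    ep$g_rec[cbind(fd$row[is_rec], fd$col[is_rec])]
  fd$eventprop_grad[!is_rec] <-
    ep$g_in[cbind(fd$row[!is_rec], fd$col[!is_rec])]
  denom <- pmax(abs(fd$fd_grad), abs(fd$eventprop_grad))
  fd$rel_error <- ifelse(denom > 0,
                         abs(fd$eventprop_grad - fd$fd_grad) / denom, 0)
  fd[, c("matrix", "row", "col", "eventprop_grad", "fd_grad", "rel_error",
         "critical")]
}

#' Dense explicit-Euler forward simulation
#'
#' Discretized oracle for the event-driven simulator: explicit Euler on the
#' free dynamics with a per-step threshold test, reset, and current jumps.
#' Spike times carry an O(dt) discretization error, so agreement with the
#' event-driven engine must improve linearly as `dt` shrinks.
#'
#' @param cfg An [lif_config()].
#' @param inputs A [spike_train()].
#' @param dt Step size (ms).
#' @return Data frame with columns `time`, `neuron`.
#' @export
euler_forward <- function(cfg, inputs, dt) {
  stopifnot(dt > 0)
  n_steps <- ceiling(cfg$t_end / dt)
  v <- numeric(cfg$n)
  i <- numeric(cfg$n)
  # bin input spikes onto the grid (applied at the start of their step)
  in_step <- floor(inputs$time / dt)
  rec_t <- numeric()
  rec_n <- integer()
  for (s in seq_len(n_steps) - 1L) {
    hits <- which(in_step == s)
    for (j in hits) i <- i + cfg$w_in[, inputs$channel[j]]
    v_new <- v + dt * (-v + i) / cfg$tau_mem
    i_new <- i + dt * (-i) / cfg$tau_syn
    v <- v_new
    i <- i_new
    crossed <- which(cfg$firing & v >= cfg$threshold)
    for (nn in crossed) {
      v[nn] <- 0
      i <- i + cfg$w_rec[, nn]
      rec_t <- c(rec_t, (s + 1) * dt)
      rec_n <- c(rec_n, nn)
    }
  }
  data.frame(time = rec_t, neuron = rec_n)
}

#' Bouncing-ball hybrid system
#'
#' The canonical worked example of partial-derivative jumps at state
#' transitions: a ball dropped from height `y0` under gravity `g`,
#' inelastically reflected (`v+ = -restitution * v-`) whenever it reaches
#' the ground. Ballistic flight between impacts is closed-form and impact
#' times are solved exactly, so trajectories carry no integration error.
#'
#' @param y0 Initial height (`> 0`); initial velocity is zero.
#' @param g Gravitational acceleration.
#' @param n_bounces Number of ground impacts to simulate.
#' @param restitution Reflection coefficient.
#' @return Object of class `ball_trajectory`: list with `impacts` (data
#'   frame `time`, `v_minus`, `v_plus`), the parameters, and `t_end` (time
#'   of the last simulated impact).
#' @export
simulate_ball <- function(y0, g = 9.81, n_bounces = 3, restitution = 0.8) {
  stopifnot(y0 > 0, g > 0, n_bounces >= 1)
  t <- 0
  y <- y0
  v <- 0
  impacts <- data.frame()
  for (b in seq_len(n_bounces)) {
    # y(t + dt) = y + v dt - g dt^2 / 2 = 0, root with dt > 0
    dt_imp <- (v + sqrt(v^2 + 2 * g * y)) / g
    t <- t + dt_imp
    v_minus <- v - g * dt_imp
    v <- -restitution * v_minus
    y <- 0
    impacts <- rbind(impacts,
                     data.frame(time = t, v_minus = v_minus, v_plus = v))
  }
  structure(list(impacts = impacts, y0 = y0, g = g,
                 restitution = restitution, t_end = t),
            class = "ball_trajectory")
}

#' Evaluate a ball trajectory at a time
#'
#' @param ball A `ball_trajectory`.
#' @param t Time (`>= 0`; past the last simulated impact the flight
#'   continues ballistically).
#' @return `list(y, v)`.
#' @export
ball_state <- function(ball, t) {
  stopifnot(t >= 0)
  prev <- ball$impacts[ball$impacts$time <= t, ]
  if (nrow(prev) == 0) {
    t0 <- 0
    y0 <- ball$y0
    v0 <- 0
  } else {
    last <- prev[nrow(prev), ]
    t0 <- last$time
    y0 <- 0
    v0 <- last$v_plus
  }
  dt <- t - t0
  list(y = y0 + v0 * dt - ball$g * dt^2 / 2, v = v0 - ball$g * dt)
}

#' Finite-difference sensitivity jumps of the bouncing ball
#'
#' Estimates the partial derivatives of height, velocity, and impact time
#' with respect to the initial height `y0` by central differences, sampled
#' just before and just after the first impact, and forms the jump
#' quantities predicted by the implicit function theorem:
#' the position-derivative ratio `-restitution`, the velocity-derivative
#' jump `-restitution * dv-/dy0 - (1 + restitution) * g / v- * dy-/dy0`,
#' and the impact-time derivative `-(1/v-) * dy-/dy0`.
#'
#' @param y0,g,restitution Ball parameters.
#' @param eps Central-difference step in `y0`.
#' @param delta Time offset around the impact at which the derivatives are
#'   sampled (must exceed the impact-time shift induced by `eps`).
#' @return List with `ratio_y` (after/before ratio of `dy/dy0`),
#'   `dy_dy0_before`, `dy_dy0_after`, `dv_dy0_before`, `dv_dy0_after`,
#'   `dv_dy0_after_pred`, `dt_impact_dy0` (finite-difference), and
#'   `dt_impact_dy0_pred` (implicit-function-theorem value).
#' @export
ball_jump_derivatives <- function(y0, g = 9.81, restitution = 0.8,
                                  eps = 1e-6, delta = 1e-5) {
  base <- simulate_ball(y0, g, n_bounces = 1, restitution = restitution)
  up <- simulate_ball(y0 + eps, g, n_bounces = 1, restitution = restitution)
  dn <- simulate_ball(y0 - eps, g, n_bounces = 1, restitution = restitution)
  t_imp <- base$impacts$time[1]
  v_minus <- base$impacts$v_minus[1]
  fd <- function(t) {
    su <- ball_state(up, t)
    sd <- ball_state(dn, t)
    list(dy = (su$y - sd$y) / (2 * eps), dv = (su$v - sd$v) / (2 * eps))
  }
  before <- fd(t_imp - delta)
  after <- fd(t_imp + delta)
  dt_fd <- (up$impacts$time[1] - dn$impacts$time[1]) / (2 * eps)
  list(ratio_y = after$dy / before$dy,
       dy_dy0_before = before$dy, dy_dy0_after = after$dy,
       dv_dy0_before = before$dv, dv_dy0_after = after$dv,
       dv_dy0_after_pred = -restitution * before$dv -
         (1 + restitution) * g / v_minus * before$dy,
       dt_impact_dy0 = dt_fd,
       dt_impact_dy0_pred = -(1 / v_minus) * before$dy)
}
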