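cfg1 <- lif_config(matrix(0, 1, 1), matrix(1, 1, 1), t_end = 100)

test_that("free evolution is the exact closed form", {
  # pure leak: V(tau_mem) = exp(-1), I stays 0
  st <- evolve_free(1, 0, cfg1$tau_mem, cfg1)
  expect_equal(st$v, exp(-1), tolerance = 1e-14)
  expect_identical(st$i, 0)
  # dt = 0 is the identity
  st0 <- evolve_free(c(0.3, -0.2), c(2, 0.5), 0, cfg1)
  expect_identical(st0$v, c(0.3, -0.2))
  expect_identical(st0$i, c(2, 0.5))
  # rejects the degenerate equal-time-constant case
  expect_error(lif_config(matrix(0, 1, 1), matrix(1, 1, 1),
                          tau_mem = 5, tau_syn = 5), "unsupported")
})

test_that("free evolution matches an adaptive-step ODE integration", {
  skip_if_not_installed("deSolve")
  cfg <- lif_config(matrix(0, 1, 1), matrix(1, 1, 1),
                    tau_mem = 20, tau_syn = 5, t_end = 100)
  deriv <- function(t, y, p)
    list(c((-y[1] + y[2]) / cfg$tau_mem, -y[2] / cfg$tau_syn))
  set.seed(1)
  for (rep in 1:8) {
    v0 <- runif(1, -1, 2)
    i0 <- runif(1, -2, 4)
    dt <- runif(1, 0.1, 15)
    ode <- deSolve::lsoda(c(v0, i0), c(0, dt), deriv, NULL,
                          rtol = 1e-12, atol = 1e-13)
    st <- evolve_free(v0, i0, dt, cfg)
    expect_equal(st$v, unname(ode[2, 2]), tolerance = 1e-9)
    expect_equal(st$i, unname(ode[2, 3]), tolerance = 1e-9)
  }
  # spot check: V(0)=0, I(0)=2, tau_mem=20, tau_syn=5, dt=3
  ode <- deSolve::lsoda(c(0, 2), c(0, 3), deriv, NULL,
                        rtol = 1e-12, atol = 1e-14)
  expect_equal(evolve_free(0, 2, 3, cfg)$v, unname(ode[2, 2]),
               tolerance = 1e-10)
})

test_that("threshold crossing detection agrees with a dense scan", {
  cfg <- lif_config(matrix(0, 2, 2), matrix(1, 2, 1), t_end = 100)
  # subthreshold decay never crosses
  expect_null(next_threshold_crossing(0.5, 0, 0, 50, cfg1))
  # supra-threshold drive: compare against a dense closed-form scan
  i0 <- 8
  cr <- next_threshold_crossing(c(0, 0), c(i0, 3), 0, 60, cfg)
  scan <- dense_v_scan(0, i0, cfg, 60)
  t_scan <- scan$t[which(scan$v >= cfg$threshold)[1]]
  expect_equal(cr$time, t_scan, tolerance = 2e-5)
  # the neuron with the larger current crosses first and is identified
  cr2 <- next_threshold_crossing(c(0, 0), c(7, 12), 0, 60, cfg)
  expect_identical(cr2$neuron, 2L)
  # non-firing neurons are never reported
  cfg_nf <- lif_config(matrix(0, 2, 2), matrix(1, 2, 1),
                       firing = c(FALSE, TRUE), t_end = 100)
  cr3 <- next_threshold_crossing(c(0, 0), c(12, 0), 0, 60, cfg_nf)
  expect_null(cr3)
})

test_that("spike and input transitions implement the jump rules", {
  w <- 0.7
  cfg <- lif_config(matrix(c(0, w, 0, 0), 2, 2), matrix(0.5, 2, 1),
                    t_end = 10)
  tr <- apply_spike_transition(c(1, 0.2), c(3, 0.1), 1, cfg)
  expect_identical(tr$v, c(0, 0.2))          # reset + others unchanged
  expect_equal(tr$i, c(3, 0.1 + w))          # current jump by column 1
  expect_equal(tr$vdot_minus, (-1 + 3) / cfg$tau_mem)
  expect_equal(tr$i_minus, 3)
  # zero column: only the reset happens
  cfg0 <- lif_config(matrix(0, 2, 2), matrix(0.5, 2, 1), t_end = 10)
  tr0 <- apply_spike_transition(c(1, 0.2), c(3, 0.1), 1, cfg0)
  expect_equal(tr0$i, c(3, 0.1))
  # near-critical points are flagged
  expect_warning(apply_spike_transition(1, 1 + 1e-10, 1, cfg0),
                 "near-critical")
  # input spikes only touch currents
  st <- apply_input_spike(c(0.4, 0.4), c(0, 0), 1, cfg)
  expect_identical(st$v, c(0.4, 0.4))
  expect_equal(st$i, c(0.5, 0.5))
  # two simultaneous spikes on one channel add
  st2 <- apply_input_spike(st$v, st$i, 1, cfg)
  expect_equal(st2$i, c(1, 1))
})

test_that("coincident spike transitions commute", {
  # two neurons forced to cross at the identical time; applying the
  # transitions in either order yields the same state
  w_rec <- matrix(c(0, 0.3, 0.5, 0), 2, 2)
  cfg <- lif_config(w_rec, matrix(1, 2, 1), t_end = 10)
  v <- c(1, 1)
  i <- c(2, 3)
  a1 <- apply_spike_transition(v, i, 1, cfg)
  a2 <- apply_spike_transition(a1$v, a1$i, 2, cfg)
  b1 <- apply_spike_transition(v, i, 2, cfg)
  b2 <- apply_spike_transition(b1$v, b1$i, 1, cfg)
  expect_equal(a2$v, b2$v)
  expect_equal(a2$i, b2$i)
})

test_that("event-driven simulation matches a dense Euler oracle", {
  for (seed in c(2, 5)) {
    net <- random_recurrent_net(seed, n = 3, m = 2, t_end = 30)
    sim <- simulate(net$cfg, net$inputs)
    eul <- euler_forward(net$cfg, net$inputs, dt = 1e-4)
    expect_identical(nrow(sim$record), nrow(eul))
    if (nrow(eul)) {
      o1 <- order(sim$record$time)
      expect_identical(sim$record$neuron[o1], eul$neuron)
      expect_lt(max(abs(sim$record$time[o1] - eul$time)), 1e-3)
    }
  }
})

test_that("Euler spike-time error shrinks linearly with dt", {
  net <- random_recurrent_net(4, n = 2, m = 2, t_end = 25)
  sim <- simulate(net$cfg, net$inputs)
  expect_gt(nrow(sim$record), 0)
  err <- sapply(c(4e-4, 2e-4, 1e-4), function(dt) {
    eul <- euler_forward(net$cfg, net$inputs, dt)
    expect_identical(nrow(eul), nrow(sim$record))
    max(abs(sort(eul$time) - sort(sim$record$time)))
  })
  # halving dt should roughly halve the error (allow generous slack)
  expect_lt(err[3], err[1] * 0.75)
})

test_that("zero weights produce an empty spike record", {
  cfg <- lif_config(matrix(0, 2, 2), matrix(0, 2, 1), t_end = 20)
  sim <- simulate(cfg, spike_train(c(1, 5), c(1, 1)))
  expect_identical(nrow(sim$record), 0L)
})

test_that("recorded spikes cache the threshold state and pre-reset slope", {
  net <- ttfs_toy_net(11)
  sim <- simulate(net$cfg, encode_yinyang(0.3, 0.6))
  expect_gt(nrow(sim$record), 0)
  rec <- sim$record
  # vdot_minus is determined by the cached current (V is at threshold)
  expect_equal(rec$vdot_minus,
               (-net$cfg$threshold + rec$i_minus) / net$cfg$tau_mem)
  expect_true(all(rec$vdot_minus != 0))
  # membrane potential just before each spike is at threshold
  for (k in seq_len(nrow(rec))) {
    st <- trajectory_state(sim, rec$time[k] - 1e-9, net$cfg)
    expect_equal(st$v[rec$neuron[k]], net$cfg$threshold, tolerance = 1e-6)
  }
})

test_that("both engines and repeated runs are bit-identical", {
  for (seed in c(3, 9)) {
    net <- random_recurrent_net(seed, n = 3, m = 2, t_end = 30)
    a <- simulate(net$cfg, net$inputs)
    b <- simulate(net$cfg, net$inputs)
    expect_identical(a$record, b$record)
    r <- simulate(net$cfg, net$inputs, engine = "r")
    expect_equal(a$record, r$record, tolerance = 1e-12)
    expect_equal(a$v_end, r$v_end, tolerance = 1e-12)
  }
})

test_that("translating all inputs in time translates all output spikes", {
  net <- ttfs_toy_net(21)
  ins <- encode_yinyang(0.4, 0.2)
  delta <- 7.5
  cfg2 <- net$cfg
  cfg2$t_end <- cfg2$t_end + delta
  sim1 <- simulate(net$cfg, ins)
  sim2 <- simulate(cfg2, spike_train(ins$time + delta, ins$channel))
  expect_identical(nrow(sim1$record), nrow(sim2$record))
  expect_equal(sim2$record$time, sim1$record$time + delta, tolerance = 1e-9)
  expect_identical(sim2$record$neuron, sim1$record$neuron)
})

test_that("the trajectory reconstructs the state between events", {
  net <- ttfs_toy_net(31)
  ins <- encode_yinyang(0.7, 0.3)
  sim <- simulate(net$cfg, ins)
  sim_r <- simulate(net$cfg, ins, engine = "r")
  for (t in c(0, 4.3, 17.9, 33.3, 59.9)) {
    a <- trajectory_state(sim, t, net$cfg)
    b <- trajectory_state(sim_r, t, net$cfg)
    expect_equal(a$v, b$v, tolerance = 1e-10)
    expect_equal(a$i, b$i, tolerance = 1e-10)
  }
})

test_that("the runaway-activity guard aborts", {
  # strong positive feedback loop => unbounded spiking
  w_rec <- matrix(c(0, 5, 5, 0), 2, 2)
  cfg <- lif_config(w_rec, matrix(8, 2, 1), t_end = 200, spike_cap = 50)
  expect_error(simulate(cfg, spike_train(0, 1)), "spike cap")
})

test_that("spike trains and records round-trip through CSV", {
  tr <- spike_train(c(0.5, 3.25, 3.25), c(2L, 1L, 3L))
  f <- tempfile(fileext = ".csv")
  write_spike_csv(tr, f)
  back <- read_spike_csv(f)
  expect_equal(back$time, tr$time)
  expect_identical(back$channel, tr$channel)
  unlink(f)
})

test_that("network configurations round-trip through YAML + CSV", {
  net <- ttfs_toy_net(41)
  d <- tempfile()
  save_network(net$cfg, d)
  cfg2 <- load_network(d)
  expect_equal(cfg2$w_rec, net$cfg$w_rec)
  expect_equal(cfg2$w_in, net$cfg$w_in)
  expect_identical(cfg2$firing, net$cfg$firing)
  expect_equal(cfg2$tau_mem, net$cfg$tau_mem)
  unlink(d, recursive = TRUE)
})
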