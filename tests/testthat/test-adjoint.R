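test_that("adjoint free evolution is exact and fixes zero", {
  cfg <- lif_config(matrix(0, 2, 2), matrix(1, 2, 1), t_end = 50)
  # zero is a fixed point of the homogeneous adjoint system
  st <- adjoint_evolve_free(c(0, 0), c(0, 0), 13.7, cfg)
  expect_identical(st$lv, c(0, 0))
  expect_identical(st$li, c(0, 0))
  # dt = 0 is the identity
  st0 <- adjoint_evolve_free(c(0.3, 1), c(-2, 0.1), 0, cfg)
  expect_identical(st0$lv, c(0.3, 1))
  expect_identical(st0$li, c(-2, 0.1))
})

test_that("adjoint free evolution matches an adaptive-step ODE solve", {
  skip_if_not_installed("deSolve")
  cfg <- lif_config(matrix(0, 1, 1), matrix(1, 1, 1), t_end = 50)
  # reverse time s: dlv/ds = -lv/tau_mem, dli/ds = (-li + lv)/tau_syn
  deriv <- function(s, y, p)
    list(c(-y[1] / cfg$tau_mem, (-y[2] + y[1]) / cfg$tau_syn))
  set.seed(2)
  for (rep in 1:8) {
    lv0 <- runif(1, -2, 2)
    li0 <- runif(1, -2, 2)
    ds <- runif(1, 0.2, 10)
    ode <- deSolve::lsoda(c(lv0, li0), c(0, ds), deriv, NULL,
                          rtol = 1e-12, atol = 1e-14)
    st <- adjoint_evolve_free(lv0, li0, ds, cfg)
    expect_equal(st$lv, unname(ode[2, 2]), tolerance = 1e-10)
    expect_equal(st$li, unname(ode[2, 3]), tolerance = 1e-10)
  }
})

test_that("the adjoint spike jump matches its term-by-term reference", {
  # isolated neuron (empty weight column), no loss term: the jump factor is
  # the same (theta/(tau_mem Vdot-) + 1) factor as the forward
  # partial-derivative jump
  cfg0 <- lif_config(matrix(0, 1, 1), matrix(1, 1, 1), t_end = 10)
  vd <- 0.17
  ev <- data.frame(neuron = 1L, vdot_minus = vd)
  st <- apply_adjoint_spike_jump(0.6, 0.25, ev, dlp = 0, cfg0)
  expect_equal(st$lv, (cfg0$threshold / (cfg0$tau_mem * vd) + 1) * 0.6)
  expect_identical(st$li, 0.25)
  # zero adjoint state, pure spike-time sensitivity c: jump = c/(tau_mem vd)
  st2 <- apply_adjoint_spike_jump(0, 0, ev, dlp = 0.3, cfg0)
  expect_equal(st2$lv, 0.3 / (cfg0$tau_mem * vd))
  # random small networks against the independent reference
  for (seed in c(6, 7, 8)) {
    set.seed(seed)
    n <- 4
    w_rec <- matrix(rnorm(n * n), n, n)
    diag(w_rec) <- 0
    cfg <- lif_config(w_rec, matrix(1, n, 1), t_end = 10)
    lv <- rnorm(n)
    li <- rnorm(n)
    nn <- sample(n, 1)
    vdm <- runif(1, 0.05, 0.6)
    dlp <- rnorm(1)
    ev <- data.frame(neuron = nn, vdot_minus = vdm)
    st <- apply_adjoint_spike_jump(lv, li, ev, dlp, cfg)
    expect_equal(st$lv, adjoint_jump_reference(lv, li, nn, vdm, dlp, cfg),
                 tolerance = 1e-13)
    expect_identical(st$li, li)  # lambda_I is continuous
    expect_identical(st$lv[-nn], lv[-nn])  # only the firing component jumps
  }
})

test_that("voltage-loss jumps add the supplied magnitude", {
  lv <- c(0.2, -0.4)
  expect_identical(apply_voltage_loss_jump(lv, 2, 0), lv)
  expect_equal(apply_voltage_loss_jump(lv, 2, 1 / 20), c(0.2, -0.4 + 0.05))
})

test_that("gradient accumulation sums -tau_syn * lambda_I per event", {
  cfg <- lif_config(matrix(0, 2, 2), matrix(1, 2, 2), t_end = 10)
  acc <- list(g_rec = matrix(0, 2, 2), g_in = matrix(0, 2, 2))
  acc <- accumulate_gradient(acc, "spike", 1, c(0.5, -0.2), cfg)
  # the diagonal (self-connection) is not a parameter and stays zero
  expect_equal(acc$g_rec[, 1], -cfg$tau_syn * c(0, -0.2))
  expect_equal(acc$g_rec[, 2], c(0, 0))
  acc <- accumulate_gradient(acc, "input", 2, c(1, 1), cfg)
  expect_equal(acc$g_in[, 2], -cfg$tau_syn * c(1, 1))
  # lambda_I identically zero => zero gradient
  acc0 <- accumulate_gradient(list(g_rec = matrix(0, 2, 2),
                                   g_in = matrix(0, 2, 2)),
                              "spike", 2, c(0, 0), cfg)
  expect_true(all(acc0$g_rec == 0))
})

test_that("adjoint boundary condition and continuity hold along the sweep", {
  net <- ttfs_toy_net(11)
  ins <- encode_yinyang(0.3, 0.6)
  res <- eventprop_gradient(net$cfg, ins, ttfs_head(net$output, 2),
                            keep_lambda = TRUE)
  expect_gt(res$n_spikes, 2)
  rec <- simulate(net$cfg, ins)$record
  last <- which.max(rec$time)
  # lambda(T) = 0 evolves freely to the last event: still exactly zero there
  expect_identical(unname(res$lambda_v_pre[last, ]), rep(0, net$cfg$n))
  expect_identical(unname(res$lambda_i_pre[last, ]), rep(0, net$cfg$n))
  # lambda_I and the non-firing components of lambda_V are continuous
  for (k in seq_len(res$n_spikes)) {
    expect_identical(res$lambda_i_pre[k, ], res$lambda_i_post[k, ])
    nn <- rec$neuron[k]
    expect_identical(res$lambda_v_pre[k, -nn], res$lambda_v_post[k, -nn])
  }
})

test_that("weights that transmitted no spike get exactly zero gradient", {
  # neuron 3 receives input but never fires (weak drive); its outgoing
  # column must receive exactly zero gradient
  w_rec <- matrix(0, 3, 3)
  w_rec[2, 1] <- 1.5
  w_rec[1, 3] <- 2.0   # from the silent neuron
  w_in <- matrix(0, 3, 2)
  w_in[1, 1] <- 9
  w_in[3, 2] <- 0.1    # far subthreshold
  cfg <- lif_config(w_rec, w_in, t_end = 50)
  ins <- spike_train(c(0, 1), c(1, 2))
  res <- eventprop_gradient(cfg, ins, spike_sum_head(1))
  counts <- tabulate(simulate(cfg, ins)$record$neuron, 3)
  expect_identical(counts[3], 0L)
  expect_identical(res$g_rec[, 3], rep(0, 3))
  # a channel with no input spikes also gets zero
  cfg2 <- lif_config(w_rec, cbind(w_in, c(1, 1, 1)), t_end = 50)
  res2 <- eventprop_gradient(cfg2, ins, spike_sum_head(1))
  expect_identical(res2$g_in[, 3], rep(0, 3))
})

test_that("no spikes and a spike-time loss give zero loss and gradient", {
  cfg <- lif_config(matrix(0, 2, 2), matrix(0.1, 2, 1), t_end = 30)
  res <- eventprop_gradient(cfg, spike_train(5, 1), spike_sum_head(1:2))
  expect_identical(res$loss, 0)
  expect_true(all(res$g_rec == 0) && all(res$g_in == 0))
})

test_that("adjoint gradients match central differences on random networks", {
  # 20 random instances across both loss heads; only non-critical entries
  # (spike counts preserved under perturbation) are compared. Entries whose
  # magnitude is negligible relative to the dominant gradient are checked
  # absolutely (the relative error of a ~0 entry only measures FD noise).
  check_agreement <- function(chk) {
    ok <- !chk$critical
    expect_gt(sum(ok), 0)
    chk <- chk[ok, ]
    scale <- max(abs(chk$eventprop_grad), abs(chk$fd_grad))
    informative <- pmax(abs(chk$eventprop_grad), abs(chk$fd_grad)) >
      1e-3 * scale
    if (any(informative))
      expect_lt(max(chk$rel_error[informative]), 1e-6)
    if (any(!informative))
      expect_lt(max(abs(chk$eventprop_grad - chk$fd_grad)[!informative]),
                1e-6 * scale)
  }
  n_checked <- 0
  for (seed in 1:10) {
    net <- ttfs_toy_net(seed * 13)
    ins <- toy_inputs(seed, 5, t_max = 25)
    sim <- simulate(net$cfg, ins)
    label <- 1 + seed %% 3
    ft <- first_spike_times(sim$record, net$output)
    if (any(is.na(ft))) next  # quiescent draw: no informative gradient
    head <- ttfs_head(net$output, label)
    set.seed(seed)
    wr <- cbind(sample(net$output, 3, TRUE), sample(net$hidden, 3, TRUE))
    wi <- cbind(sample(net$hidden, 3, TRUE), sample(5, 3, TRUE))
    chk <- gradient_check(net$cfg, ins, head, wr, wi, eps = 1e-5)
    check_agreement(chk)
    n_checked <- n_checked + 1
  }
  for (seed in 1:10) {
    net <- vmax_toy_net(seed * 29)
    ins <- toy_inputs(seed + 50, 3, t_max = 25)
    head <- max_voltage_head(net$output, 1 + seed %% 3)
    set.seed(seed)
    wr <- cbind(sample(net$output, 3, TRUE), sample(net$hidden, 3, TRUE))
    wi <- cbind(sample(net$hidden, 3, TRUE), sample(3, 3, TRUE))
    chk <- gradient_check(net$cfg, ins, head, wr, wi, eps = 1e-5)
    check_agreement(chk)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 16)
})

test_that("gradient agreement is robust to the difference step", {
  net <- ttfs_toy_net(11)
  ins <- encode_yinyang(0.3, 0.6)
  head <- ttfs_head(net$output, 2)
  for (eps in c(1e-5, 1e-4, 1e-3)) {
    chk <- gradient_check(net$cfg, ins, head,
                          which_rec = rbind(c(5, 1), c(6, 2)),
                          which_in = rbind(c(1, 1)), eps = eps)
    ok <- !chk$critical
    expect_lt(max(chk$rel_error[ok]), 1e-5)
  }
})

test_that("a small step against the gradient decreases the loss", {
  net <- ttfs_toy_net(11)
  ins <- encode_yinyang(0.3, 0.6)
  head <- ttfs_head(net$output, 2)
  res <- eventprop_gradient(net$cfg, ins, head)
  gnorm2 <- sum(res$g_rec^2) + sum(res$g_in^2)
  expect_gt(gnorm2, 0)
  decreased <- FALSE
  for (step in 10^seq(-3, -6)) {
    cfg2 <- net$cfg
    cfg2$w_rec <- cfg2$w_rec - step * res$g_rec
    diag(cfg2$w_rec) <- 0
    cfg2$w_in <- cfg2$w_in - step * res$g_in
    sim2 <- simulate(cfg2, ins)
    l2 <- loss_sensitivities(head, sim2, cfg2)$value
    if (l2 < res$loss) {
      decreased <- TRUE
      break
    }
  }
  expect_true(decreased)
})

test_that("compiled and reference backward sweeps agree", {
  for (seed in c(11, 21)) {
    net <- ttfs_toy_net(seed)
    ins <- encode_yinyang(0.35, 0.55)
    head <- ttfs_head(net$output, 1)
    a <- eventprop_gradient(net$cfg, ins, head)
    b <- eventprop_gradient(net$cfg, ins, head, engine = "r")
    expect_equal(a$loss, b$loss, tolerance = 1e-12)
    expect_equal(a$g_rec, b$g_rec, tolerance = 1e-10)
    expect_equal(a$g_in, b$g_in, tolerance = 1e-10)
  }
  net <- vmax_toy_net(5)
  ins <- toy_inputs(5, 3)
  head <- max_voltage_head(net$output, 2)
  a <- eventprop_gradient(net$cfg, ins, head)
  b <- eventprop_gradient(net$cfg, ins, head, engine = "r")
  expect_equal(a$g_rec, b$g_rec, tolerance = 1e-10)
  expect_equal(a$g_in, b$g_in, tolerance = 1e-10)
})

test_that("the gradient accumulator diagonal stays zero", {
  net <- random_recurrent_net(17, n = 4, m = 2, t_end = 30)
  res <- eventprop_gradient(net$cfg, net$inputs, spike_sum_head(1:4))
  expect_identical(diag(res$g_rec), rep(0, 4))
  expect_true(all(is.finite(res$g_rec)) && all(is.finite(res$g_in)))
})
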