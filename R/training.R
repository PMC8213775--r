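#' Gaussian weight initialization
#'
#' Independent Gaussian per weight with block-level mean and standard
#' deviation (no fan-in scaling; the statistics are raw per-weight
#' parameters). With a suitable mean this produces a non-quiescent network
#' at initialization, which the spike-time loss needs: gradients only exist
#' where spikes exist.
#'
#' @param nrow,ncol Block shape.
#' @param mean,sd Per-weight Gaussian parameters (`sd >= 0`).
#' @return A `nrow x ncol` matrix.
#' @export
gaussian_weights <- function(nrow, ncol, mean, sd) {
  stopifnot(sd >= 0)
  matrix(stats::rnorm(nrow * ncol, mean, sd), nrow, ncol)
}

#' Two-layer spiking classifier network
#'
#' Builds the block-structured recurrent matrix of a feed-forward network
#' with `n_hidden` LIF neurons and `n_class` output neurons: neurons
#' `1..n_hidden` receive the input channels through `hidden_w`, outputs
#' `n_hidden + (1..n_class)` receive hidden spikes through `out_w`. Outputs
#' are firing neurons for spike-time classification and non-firing leaky
#' integrators for voltage-maximum classification.
#'
#' @param hidden_w `n_hidden x n_in` input weight block.
#' @param out_w `n_class x n_hidden` output weight block.
#' @param readout_firing `TRUE` for spike-time readouts, `FALSE` for
#'   non-firing voltage readouts.
#' @param tau_mem,tau_syn,threshold,t_end Passed to [lif_config()].
#' @return List with `cfg` ([lif_config()]), `hidden` and `output` neuron
#'   index vectors, and logical masks `mask_rec`, `mask_in` marking the
#'   trainable weight blocks.
#' @export
snn_classifier <- function(hidden_w, out_w, readout_firing = TRUE,
                           tau_mem = 20, tau_syn = 5, threshold = 1,
                           t_end = 60) {
  h <- nrow(hidden_w)
  k <- nrow(out_w)
  stopifnot(ncol(out_w) == h)
  n <- h + k
  w_rec <- matrix(0, n, n)
  w_rec[h + seq_len(k), seq_len(h)] <- out_w
  w_in <- matrix(0, n, ncol(hidden_w))
  w_in[seq_len(h), ] <- hidden_w
  firing <- c(rep(TRUE, h), rep(readout_firing, k))
  mask_rec <- matrix(FALSE, n, n)
  mask_rec[h + seq_len(k), seq_len(h)] <- TRUE
  mask_in <- matrix(FALSE, n, ncol(hidden_w))
  mask_in[seq_len(h), ] <- TRUE
  list(cfg = lif_config(w_rec, w_in, tau_mem = tau_mem, tau_syn = tau_syn,
                        threshold = threshold, firing = firing,
                        t_end = t_end),
       hidden = seq_len(h), output = h + seq_len(k),
       mask_rec = mask_rec, mask_in = mask_in)
}

#' Adam optimizer
#'
#' `adam_init` creates zeroed first/second-moment accumulators for a named
#' list of weight matrices; `adam_step` applies one standard bias-corrected
#' Adam update.
#'
#' @param weights Named list of weight matrices.
#' @param beta1,beta2,eps Adam parameters.
#' @param eta Base learning rate.
#' @param decay_factor,decay_step Learning-rate schedule: the rate is
#'   `eta * decay_factor^(floor(epoch / decay_step))`, updated once per
#'   epoch by the training loop.
#' @return `adam_init`: an optimizer state. `adam_step`: list with updated
#'   `opt` and `weights`.
#' @export
adam_init <- function(weights, eta = 5e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, decay_factor = 0.95, decay_step = 1) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0),
       step = 0L, eta = eta, beta1 = beta1, beta2 = beta2, eps = eps,
       decay_factor = decay_factor, decay_step = decay_step)
}

#' @rdname adam_init
#' @param opt Optimizer state from `adam_init`.
#' @param grads Named list of gradients, shapes matching `weights`.
#' @param lr Learning rate for this step (defaults to `opt$eta`).
#' @export
adam_step <- function(opt, weights, grads, lr = NULL) {
  if (is.null(lr)) lr <- opt$eta
  for (g in grads) if (any(!is.finite(g)))
    stop("non-finite gradient in adam_step")
  opt$step <- opt$step + 1L
  bc1 <- 1 - opt$beta1^opt$step
  bc2 <- 1 - opt$beta2^opt$step
  for (nm in names(weights)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + opt$eps)
  }
  list(opt = opt, weights = weights)
}

# classification rules (internal)
predict_ttfs <- function(sim, output_neurons) {
  ft <- first_spike_times(sim$record, output_neurons)
  if (all(is.na(ft))) return(1L)  # degenerate: tie-break to class 1
  which.min(ft)  # ties break to the lowest class index
}

predict_vmax <- function(sim, readout_neurons, cfg) {
  vm <- vapply(readout_neurons, function(n) voltage_max(sim, n, cfg)$v_max,
               numeric(1))
  which.max(vm)
}

# build the per-sample loss head (internal)
make_head <- function(loss, output_neurons, label, n_batch, loss_opts) {
  if (loss == "ttfs")
    do.call(ttfs_head, c(list(output_neurons = output_neurons, label = label,
                              n_batch = n_batch), loss_opts))
  else
    max_voltage_head(output_neurons, label, n_batch = n_batch)
}

#' Evaluate a spiking classifier
#'
#' Forward passes only. Classification rule: for the `"ttfs"` loss the
#' class of the output neuron with the earliest first spike (ties broken by
#' the lowest class index; a fully silent output layer predicts class 1);
#' for `"max_over_time"` the readout with the largest voltage maximum.
#'
#' @param net An [snn_classifier()].
#' @param spikes List of [spike_train()] samples.
#' @param labels Integer class labels.
#' @param loss `"ttfs"` or `"max_over_time"`.
#' @param loss_opts Extra arguments for the loss head (e.g. `tau0`).
#' @return List with `loss` (mean per-sample loss), `accuracy`, and the
#'   `confusion` matrix (rows = truth, columns = prediction;
#'   `accuracy == sum(diag(confusion)) / sum(confusion)` by construction).
#' @export
evaluate_classifier <- function(net, spikes, labels,
                                loss = c("ttfs", "max_over_time"),
                                loss_opts = list()) {
  loss <- match.arg(loss)
  k <- length(net$output)
  confusion <- matrix(0L, k, k)
  total_loss <- 0
  for (j in seq_along(spikes)) {
    sim <- simulate(net$cfg, spikes[[j]],
                    record_trajectory = (loss == "max_over_time"))
    pred <- if (loss == "ttfs") predict_ttfs(sim, net$output)
    else predict_vmax(sim, net$output, net$cfg)
    confusion[labels[j], pred] <- confusion[labels[j], pred] + 1L
    head <- make_head(loss, net$output, labels[j], 1, loss_opts)
    total_loss <- total_loss + loss_sensitivities(head, sim, net$cfg)$value
  }
  list(loss = total_loss / length(spikes),
       accuracy = sum(diag(confusion)) / length(spikes),
       confusion = confusion)
}

# shared minibatch training loop (internal). Gradients of a batch are the
# sums of per-sample gradients with the 1/N_batch factor inside the loss
# heads; Adam steps per batch; learning rate decays once per epoch.
train_loop <- function(weights, build_net, spikes_train, labels_train,
                       spikes_val, labels_val, spikes_test, labels_test,
                       loss, loss_opts, epochs, batch_size,
                       opt, p_drop = 0, eval_test = TRUE, verbose = FALSE) {
  n_train <- length(spikes_train)
  history <- data.frame()
  for (epoch in seq_len(epochs)) {
    lr <- opt$eta * opt$decay_factor^((epoch - 1) %/% opt$decay_step)
    perm <- sample.int(n_train)
    epoch_loss <- 0
    epoch_spikes <- 0
    for (b0 in seq(1, n_train, by = batch_size)) {
      idx <- perm[b0:min(b0 + batch_size - 1, n_train)]
      nb <- length(idx)
      net <- build_net(weights)
      g <- lapply(weights, function(w) w * 0)
      for (j in idx) {
        sp <- if (p_drop > 0) drop_spikes(spikes_train[[j]], p_drop)
        else spikes_train[[j]]
        head <- make_head(loss, net$output, labels_train[j], nb, loss_opts)
        res <- eventprop_gradient(net$cfg, sp, head)
        g$hidden <- g$hidden + res$g_in[net$hidden, , drop = FALSE]
        g$out <- g$out + res$g_rec[net$output, net$hidden, drop = FALSE]
        epoch_loss <- epoch_loss + res$loss
        epoch_spikes <- epoch_spikes + res$n_spikes
      }
      st <- adam_step(opt, weights, g, lr)
      opt <- st$opt
      weights <- st$weights
    }
    net <- build_net(weights)
    val <- evaluate_classifier(net, spikes_val, labels_val, loss, loss_opts)
    test <- if (eval_test)
      evaluate_classifier(net, spikes_test, labels_test, loss, loss_opts)
    else list(accuracy = NA_real_)
    n_batches <- ceiling(n_train / batch_size)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = epoch_loss / n_batches,
      val_acc = val$accuracy, test_acc = test$accuracy,
      lr = lr, mean_spikes = epoch_spikes / n_train))
    if (verbose)
      message(sprintf(
        "epoch %3d  train_loss %.4f  val_acc %.4f  test_acc %s  (%.0f spikes/sample)",
        epoch, epoch_loss / n_batches, val$accuracy,
        ifelse(is.na(test$accuracy), "-", sprintf("%.4f", test$accuracy)),
        epoch_spikes / n_train))
  }
  list(weights = weights, opt = opt, history = history)
}

#' Train a spiking classifier on the Yin-Yang task
#'
#' Minibatch training with Adam and exact gradients on the
#' latency-encoded Yin-Yang dataset, using the first-spike-time
#' cross-entropy loss and spike-time classification. All hyperparameter
#' defaults are the published task settings; the network sizes and dataset
#' sizes are configurable for scaled-down runs. Fully deterministic given
#' `seed`.
#'
#' @param n_hidden Hidden layer size.
#' @param epochs Training epochs (0 returns the initialization unchanged).
#' @param n_train,n_val,n_test Dataset split sizes (generated with disjoint
#'   draws from one seeded stream).
#' @param seed Integer seed controlling data generation, initialization,
#'   and shuffling.
#' @param batch_size Minibatch size.
#' @param eta,decay_factor Adam base learning rate and per-epoch decay.
#' @param hidden_mean,hidden_sd,out_mean,out_sd Gaussian init statistics of
#'   the two weight blocks.
#' @param tau0,tau1,alpha TTFS loss parameters.
#' @param t_max,t_bias Latency encoding parameters (ms).
#' @param t_end Simulation horizon (ms).
#' @param eval_test Evaluate the test split every epoch (else only at the
#'   best-validation epoch).
#' @param verbose Print per-epoch progress.
#' @return List with `history` (per-epoch data frame: `epoch`,
#'   `train_loss`, `val_acc`, `test_acc`, `lr`, `mean_spikes`), final
#'   `weights`, the `net` at the final weights, `best_epoch` (highest
#'   validation accuracy, earliest on ties), and `test_acc_best` /
#'   `test_acc_final`.
#' @export
train_yinyang <- function(n_hidden = 200, epochs = 300,
                          n_train = 5000, n_val = 1000, n_test = 1000,
                          seed = 1, batch_size = 32,
                          eta = 5e-3, decay_factor = 0.95,
                          hidden_mean = 1.5, hidden_sd = 0.78,
                          out_mean = 0.93, out_sd = 0.1,
                          tau0 = 0.5, tau1 = 6.4, alpha = 3e-3,
                          t_max = 30, t_bias = 0, t_end = 2 * t_max,
                          eval_test = TRUE, verbose = FALSE) {
  set.seed(seed)
  d_train <- generate_yinyang(n_train)
  d_val <- generate_yinyang(n_val)
  d_test <- generate_yinyang(n_test)
  e_train <- encode_yinyang_dataset(d_train, t_max, t_bias)
  e_val <- encode_yinyang_dataset(d_val, t_max, t_bias)
  e_test <- encode_yinyang_dataset(d_test, t_max, t_bias)
  weights <- list(hidden = gaussian_weights(n_hidden, 5, hidden_mean,
                                            hidden_sd),
                  out = gaussian_weights(3, n_hidden, out_mean, out_sd))
  build_net <- function(w) snn_classifier(w$hidden, w$out,
                                          readout_firing = TRUE,
                                          t_end = t_end)
  opt <- adam_init(weights, eta = eta, decay_factor = decay_factor)
  loss_opts <- list(tau0 = tau0, tau1 = tau1, alpha = alpha)
  if (epochs == 0)
    return(list(history = data.frame(), weights = weights,
                net = build_net(weights), best_epoch = NA_integer_,
                test_acc_best = NA_real_, test_acc_final = NA_real_))
  fit <- train_loop(weights, build_net, e_train$spikes, e_train$label,
                    e_val$spikes, e_val$label, e_test$spikes, e_test$label,
                    "ttfs", loss_opts, epochs, batch_size, opt,
                    eval_test = eval_test, verbose = verbose)
  best <- which.max(fit$history$val_acc)
  net <- build_net(fit$weights)
  test_final <- fit$history$test_acc[epochs]
  if (is.na(test_final))
    test_final <- evaluate_classifier(net, e_test$spikes, e_test$label,
                                      "ttfs", loss_opts)$accuracy
  test_best <- fit$history$test_acc[best]
  if (is.na(test_best)) test_best <- test_final
  c(fit, list(net = net, best_epoch = best,
              test_acc_best = test_best, test_acc_final = test_final))
}

#' Train a voltage-maximum spiking classifier
#'
#' Generic front-end for the max-over-time voltage loss: a hidden layer of
#' firing LIF neurons feeding non-firing leaky-integrator readouts, one per
#' class, with the class read off the largest voltage maximum. This is the
#' MNIST-style architecture; inputs are arbitrary pre-encoded spike trains,
#' so the same function trains on full MNIST latency encodings or on small
#' synthetic problems.
#'
#' @param spikes_train,spikes_val,spikes_test Lists of [spike_train()].
#' @param labels_train,labels_val,labels_test Integer labels.
#' @param n_in,n_hidden,n_class Architecture sizes.
#' @param epochs,batch_size,eta,decay_factor Optimization settings.
#' @param hidden_mean,hidden_sd,out_mean,out_sd Init statistics.
#' @param p_drop Probability of dropping each input spike during training.
#' @param t_end Simulation horizon (ms).
#' @param seed Integer seed (initialization and shuffling).
#' @param eval_test,verbose See [train_yinyang()].
#' @return As [train_yinyang()].
#' @export
train_voltage_classifier <- function(spikes_train, labels_train,
                                     spikes_val, labels_val,
                                     spikes_test, labels_test,
                                     n_in, n_hidden = 350, n_class = 10,
                                     epochs = 100, batch_size = 5,
                                     eta = 5e-3, decay_factor = 0.95,
                                     hidden_mean = 0.078, hidden_sd = 0.045,
                                     out_mean = 0.2, out_sd = 0.37,
                                     p_drop = 0.2, t_end = 40, seed = 1,
                                     eval_test = TRUE, verbose = FALSE) {
  set.seed(seed)
  weights <- list(hidden = gaussian_weights(n_hidden, n_in, hidden_mean,
                                            hidden_sd),
                  out = gaussian_weights(n_class, n_hidden, out_mean, out_sd))
  build_net <- function(w) snn_classifier(w$hidden, w$out,
                                          readout_firing = FALSE,
                                          t_end = t_end)
  opt <- adam_init(weights, eta = eta, decay_factor = decay_factor)
  if (epochs == 0)
    return(list(history = data.frame(), weights = weights,
                net = build_net(weights), best_epoch = NA_integer_,
                test_acc_best = NA_real_, test_acc_final = NA_real_))
  fit <- train_loop(weights, build_net, spikes_train, labels_train,
                    spikes_val, labels_val, spikes_test, labels_test,
                    "max_over_time", list(), epochs, batch_size, opt,
                    p_drop = p_drop, eval_test = eval_test,
                    verbose = verbose)
  best <- which.max(fit$history$val_acc)
  c(fit, list(net = build_net(fit$weights), best_epoch = best,
              test_acc_best = fit$history$test_acc[best],
              test_acc_final = fit$history$test_acc[epochs]))
}

#' Write a training history as CSV
#'
#' @param history The `history` data frame from a training run.
#' @param path Output file.
#' @export
write_metrics_csv <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
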