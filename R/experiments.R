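#' Two-neuron gradient-verification experiment
#'
#' The canonical exactness check for event-driven adjoint gradients: neuron
#' A receives `n_inputs` independent Poisson spike trains across random
#' Gaussian weights and drives neuron B through a single feed-forward
#' weight `w`; the loss is the sum of B's spike times. Every weight's
#' adjoint gradient can then be compared against central differences with
#' [gradient_check()].
#'
#' The stimulus statistics follow the published illustration (100 channels
#' at 200 Hz); the weight scale and horizon are chosen so that both neurons
#' fire several times and the base point is non-critical.
#'
#' @param seed Integer seed for the input weights and Poisson trains.
#' @param n_inputs Number of Poisson channels.
#' @param rate_hz Poisson rate per channel (Hz).
#' @param t_end Horizon (ms).
#' @param w Feed-forward weight A -> B.
#' @param in_mean,in_sd Gaussian statistics of the input weights.
#' @param tau_mem,tau_syn Time constants (ms).
#' @return List with `cfg`, `inputs`, and `head` ready for
#'   [eventprop_gradient()] / [gradient_check()].
#' @examples
#' ex <- two_neuron_experiment(seed = 1)
#' chk <- gradient_check(ex$cfg, ex$inputs, ex$head,
#'                       which_rec = cbind(2, 1), eps = 1e-5)
#' chk$rel_error
#' @export
two_neuron_experiment <- function(seed = 1, n_inputs = 100, rate_hz = 200,
                                  t_end = 50, w = 2,
                                  in_mean = 0.07, in_sd = 0.02,
                                  tau_mem = 20, tau_syn = 5) {
  set.seed(seed)
  w_in <- matrix(0, 2, n_inputs)
  w_in[1, ] <- stats::rnorm(n_inputs, in_mean, in_sd)
  w_rec <- matrix(0, 2, 2)
  w_rec[2, 1] <- w
  cfg <- lif_config(w_rec, w_in, tau_mem = tau_mem, tau_syn = tau_syn,
                    t_end = t_end)
  list(cfg = cfg, inputs = poisson_input(n_inputs, rate_hz, t_end),
       head = spike_sum_head(2))
}
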