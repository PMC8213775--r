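#' Network configuration for a leaky integrate-and-fire network
#'
#' Bundles the parameters of the hybrid LIF system: between spikes the
#' membrane potentials `V` and synaptic currents `I` follow
#' \deqn{\tau_{mem} \dot V = -V + I, \qquad \tau_{syn} \dot I = -I,}
#' and when a firing neuron's `V` reaches the threshold (with nonzero slope)
#' its potential is reset to zero and the currents of all neurons jump by the
#' corresponding column of the recurrent weight matrix.
#'
#' The membrane potential is measured in units of the threshold, so the
#' default `threshold = 1` is the natural choice. Time is in milliseconds.
#' Feed-forward architectures are expressed through a block-structured
#' `w_rec`; there is no separate layer engine. Non-firing leaky-integrator
#' readout neurons are declared via `firing = FALSE`: they are excluded from
#' threshold-crossing detection entirely and never reset.
#'
#' @param w_rec N x N recurrent weight matrix; the diagonal must be exactly
#'   zero (no self-connections).
#' @param w_in N x M input weight matrix mapping input channels to neurons.
#'   May have zero columns (`M = 0`) for input-free networks.
#' @param tau_mem Membrane time constant (ms).
#' @param tau_syn Synaptic time constant (ms). Must differ from `tau_mem`;
#'   the degenerate alpha-kernel case is unsupported.
#' @param threshold Firing threshold for the membrane potential.
#' @param firing Logical vector of length N; `FALSE` marks non-firing
#'   leaky-integrator readouts (effectively infinite threshold).
#' @param t_end Simulation horizon T (ms).
#' @param grid Bracketing grid step for threshold-crossing detection (ms).
#'   Defaults to `tau_syn / 20`.
#' @param eps_crit Guard on `|dV/dt|` at a spike: below this a warning about
#'   a near-critical point (diverging gradient) is emitted.
#' @param spike_cap Maximum number of spikes per simulation (runaway guard).
#'
#' @return An object of class `lif_config`.
#' @examples
#' cfg <- lif_config(w_rec = matrix(0, 1, 1), w_in = matrix(1, 1, 1),
#'                   t_end = 50)
#' cfg
#' @export
lif_config <- function(w_rec, w_in,
                       tau_mem = 20, tau_syn = 5, threshold = 1,
                       firing = NULL, t_end = 100,
                       grid = tau_syn / 20,
                       eps_crit = 1e-8, spike_cap = 1e6) {
  w_rec <- as.matrix(w_rec)
  w_in <- as.matrix(w_in)
  n <- nrow(w_rec)
  stopifnot(ncol(w_rec) == n, nrow(w_in) == n)
  if (any(diag(w_rec) != 0))
    stop("w_rec must have an exactly zero diagonal (no self-connections)")
  if (!(tau_mem > 0) || !(tau_syn > 0))
    stop("time constants must be positive")
  if (tau_mem == tau_syn)
    stop("tau_mem == tau_syn (degenerate alpha-kernel) is unsupported")
  if (!(t_end > 0)) stop("t_end must be positive")
  if (is.null(firing)) firing <- rep(TRUE, n)
  stopifnot(length(firing) == n, is.logical(firing))
  structure(
    list(n = n, m = ncol(w_in),
         w_rec = w_rec, w_in = w_in,
         tau_mem = tau_mem, tau_syn = tau_syn, threshold = threshold,
         firing = firing, t_end = t_end,
         grid = grid, eps_crit = eps_crit, spike_cap = spike_cap),
    class = "lif_config")
}

#' @export
print.lif_config <- function(x, ...) {
  cat(sprintf("<lif_config> %d neurons (%d firing), %d input channels\n",
              x$n, sum(x$firing), x$m))
  cat(sprintf("  tau_mem = %g ms, tau_syn = %g ms, threshold = %g, T = %g ms\n",
              x$tau_mem, x$tau_syn, x$threshold, x$t_end))
  invisible(x)
}

#' Save / load a network configuration as YAML + CSV
#'
#' Scalars go into `network.yaml`; the weight matrices are stored as plain
#' CSV files (`w_rec.csv`, `w_in.csv`) next to it, so a saved network is
#' human-inspectable and diff-able.
#'
#' @param cfg An [lif_config()] object.
#' @param dir Directory to write to (created if missing).
#' @return `save_network` returns `dir` invisibly; `load_network` returns the
#'   reconstructed [lif_config()].
#' @export
save_network <- function(cfg, dir) {
  stopifnot(inherits(cfg, "lif_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scalars <- cfg[c("tau_mem", "tau_syn", "threshold", "t_end",
                   "grid", "eps_crit", "spike_cap")]
  scalars$firing <- as.logical(cfg$firing)
  yaml::write_yaml(scalars, file.path(dir, "network.yaml"))
  utils::write.table(cfg$w_rec, file.path(dir, "w_rec.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(cfg$w_in, file.path(dir, "w_in.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname save_network
#' @export
load_network <- function(dir) {
  y <- yaml::read_yaml(file.path(dir, "network.yaml"))
  w_rec <- as.matrix(utils::read.table(file.path(dir, "w_rec.csv"), sep = ","))
  w_in <- as.matrix(utils::read.table(file.path(dir, "w_in.csv"), sep = ","))
  dimnames(w_rec) <- NULL
  dimnames(w_in) <- NULL
  lif_config(w_rec = w_rec, w_in = w_in,
             tau_mem = y$tau_mem, tau_syn = y$tau_syn,
             threshold = y$threshold, firing = as.logical(y$firing),
             t_end = y$t_end, grid = y$grid,
             eps_crit = y$eps_crit, spike_cap = y$spike_cap)
}
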