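#' Input spike trains
#'
#' An input spike train is an ordered set of (time, channel) events that is
#' fed into a network through the columns of the input weight matrix. Times
#' are in milliseconds; channels are 1-based indices into `1..M`.
#'
#' @param times Numeric vector of spike times (ms), any order.
#' @param channels Integer vector of input channel indices, same length.
#' @return A data frame of class `spike_train` with columns `time`,
#'   `channel`, sorted by time (ties keep input order).
#' @examples
#' spike_train(c(3, 1, 2), c(1L, 2L, 1L))
#' @export
spike_train <- function(times = numeric(), channels = integer()) {
  stopifnot(length(times) == length(channels))
  channels <- as.integer(channels)
  if (any(times < 0)) stop("spike times must be non-negative")
  if (length(times) && any(channels < 1L)) stop("channels are 1-based")
  o <- order(times)
  structure(data.frame(time = times[o], channel = channels[o]),
            class = c("spike_train", "data.frame"))
}

#' Merge spike trains
#'
#' @param ... `spike_train` objects.
#' @return A single merged, time-sorted [spike_train()].
#' @export
merge_spike_trains <- function(...) {
  parts <- list(...)
  spike_train(unlist(lapply(parts, `[[`, "time")),
              unlist(lapply(parts, `[[`, "channel")))
}

#' Read / write spike events as CSV
#'
#' The on-disk format is a two-column CSV `time_ms,index`; a spike record's
#' cached pre-reset quantities (`i_minus`, `vdot_minus`) are appended as
#' extra columns when present.
#'
#' @param x A `spike_train` or the `record` data frame from [simulate()].
#' @param path File path.
#' @return `read_spike_csv` returns a [spike_train()].
#' @export
write_spike_csv <- function(x, path) {
  df <- data.frame(time_ms = x$time,
                   index = if (!is.null(x$channel)) x$channel else x$neuron)
  if (!is.null(x$i_minus)) {
    df$i_minus <- x$i_minus
    df$vdot_minus <- x$vdot_minus
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_csv
#' @export
read_spike_csv <- function(path) {
  df <- utils::read.csv(path)
  spike_train(df$time_ms, df$index)
}

#' Poisson spike trains
#'
#' Independent homogeneous Poisson processes, one per channel, on `[0, t_end]`.
#' Used for stimulus generation in gradient-verification experiments.
#'
#' @param n_channels Number of channels.
#' @param rate_hz Firing rate per channel in Hz.
#' @param t_end Interval end (ms).
#' @return A [spike_train()].
#' @export
poisson_input <- function(n_channels, rate_hz, t_end) {
  rate_ms <- rate_hz / 1000
  times <- list()
  chans <- list()
  for (c in seq_len(n_channels)) {
    # expected count + slack, then trim; exact given the RNG state
    n_exp <- rate_ms * t_end
    n_draw <- max(10, ceiling(n_exp + 6 * sqrt(n_exp) + 10))
    isi <- stats::rexp(n_draw, rate_ms)
    tt <- cumsum(isi)
    while (sum(tt) < t_end) { # extremely unlikely; extend
      isi <- c(isi, stats::rexp(n_draw, rate_ms))
      tt <- cumsum(isi)
    }
    tt <- tt[tt <= t_end]
    times[[c]] <- tt
    chans[[c]] <- rep(c, length(tt))
  }
  spike_train(unlist(times), unlist(chans))
}
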