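#' Yin-Yang class membership predicate
#'
#' The Yin-Yang benchmark lives on a disc of radius `r_big` centred at
#' `(r_big, r_big)` in the unit square, split by two interlocking
#' semicircular lobes (of radius `r_big/2`, centred at the left and right
#' "dot" positions) into the yin and yang regions, with two small discs of
#' radius `r_small` on the horizontal midline forming the third class. The
#' constants follow the dataset's reference conventions; this predicate is
#' deterministic in `(x, y)`.
#'
#' @param x,y Coordinates in `[0, 2 * r_big]` (the unit square for the
#'   default radius).
#' @param r_big Disc radius (default 0.5).
#' @param r_small Dot radius (default 0.1).
#' @return Integer class: 1 = yin, 2 = yang, 3 = dot. Vectorized.
#' @export
yinyang_class <- function(x, y, r_big = 0.5, r_small = 0.1) {
  d_right <- sqrt((x - 1.5 * r_big)^2 + (y - r_big)^2)
  d_left <- sqrt((x - 0.5 * r_big)^2 + (y - r_big)^2)
  crit1 <- d_right <= r_small
  crit2 <- d_left > r_small & d_left <= 0.5 * r_big
  crit3 <- y > r_big & d_right > 0.5 * r_big
  is_yin <- crit1 | crit2 | crit3
  is_dot <- d_right < r_small | d_left < r_small
  ifelse(is_dot, 3L, ifelse(is_yin, 1L, 2L))
}

#' Generate a balanced Yin-Yang dataset
#'
#' Rejection-samples points uniformly on the Yin-Yang disc and keeps them
#' in round-robin class order, so the three classes are exactly balanced
#' (`n` is rounded up to a multiple of 3 being unnecessary — the round-robin
#' guarantees counts differ by at most one). Deterministic given `seed`.
#'
#' @param n Number of samples (`> 0`).
#' @param seed Optional integer seed (sets the R RNG).
#' @param r_big,r_small Geometry constants, see [yinyang_class()].
#' @return Data frame with columns `x`, `y`, `label` (integer 1/2/3) and
#'   `class` (factor yin/yang/dot).
#' @examples
#' d <- generate_yinyang(30, seed = 1)
#' table(d$class)
#' @export
generate_yinyang <- function(n, seed = NULL, r_big = 0.5, r_small = 0.1) {
  stopifnot(n > 0)
  if (!is.null(seed)) set.seed(seed)
  x <- numeric(n)
  y <- numeric(n)
  lab <- integer(n)
  for (j in seq_len(n)) {
    goal <- (j - 1L) %% 3L + 1L
    repeat {
      px <- stats::runif(1, 0, 2 * r_big)
      py <- stats::runif(1, 0, 2 * r_big)
      if ((px - r_big)^2 + (py - r_big)^2 > r_big^2) next  # outside the disc
      cl <- yinyang_class(px, py, r_big, r_small)
      if (cl == goal) break
    }
    x[j] <- px
    y[j] <- py
    lab[j] <- goal
  }
  data.frame(x = x, y = y, label = lab,
             class = factor(c("yin", "yang", "dot")[lab],
                            levels = c("yin", "yang", "dot")))
}

#' Latency-encode a Yin-Yang point
#'
#' The point `(x, y)` is expanded to `(x, 1-x, y, 1-y)` and each component
#' `v` becomes one spike at time `v * t_max` on channels 1-4; channel 5
#' carries a fixed bias spike at `t_bias`. Encoding is deterministic and
#' invertible (divide the four latencies by `t_max`).
#'
#' @param x,y Coordinates in `[0, 1]`.
#' @param t_max Latest coordinate latency (ms).
#' @param t_bias Bias spike time (ms).
#' @return A [spike_train()] over 5 channels.
#' @examples
#' encode_yinyang(0.3, 0.6, t_max = 30)
#' @export
encode_yinyang <- function(x, y, t_max = 30, t_bias = 0) {
  stopifnot(x >= 0, x <= 1, y >= 0, y <= 1)
  spike_train(c(c(x, 1 - x, y, 1 - y) * t_max, t_bias), 1:5)
}

#' Latency-encode an MNIST image
#'
#' Each pixel with gray value `v >= 2` (out of 255) produces one spike on
#' its own channel; pixels of value 0 or 1 are not converted to spikes.
#' The default mapping is intensity-to-latency with brighter pixels spiking
#' earlier, `t = t_max * (1 - v/255)`; the direction is a convention (the
#' inverse is available via `bright_early = FALSE`).
#'
#' @param image Numeric vector or matrix of gray values 0-255 (one channel
#'   per pixel, in storage order).
#' @param t_max Encoding interval end (ms).
#' @param bright_early If `TRUE` (default) brighter pixels spike earlier.
#' @return A [spike_train()] over `length(image)` channels.
#' @export
encode_mnist <- function(image, t_max = 20, bright_early = TRUE) {
  v <- as.numeric(image)
  keep <- which(v >= 2)
  frac <- v[keep] / 255
  tt <- if (bright_early) t_max * (1 - frac) else t_max * frac
  spike_train(tt, keep)
}

#' Randomly drop input spikes
#'
#' Each spike is independently removed with probability `p_drop`
#' (training-time regularization). Deterministic given the RNG state.
#'
#' @param train A [spike_train()].
#' @param p_drop Drop probability in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return A [spike_train()].
#' @export
drop_spikes <- function(train, p_drop, seed = NULL) {
  stopifnot(p_drop >= 0, p_drop < 1)
  if (!is.null(seed)) set.seed(seed)
  if (p_drop == 0 || !nrow(train)) return(train)
  keep <- stats::runif(nrow(train)) >= p_drop
  spike_train(train$time[keep], train$channel[keep])
}

#' Read an IDX (MNIST-format) file
#'
#' Reads the standard big-endian IDX container used by the MNIST
#' distribution files; gzip-compressed files are accepted transparently.
#' Only the unsigned-byte element type is supported.
#'
#' @param path Path to an `idx`/`idx-ubyte` file, optionally `.gz`.
#' @return For 1-d files (labels) an integer vector; for 3-d files (images)
#'   an integer array `n x rows x cols`.
#' @export
read_idx <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 4, size = 1, signed = FALSE)
  if (magic[1] != 0 || magic[2] != 0)
    stop("not an IDX file (bad magic bytes)")
  if (magic[3] != 0x08)
    stop("only the unsigned-byte IDX element type is supported")
  ndim <- magic[4]
  dims <- readBin(con, "integer", n = ndim, size = 4, endian = "big")
  data <- readBin(con, "integer", n = prod(dims), size = 1, signed = FALSE)
  if (length(data) != prod(dims)) stop("truncated IDX file")
  if (ndim == 1) return(data)
  # row-major on disk; return n x d1 x d2 ... with natural indexing
  aperm(array(data, dim = rev(dims)), rev(seq_len(ndim)))
}

#' Encode a Yin-Yang data frame for training
#'
#' @param data Data frame from [generate_yinyang()].
#' @param t_max,t_bias See [encode_yinyang()].
#' @return List with `spikes` (list of [spike_train()]) and `label`
#'   (integer vector).
#' @export
encode_yinyang_dataset <- function(data, t_max = 30, t_bias = 0) {
  list(spikes = lapply(seq_len(nrow(data)), function(j)
    encode_yinyang(data$x[j], data$y[j], t_max, t_bias)),
    label = data$label)
}
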