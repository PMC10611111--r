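## Butterworth design, zero-phase filtering and block-average decimation.
## Filter design is done from first principles (analog prototype ->
## band transform -> bilinear transform) because no DSP package is assumed.

#' Band-pass filter specification
#'
#' Defaults reproduce the gait-segmentation preprocessing: a zero-phase
#' 0.5--5 Hz fourth-order Butterworth band-pass.
#'
#' @param band numeric length-2, pass band in Hz (low, high).
#' @param order Butterworth prototype order per pass (the band-pass
#'   transform doubles the pole count).
#' @param zero_phase logical; apply forward-backward for zero net delay.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(band = c(0.5, 5), order = 4L, zero_phase = TRUE) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1], order >= 1)
  structure(list(band = as.numeric(band), order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# polynomial coefficients (descending powers) from complex roots
.poly_from_roots <- function(r) {
  p <- complex(real = 1)
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# digital Butterworth band-pass via bilinear transform; returns list(b, a)
.butter_bandpass <- function(order, band, fs) {
  if (band[2] >= fs / 2) {
    stop("band infeasible for fs: high cutoff ", band[2],
         " Hz >= Nyquist ", fs / 2, " Hz")
  }
  n <- order
  # prewarped analog edge frequencies (rad/s)
  w1 <- 2 * fs * tan(pi * band[1] / fs)
  w2 <- 2 * fs * tan(pi * band[2] / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  # analog low-pass prototype poles on the unit circle, left half plane
  k <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # low-pass -> band-pass: each pole splits into two
  half <- p_lp * bw / 2
  p_bp <- c(half + sqrt(half^2 - w0^2), half - sqrt(half^2 - w0^2))
  # bilinear transform
  fs2 <- 2 * fs
  z_p <- (fs2 + p_bp) / (fs2 - p_bp)
  z_z <- c(rep(1, n), rep(-1, n))   # s = 0 -> z = 1; s = Inf -> z = -1
  b <- Re(.poly_from_roots(z_z))
  a <- Re(.poly_from_roots(z_p))
  # unit gain at the (digital) centre frequency
  wc <- 2 * atan(w0 / fs2)
  zc <- exp(1i * wc)
  h <- sum(b * zc^(-(seq_along(b) - 1))) / sum(a * zc^(-(seq_along(a) - 1)))
  list(b = b / Mod(h), a = a)
}

# digital Butterworth low-pass (used for trunk/thigh smoothing)
.butter_lowpass <- function(order, cutoff, fs) {
  if (cutoff >= fs / 2) stop("cutoff >= Nyquist")
  n <- order
  wc <- 2 * fs * tan(pi * cutoff / fs)
  k <- seq_len(n)
  p <- wc * exp(1i * pi * (2 * k + n - 1) / (2 * n))
  fs2 <- 2 * fs
  z_p <- (fs2 + p) / (fs2 - p)
  b <- Re(.poly_from_roots(rep(-1, n)))
  a <- Re(.poly_from_roots(z_p))
  list(b = b * sum(a) / sum(b), a = a)   # unit DC gain
}

# steady-state initial filter state for a unit step (lfilter_zi construction):
# starting each pass from this state (scaled by the first sample) removes
# the startup transient, so constant inputs map to exactly zero output
.filter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  a0 <- a[1]
  a <- c(a, rep(0, nf - length(a))) / a0
  b <- c(b, rep(0, nf - length(b))) / a0
  n <- nf - 1L
  if (n == 0) return(numeric(0))
  # companion matrix of a, transposed
  A <- rbind(-a[2:nf], cbind(diag(1, n - 1), 0))
  B <- b[2:nf] - a[2:nf] * b[1]
  solve(diag(1, n) - t(A), B, tol = 0)
}

# forward-backward filtering with odd-reflection padding
.filtfilt <- function(b, a, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad > 0) {
    pre <- 2 * x[1] - x[seq(pad + 1, 2)]
    post <- 2 * x[n] - x[seq(n - 1, n - pad)]
    xp <- c(pre, x, post)
  } else xp <- x
  zi <- .filter_zi(b, a)
  y <- .iir_filter_cpp(b, a, xp, zi * xp[1])
  y <- rev(y)
  y <- rev(.iir_filter_cpp(b, a, y, zi * y[1]))
  if (pad > 0) y <- y[seq(pad + 1, pad + n)]
  y
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero net group delay) Butterworth band-pass of a single
#' channel, with 3 s odd-reflection padding to suppress edge transients.
#' DC is rejected by the band-pass structure.
#'
#' @param x numeric vector, one channel.
#' @param fs sampling rate in Hz; must exceed twice the upper band edge.
#' @param spec a [filter_spec()].
#' @return Filtered numeric vector, same length as `x`.
#' @export
bandpass_zero_phase <- function(x, fs, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"), is.numeric(x), fs > 0)
  if (fs <= 2 * spec$band[2]) {
    stop("band infeasible for fs: need fs > ", 2 * spec$band[2], " Hz")
  }
  ba <- .butter_bandpass(spec$order, spec$band, fs)
  pad <- as.integer(round(3 * fs))
  if (spec$zero_phase) {
    .filtfilt(ba$b, ba$a, x, pad)
  } else {
    .iir_filter_cpp(ba$b, ba$a, x)
  }
}

# zero-phase low-pass convenience (generator + trunk mixing)
.lowpass_zero_phase <- function(x, fs, cutoff, order = 2L) {
  ba <- .butter_lowpass(order, cutoff, fs)
  .filtfilt(ba$b, ba$a, x, as.integer(round(fs)))
}

#' Decimation by block averaging
#'
#' Averages consecutive non-overlapping blocks of `factor` samples,
#' reducing the rate to `fs / factor`. For white noise this attenuates the
#' noise SD by `sqrt(factor)`; the default pipeline factor of 16 gains two
#' bits of effective resolution (4x SD reduction). Trailing samples that do
#' not fill a block are dropped.
#'
#' @param x numeric vector.
#' @param factor integer >= 1.
#' @return Numeric vector of block means, length `floor(length(x)/factor)`.
#' @export
decimate_denoise <- function(x, factor = 16L) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop("decimation factor must be >= 1")
  if (factor == 1L) return(x)
  n <- (length(x) %/% factor) * factor
  if (n == 0) stop("signal shorter than one decimation block")
  colMeans(matrix(x[seq_len(n)], nrow = factor))
}
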