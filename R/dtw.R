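## Dynamic time warping and the participant mean cycle.

#' Dynamic time warping distance
#'
#' Classical DTW with absolute-difference local cost, steps
#' match/insert/delete, no warping window, and unnormalized accumulated
#' cost (so distances scale with amplitude and length, consistent with
#' reporting variability in the hundreds for dps-scale cycles). Symmetric
#' in its arguments.
#'
#' @param a,b non-empty numeric vectors.
#' @return Non-negative scalar distance.
#' @export
dtw_distance <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("dtw_distance: empty sequence")
  .dtw_cpp(as.numeric(a), as.numeric(b))
}

# linear resampling to a fixed length
.resample <- function(x, n_out = 100L) {
  if (length(x) == 1L) return(rep(as.numeric(x), n_out))
  approx(seq(0, 1, length.out = length(x)), x,
         xout = seq(0, 1, length.out = n_out))$y
}

# pull a named channel out of a gait_cycle
.cycle_channel <- function(cycle, channel) {
  switch(channel,
         shank_ml = cycle$shank_ml_filt,
         thigh_ml = cycle$thigh_ml_filt,
         shank_ml_raw = cycle$shank_gyro[, 2],
         thigh_ml_raw = cycle$thigh_gyro[, 2],
         stop("unknown channel: ", channel))
}

#' Participant mean cycle
#'
#' Linearly resamples each cycle's channel to a fixed length (100 samples)
#' and takes the pointwise arithmetic mean: the reference waveform for the
#' DTW distance-to-mean variability features.
#'
#' @param cycles non-empty list of `gait_cycle` objects.
#' @param channel "shank_ml" or "thigh_ml" (band-passed mediolateral gyro).
#' @param n_samples reference length.
#' @return Object of class `mean_cycle` (`$waveform`, `$channel`).
#' @export
mean_cycle <- function(cycles, channel = "shank_ml", n_samples = 100L) {
  if (length(cycles) == 0) stop("mean_cycle: empty cycle list")
  m <- vapply(cycles, function(cy) .resample(.cycle_channel(cy, channel), n_samples),
              numeric(n_samples))
  structure(list(waveform = rowMeans(m), channel = channel,
                 n_samples = as.integer(n_samples)),
            class = "mean_cycle")
}

#' DTW distance of one cycle to the participant mean
#'
#' Defines the `{G,TG}_DIS_DTW_MEAN_{SHANK,THIGH}` features: the cycle's
#' mediolateral gyro channel is resampled to the reference length and its
#' unnormalized DTW distance to the mean waveform is returned.
#'
#' @param cycle a `gait_cycle`.
#' @param ref a [mean_cycle()].
#' @return Non-negative scalar.
#' @export
dtw_to_mean <- function(cycle, ref) {
  stopifnot(inherits(ref, "mean_cycle"))
  dtw_distance(.resample(.cycle_channel(cycle, ref$channel), ref$n_samples),
               ref$waveform)
}
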