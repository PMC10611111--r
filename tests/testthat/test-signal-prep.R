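make_rec <- function(n = 512, fs = 256, accel = NULL, gyro = NULL, t0 = 0) {
  t <- t0 + (seq_len(n) - 1) / fs
  if (is.null(accel)) accel <- cbind(rep(1, n), rnorm(n, 0, .01), rnorm(n, 0, .01))
  if (is.null(gyro)) gyro <- matrix(rnorm(3 * n), n, 3)
  imu_recording("shank_R", "gait", t, accel, gyro, fs = fs)
}

test_that("standardize_axes: identity, involution, round-trip, norm preservation", {
  set.seed(1)
  rec <- make_rec()
  expect_identical(standardize_axes(rec, c(1, 2, 3)), rec)
  swapped_twice <- standardize_axes(standardize_axes(rec, c(2, 1, 3)), c(2, 1, 3))
  expect_identical(swapped_twice$gyro, rec$gyro)
  # scramble with a known signed mapping, then undo it (the scrambled
  # intermediate legitimately trips the gravity check)
  scr <- suppressWarnings(standardize_axes(rec, c(3, -1, 2)))
  back <- standardize_axes(scr, c(-2, 3, 1))  # inverse mapping
  expect_identical(back$accel, rec$accel)
  expect_identical(back$gyro, rec$gyro)
  # per-sample vector norms are invariant
  expect_equal(rowSums(scr$gyro^2), rowSums(rec$gyro^2))
  expect_error(standardize_axes(rec, c(1, 1, 3)), "permutation")
  expect_warning(standardize_axes(rec, c(-1, 2, 3)), "gravity")
})

test_that("synchronize_recordings crops to a shared window on each grid", {
  set.seed(2)
  a <- make_rec(n = 256 * 6, t0 = 0)
  b <- make_rec(n = 256 * 6, t0 = 0.5)  # device clock offset
  out <- synchronize_recordings(list(a = a, b = b), 1, 5)
  expect_equal(range(out$a$t), c(1, 5), tolerance = 1 / 256)
  expect_equal(diff(range(out$b$t)), 4, tolerance = 2 / 256)
  expect_lt(abs(out$a$t[1] - out$b$t[1]), 1 / 256)
  # full span: unchanged
  full <- synchronize_recordings(list(a = a), 0, a$t[length(a$t)])
  expect_identical(full$a$gyro, a$gyro)
  expect_error(synchronize_recordings(list(a = a), 5, 1), "start < end")
  expect_error(synchronize_recordings(list(a = a, b = b), 0, 5.9),
               "shank_R")
})

test_that("decimate_denoise: block means, identity, noise reduction", {
  expect_equal(decimate_denoise(rep(3.5, 64), 16), rep(3.5, 4))
  x <- rnorm(100)
  expect_identical(decimate_denoise(x, 1), x)
  expect_error(decimate_denoise(x, 0), "factor")
  # mean conserved exactly for factor-divisible lengths
  set.seed(3)
  y <- rnorm(1600)
  expect_equal(mean(decimate_denoise(y, 16)), mean(y))
  # white noise SD reduced ~4x at factor 16 (two extra bits)
  set.seed(4)
  z <- rnorm(160000, sd = 2)
  expect_lt(abs(sd(decimate_denoise(z, 16)) - 2 / 4) / (2 / 4), 0.10)
})

test_that("bandpass_zero_phase: pass band, DC rejection, stop band, zero lag", {
  fs <- 256
  t <- (0:(fs * 10 - 1)) / fs
  spec <- filter_spec()
  # in-band 2 Hz sinusoid: peaks shifted by less than one sample
  x <- sin(2 * pi * 2 * t)
  y <- bandpass_zero_phase(x, fs, spec)
  mid <- seq(fs, length(x) - fs)
  one_cycle <- seq(5 * fs, 5.5 * fs)  # exactly one 2 Hz peak
  expect_lt(abs(which.max(x[one_cycle]) - which.max(y[one_cycle])), 1 + 1e-9)
  # cross-correlation lag between input and output is 0
  lags <- -5:5
  cc <- vapply(lags, function(L) {
    i <- seq(fs * 2, fs * 8)
    sum(x[i] * y[i + L])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 0)
  # constant input -> zero output after edge trim
  yc <- bandpass_zero_phase(rep(5, fs * 10), fs, spec)
  expect_lt(max(abs(yc[mid])), 1e-6)
  # far-below-band 0.05 Hz sinusoid: attenuated > 90%
  xs <- sin(2 * pi * 0.05 * (0:(fs * 60 - 1)) / fs)
  ys <- bandpass_zero_phase(xs, fs, spec)
  core <- seq(fs * 20, fs * 40)
  expect_lt(max(abs(ys[core])), 0.1)
  expect_error(bandpass_zero_phase(x, fs = 8, spec), "infeasible")
})

test_that("band-pass frequency response matches the reference gain formula", {
  ba <- gaitcoord:::.butter_bandpass(4, c(0.5, 5), 16)
  expect_equal(freq_gain(ba$b, ba$a, sqrt(0.5 * 5), 16), 1, tolerance = 1e-6)
  expect_equal(freq_gain(ba$b, ba$a, 0.5, 16), sqrt(0.5), tolerance = 1e-6)
  expect_equal(freq_gain(ba$b, ba$a, 5, 16), sqrt(0.5), tolerance = 1e-6)
  expect_lt(freq_gain(ba$b, ba$a, 0.05, 16), 0.001)
})
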