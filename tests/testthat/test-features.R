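test_that("dtw_distance matches hand-derived and brute-force values", {
  expect_equal(dtw_distance(c(0, 1, 2), c(0, 1, 2)), 0)
  expect_equal(dtw_distance(c(0, 1, 2), c(0, 2)), 1)
  expect_equal(dtw_distance(5, 3), 2)
  expect_error(dtw_distance(numeric(0), 1), "empty")
  set.seed(10)
  for (i in 1:40) {
    a <- round(rnorm(sample(1:6, 1)), 2)
    b <- round(rnorm(sample(1:6, 1)), 2)
    expect_equal(dtw_distance(a, b), dtw_brute_force(a, b), tolerance = 1e-9)
    expect_equal(dtw_distance(a, b), dtw_distance(b, a))
    expect_gte(dtw_distance(a, b), 0)
  }
})

test_that("mean_cycle averages resampled cycles and handles degenerate input", {
  deg <- degenerate_participant()
  # noise-free, jitter-free, cv-0 cycles are exact template repetitions
  # within a side (the two sides sit at different sub-sample phases, and
  # the zero-phase IIR leaves slowly decaying onset transients on the
  # filtered stream, so the exactness claim is checked on the raw channel)
  for (s in c("L", "R")) {
    cyc_s <- Filter(function(cy) cy$side == s, deg$seg$gait$cycles)
    mc_s <- mean_cycle(cyc_s, "shank_ml_raw")
    for (cy in cyc_s) expect_lt(dtw_to_mean(cy, mc_s), 1e-9)
  }
  cyc <- deg$seg$gait$cycles
  mc <- mean_cycle(cyc, "shank_ml")
  expect_length(mc$waveform, 100)
  # a single cycle's mean is that cycle resampled
  mc1 <- mean_cycle(cyc[1], "shank_ml")
  expect_equal(mc1$waveform,
               gaitcoord:::.resample(cyc[[1]]$shank_ml_filt, 100))
  # x and -x average to zero
  cy2 <- cyc[[1]]
  cy2$shank_ml_filt <- -cy2$shank_ml_filt
  expect_equal(max(abs(mean_cycle(list(cyc[[1]], cy2), "shank_ml")$waveform)),
               0, tolerance = 1e-12)
  expect_error(mean_cycle(list()), "empty")
})

test_that("dtw_to_mean grows when a cycle is rescaled away from the mean", {
  op <- one_participant()
  cyc <- op$seg$gait$cycles
  mc <- mean_cycle(cyc, "shank_ml")
  d1 <- dtw_to_mean(cyc[[1]], mc)
  big <- cyc[[1]]
  big$shank_ml_filt <- 2 * big$shank_ml_filt
  expect_gt(dtw_to_mean(big, mc), d1)
})

test_that("curvature of a circular angular-velocity trajectory is 1/r", {
  fs <- 256
  t <- (0:(2 * fs - 1)) / fs
  r <- 100
  w <- cbind(r * cos(2 * pi * 1.5 * t), r * sin(2 * pi * 1.5 * t), 0)
  cy <- make_cycle(n = length(t), shank_gyro = w)
  expect_equal(curvature_feature(cy, "shank"), 1 / r, tolerance = 0.02)
  # straight-line trajectory: curvature ~ 0
  line <- cbind(t * 50, t * 30, t * 10)
  expect_lt(curvature_feature(make_cycle(n = length(t), shank_gyro = line), "shank"),
            1e-6)
  # constant trajectory: 0 by convention
  const <- matrix(5, length(t), 3)
  expect_equal(curvature_feature(make_cycle(n = length(t), shank_gyro = const), "shank"), 0)
})

test_that("hip flexion-extension range recovers a known thigh oscillation", {
  fs <- 256
  n <- 4 * fs
  t <- (0:(n - 1)) / fs
  # thigh pitch +/-15 deg at 1 Hz about a static pelvis
  theta <- 15 * sin(2 * pi * t)
  gyro_ml <- 15 * 2 * pi * cos(2 * pi * t)      # deg/s, analytic derivative
  th_rad <- theta * pi / 180
  cy <- make_cycle(n = n,
                   thigh_gyro = cbind(0, gyro_ml, 0),
                   thigh_accel = cbind(cos(th_rad), 0, sin(th_rad)))
  expect_equal(hip_flexion_extension_range(cy), 30, tolerance = 3)
  # zero gyro and constant accel: range 0
  expect_lt(hip_flexion_extension_range(make_cycle(n = n)), 1e-9)
  # identical thigh and pelvis motion cancels
  cy2 <- make_cycle(n = n,
                    thigh_gyro = cbind(0, gyro_ml, 0),
                    thigh_accel = cbind(cos(th_rad), 0, sin(th_rad)),
                    trunk_gyro = cbind(0, gyro_ml, 0),
                    trunk_accel = cbind(cos(th_rad), 0, sin(th_rad)))
  expect_lt(hip_flexion_extension_range(cy2), 1)
  # misaligned cycles are rejected
  off <- make_cycle(n = n, start_s = 0.5)
  expect_error(hip_flexion_extension_range(cy, off), "misaligned")
})

test_that("spatiotemporal features: arithmetic and pendulum consistency", {
  cy <- make_cycle(n = 307)  # 1.199 s at 256 Hz
  st <- spatiotemporal_features(cy)
  expect_equal(st$stride_t, 307 / 256)
  expect_equal(st$cadence, 120 / (307 / 256))
  expect_equal(st$stride_len, 0)  # zero rotation
  expect_equal(st$stance_t + st$swing_t, st$stride_t, tolerance = 1e-9)
  # generator ground truth: estimated stride length within 15%
  op <- one_participant()
  est <- vapply(op$seg$gait$cycles, function(cy)
    spatiotemporal_features(cy)$stride_len, numeric(1))
  gt <- c(op$p$ground_truth$gait$L$stride_length,
          op$p$ground_truth$gait$R$stride_length)
  expect_lt(abs(median(est) - median(gt)) / median(gt), 0.15)
})

test_that("trunk regularity: periodic ~ 1, white noise ~ 0, RMS as defined", {
  fs <- 256
  n <- 16 * fs
  stride_s <- 1.0
  periodic <- sin(2 * pi * (0:(n - 1)) / (fs * stride_s / 2))  # step-periodic
  cy <- make_cycle(n = fs)
  tr <- trunk_and_regularity_features(cy, periodic, periodic, fs,
                                      step_lag_s = stride_s / 2,
                                      stride_lag_s = stride_s)
  expect_equal(tr$stride_reg, 1, tolerance = 0.1)
  expect_equal(tr$step_reg, 1, tolerance = 0.1)
  set.seed(20)
  noise <- rnorm(n)
  trn <- trunk_and_regularity_features(cy, noise, noise, fs,
                                       step_lag_s = 0.5, stride_lag_s = 1)
  expect_lt(abs(trn$stride_reg), 0.1)
  v <- cy$trunk_accel[, 1]
  expect_equal(tr$rms_v, sqrt(mean((v - mean(v))^2)))
})

test_that("build_feature_row assembles exactly the 36-name catalogue", {
  cat36 <- feature_catalog()
  expect_length(cat36, 36)
  expect_false(any(duplicated(cat36)))
  expect_true(all(c("G_RHFE", "G_CURV_SHANK",
                    "TG_DIS_DTW_MEAN_THIGH", "TG_DIS_DTW_MEAN_SHANK") %in% cat36))
  expect_equal(sum(startsWith(cat36, "TG_")), 12)
  op <- one_participant()
  row <- build_feature_row(op$seg$gait$cycles[[1]], op$seg$tandem$cycles[[1]],
                           op$fe$context)
  expect_named(row, cat36)
  expect_true(all(is.finite(row)))
  expect_error(build_feature_row(op$seg$gait$cycles[[1]],
                                 op$seg$gait$cycles[[2]], op$fe$context),
               "tandem")
})

test_that("feature invariants: ranges nonnegative, times positive, finite", {
  fe <- one_participant()$fe
  rngs <- c("G_RNG_GYRO_ML_SHANK", "G_RNG_GYRO_ML_THIGH", "G_RHFE",
            "G_RNG_PITCH_SHANK", "G_RNG_PITCH_THIGH")
  expect_true(all(fe$gait[, rngs] >= 0))
  expect_true(all(fe$gait[, c("G_STRIDE_T", "G_STANCE_T", "G_SWING_T")] > 0))
  expect_true(all(is.finite(fe$gait)))
  expect_true(all(is.finite(fe$tandem)))
  expect_true(all(fe$tandem[, "TG_CYCLE_T"] > 0))
})

test_that("more waveform jitter never lowers the median DTW-to-mean features", {
  jit <- c(0.04, 0.12, 0.28)
  meds <- vapply(jit, function(j) {
    spec <- cohort_spec(waveform_jitter = c(EOA = j, DCD = j, CTRL = j),
                        seed = 31L)
    p <- simulate_participant(spec, "CTRL", "PJ", seed = 31L)
    seg <- segment_participant(p$recordings)
    fe <- extract_features("PJ", "CTRL", seg)
    median(fe$tandem[, "TG_DIS_DTW_MEAN_SHANK"])
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})
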