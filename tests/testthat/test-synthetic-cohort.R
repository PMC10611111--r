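test_that("cohort_spec validates its inputs", {
  expect_s3_class(cohort_spec(), "cohort_spec")
  expect_error(cohort_spec(group_sizes = c(EOA = 0L, DCD = 1L, CTRL = 1L)),
               "counts")
  expect_error(cohort_spec(cycle_duration_mean = c(EOA = -1, DCD = 1, CTRL = 1)),
               "cycle_duration_mean")
  expect_error(cohort_spec(cycle_duration_cv = c(EOA = -0.1, DCD = 0, CTRL = 0)))
  expect_error(cohort_spec(waveform_jitter = c(EOA = 0.1, DCD = 0.2, CTRL = 0.3)),
               "ordered")
  expect_error(cohort_spec(sensor_noise_sd = c(gyro = -1, accel = 0.01)))
})

test_that("simulate_participant emits six 256 Hz recordings per test with ordered events", {
  spec <- cohort_spec(n_cycles_gait = 12L, cycle_duration_mean = c(EOA = 1.1, DCD = 1.1, CTRL = 1.1))
  p <- simulate_participant(spec, "CTRL", "P1", seed = 11L)
  for (test in c("gait", "tandem")) {
    recs <- p$recordings[[test]]
    expect_named(recs, c("sternum", "L3", "thigh_L", "thigh_R", "shank_L", "shank_R"))
    for (r in recs) {
      expect_s3_class(r, "imu_recording")
      expect_equal(median(diff(r$t)), 1 / 256, tolerance = 1e-12)
      expect_equal(r$fs, 256)
    }
    for (s in c("L", "R")) {
      gt <- p$ground_truth[[test]][[s]]
      # within each cycle: toe-off < mid-swing < heel-strike
      expect_true(all(gt$toe_off < gt$mid_swing))
      expect_true(all(gt$mid_swing < gt$heel_strike))
      expect_true(all(diff(gt$mid_swing) > 0))
      expect_true(all(diff(gt$toe_off) > 0))
    }
  }
  # 12 gait cycles drawn near 1.1 s each, 1 s lead-in and tail
  gt <- p$ground_truth$gait$R
  expect_length(gt$mid_swing, 12)
  dur <- max(p$recordings$gait$shank_R$t)
  expect_lt(abs(dur - (2 + 12 * 1.1)), 1.5)
})

test_that("simulate_cohort respects group sizes and is seed-deterministic", {
  cohort <- small_cohort()
  expect_equal(nrow(cohort$manifest), 6)
  expect_equal(as.vector(table(cohort$manifest$group)[c("EOA", "DCD", "CTRL")]),
               c(2, 2, 2))
  p1 <- simulate_participant(small_spec(), "EOA", "EOA01")
  p2 <- simulate_participant(small_spec(), "EOA", "EOA01")
  expect_identical(p1, p2)
  expect_identical(cohort$participants$EOA01$recordings$gait$shank_L$gyro,
                   p1$recordings$gait$shank_L$gyro)
})

test_that("empirical duration CV converges to the specified CV", {
  spec <- cohort_spec(n_cycles_gait = 220L,
                      cycle_duration_cv = c(EOA = 0.09, DCD = 0.07, CTRL = 0.05))
  p <- simulate_participant(spec, "EOA", "PCV", seed = 123L)
  d <- c(p$ground_truth$gait$L$cycle_duration, p$ground_truth$gait$R$cycle_duration)
  cv <- sd(d) / mean(d)
  expect_lt(abs(cv - 0.09) / 0.09, 0.20)
})

test_that("degenerate spec (no noise, no jitter, cv 0) repeats the template exactly", {
  deg <- degenerate_participant()
  gt <- deg$p$ground_truth$gait$R
  expect_equal(diff(gt$mid_swing), rep(1, length(gt$mid_swing) - 1),
               tolerance = 1e-12)
  ml <- deg$p$recordings$gait$shank_R$gyro[, 2]
  # consecutive cycles are bit-identical 256-sample blocks
  i0 <- which.min(abs(deg$p$recordings$gait$shank_R$t - gt$cycle_start[2]))
  c1 <- ml[i0:(i0 + 255)]
  c2 <- ml[(i0 + 256):(i0 + 511)]
  expect_equal(c1, c2, tolerance = 1e-12)
})

test_that("cohort round-trips through CSV + JSON on disk", {
  dir <- withr::local_tempdir()
  cohort <- list(participants = small_cohort()$participants["EOA01"],
                 manifest = small_cohort()$manifest[1, , drop = FALSE])
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- read_cohort(dir)
  r0 <- cohort$participants$EOA01$recordings$gait$shank_R
  r1 <- back$participants$EOA01$recordings$gait$shank_R
  expect_equal(r1$gyro, r0$gyro, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(r1$t, r0$t, tolerance = 1e-9)
})
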