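# build a clean shank-pattern signal at a given rate from event times
template_signal <- function(t, ms, amp = 200, valley_off = 0.22, width = 0.12) {
  x <- numeric(length(t))
  bump <- function(x, c0, w, a) {
    i <- which(abs(t - c0) < w)
    x[i] <- x[i] + 0.5 * a * (1 + cos(pi * (t[i] - c0) / w))
    x
  }
  for (m in ms) {
    x <- bump(x, m, width, amp)
    x <- bump(x, m - valley_off, 0.08, -0.35 * amp)
    x <- bump(x, m + valley_off, 0.08, -0.35 * amp)
  }
  x
}

test_that("detect_events finds template triplets at decimated resolution", {
  fs_dec <- 16
  t <- (0:(8 * fs_dec - 1)) / fs_dec
  ms_true <- c(2.0, 3.1, 4.2, 5.3)
  x <- template_signal(t, ms_true)
  ev <- detect_events(x, fs_dec, t0 = 0)
  expect_s3_class(ev, "gait_events")
  expect_length(ev$mid_swing, 4)
  expect_true(all(ev$complete_cycle))
  # block-centre convention: within one decimated sample of the truth
  expect_true(all(abs(ev$mid_swing - ms_true) <= 1 / fs_dec + 1e-9))
  expect_true(all(abs(ev$toe_off - (ms_true - 0.22)) <= 1 / fs_dec + 1e-9))
  expect_true(all(abs(ev$heel_strike - (ms_true + 0.22)) <= 1 / fs_dec + 1e-9))
  expect_true(all(ev$toe_off < ev$mid_swing & ev$mid_swing < ev$heel_strike))
})

test_that("all-zero and degenerate signals are handled", {
  expect_error(detect_events(numeric(0), 16), "empty")
  ev <- detect_events(numeric(64), 16)
  expect_equal(ev$n_peaks, 0)
  expect_length(ev$mid_swing, 0)
})

test_that("a valley outside the 0.5 s search window marks the cycle incomplete", {
  fs_dec <- 16
  t <- (0:(10 * fs_dec - 1)) / fs_dec
  # toe-off valley displaced to 0.6 s before mid-swing
  x <- template_signal(t, 3.0, valley_off = 0.22)
  far <- template_signal(t, 6.0, valley_off = 0.22)
  # rebuild the 6.0 s cycle with its pre-peak valley at -0.6 s
  far <- numeric(length(t))
  bump <- function(x, c0, w, a) {
    i <- which(abs(t - c0) < w)
    x[i] <- x[i] + 0.5 * a * (1 + cos(pi * (t[i] - c0) / w))
    x
  }
  far <- bump(far, 6.0, 0.12, 200)
  far <- bump(far, 6.0 - 0.6, 0.08, -70)
  far <- bump(far, 6.0 + 0.22, 0.08, -70)
  ev <- detect_events(x + far, fs_dec, t0 = 0)
  expect_equal(ev$n_peaks, 2)
  ok <- which(abs(ev$mid_swing - 3.0) < 0.1)
  bad <- which(abs(ev$mid_swing - 6.0) < 0.1)
  expect_true(ev$complete_cycle[ok])
  expect_false(ev$complete_cycle[bad])
})

test_that("delineate_cycles: fencepost counts and gap handling", {
  deg <- degenerate_participant()
  seg <- deg$seg
  # 12 complete triplets per side -> 11 heel-strike..heel-strike gait cycles
  evR <- seg$gait$events$R
  expect_equal(sum(evR$complete_cycle), 12)
  cyc <- delineate_cycles(evR, "gait", seg$gait$recs)
  expect_length(cyc, 11)
  # tandem: toe-off..toe-off
  evT <- seg$tandem$events$R
  cyT <- delineate_cycles(evT, "tandem", seg$tandem$recs)
  expect_length(cyT, sum(evT$complete_cycle) - 1)
  expect_true(all(vapply(cyT, function(cy) {
    abs(cy$start_s - evT$toe_off[which.min(abs(evT$toe_off - cy$start_s))]) < 1e-9
  }, logical(1))))
  # knock out a middle triplet: both bridging cycles are dropped
  ev2 <- evR
  ev2$complete_cycle[6] <- FALSE
  cyc2 <- delineate_cycles(ev2, "gait", seg$gait$recs)
  expect_length(cyc2, 9)
  starts <- vapply(cyc2, function(cy) cy$start_s, numeric(1))
  ends <- vapply(cyc2, function(cy) cy$end_s, numeric(1))
  o <- order(starts)
  expect_true(all(ends[o][-length(ends)] <= starts[o][-1] + 1e-9))
})

test_that("quality_gate applies the completeness thresholds", {
  ev <- structure(list(side = "R", n_peaks = 10L,
                       complete_cycle = rep(c(TRUE, FALSE), c(9, 1)),
                       mid_swing = 1:10, toe_off = 1:10, heel_strike = 1:10,
                       fs_dec = 16), class = "gait_events")
  expect_true(quality_gate(ev)$pass)
  ev$complete_cycle <- rep(c(TRUE, FALSE), c(3, 7))
  g <- quality_gate(ev)
  expect_false(g$pass)
  expect_match(g$reason, "rate")
  ev$complete_cycle <- rep(c(TRUE, FALSE), c(2, 8))
  g2 <- quality_gate(ev)
  expect_false(g2$pass)
  expect_match(g2$reason, "complete cycles")
})

test_that("detected cycle count never exceeds ground truth + 1 on the small cohort", {
  cohort <- small_cohort()
  for (id in names(cohort$participants)[c(1, 3, 5)]) {
    p <- cohort$participants[[id]]
    seg <- segment_participant(p$recordings)
    for (test in c("gait", "tandem")) {
      for (s in c("L", "R")) {
        n_det <- sum(seg[[test]]$events[[s]]$complete_cycle)
        n_true <- length(p$ground_truth[[test]][[s]]$mid_swing)
        expect_lte(n_det, n_true + 1)
      }
    }
  }
})
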