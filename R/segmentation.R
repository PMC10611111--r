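## Gait event detection on shank mediolateral angular velocity and cycle
## delineation. Detection runs on the decimated (16 Hz) band-passed
## channel; event times are reported on the recording time base using
## block-centre timestamps, without sub-sample refinement.

# local maxima with topographic prominence
.find_peaks <- function(x) {
  n <- length(x)
  if (n < 3) return(data.frame(idx = integer(0), prominence = numeric(0)))
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  prom <- vapply(idx, function(i) {
    h <- x[i]
    lmin <- h; j <- i - 1L
    while (j >= 1 && x[j] <= h) { if (x[j] < lmin) lmin <- x[j]; j <- j - 1L }
    rmin <- h; j <- i + 1L
    while (j <= n && x[j] <= h) { if (x[j] < rmin) rmin <- x[j]; j <- j + 1L }
    h - max(lmin, rmin)
  }, numeric(1))
  data.frame(idx = idx, prominence = prom)
}

# minimum inside an open window, ties broken toward the sample nearest the
# peak; returns NA when the minimum sits on the window's outer edge or is
# not a genuine valley (non-negative)
.window_valley <- function(x, from, to, toward) {
  if (from > to) return(NA_integer_)
  w <- x[from:to]
  cand <- which(w == min(w))
  i <- if (toward == "right") max(cand) else min(cand)
  idx <- from + i - 1L
  outer_edge <- if (toward == "right") from else to
  if (idx == outer_edge && length(w) > 1) return(NA_integer_)
  if (x[idx] >= 0) return(NA_integer_)
  idx
}

#' Detect gait events on a shank mediolateral angular-velocity channel
#'
#' Mid-swing events are the positive local maxima with prominence at least
#' `min_prominence`; toe-off is the minimum in the 0.5 s window before each
#' peak and heel-strike the minimum in the 0.5 s window after it. A cycle
#' is flagged complete only when all three events are found; valleys that
#' land on the window's outer edge, are non-negative, or fall beyond a
#' neighbouring mid-swing are treated as not found.
#'
#' @param ml_gyro numeric vector: decimated and band-pass-filtered
#'   mediolateral shank gyro.
#' @param fs_dec sampling rate of `ml_gyro` in Hz (16 for the default
#'   pipeline).
#' @param min_prominence peak prominence threshold in dps; `NULL` uses the
#'   adaptive rule 0.5 x (95th percentile of the positive signal).
#' @param side "L" or "R" (carried through to the events object).
#' @param t0 time of the first block's start on the recording time base;
#'   event times are `t0 + (idx - 0.5) / fs_dec` (block centres).
#' @param search_window_s half-window for the valley search (0.5 s).
#' @return Object of class `gait_events`: vectors `mid_swing`, `toe_off`,
#'   `heel_strike` (seconds; `NA` where not found), logical
#'   `complete_cycle`, plus `side`, `fs_dec`, `n_peaks`.
#' @export
detect_events <- function(ml_gyro, fs_dec, min_prominence = NULL,
                          side = "R", t0 = 0, search_window_s = 0.5) {
  if (length(ml_gyro) == 0) stop("empty signal")
  if (length(ml_gyro) < 2 * fs_dec) stop("need at least 2 s of signal")
  if (is.null(min_prominence)) {
    pos <- ml_gyro[ml_gyro > 0]
    min_prominence <- if (length(pos)) 0.5 * quantile(pos, 0.95, names = FALSE) else Inf
  }
  pk <- .find_peaks(ml_gyro)
  keep <- pk$idx[ml_gyro[pk$idx] > 0 & pk$prominence >= min_prominence]
  w <- as.integer(round(search_window_s * fs_dec))
  n <- length(ml_gyro)
  np <- length(keep)
  to_i <- hs_i <- rep(NA_integer_, np)
  for (k in seq_len(np)) {
    i <- keep[k]
    lo <- max(1L, i - w + 1L)
    if (k > 1 && !is.na(keep[k - 1])) lo <- max(lo, keep[k - 1] + 1L)
    to_i[k] <- .window_valley(ml_gyro, lo, i - 1L, toward = "right")
    hi <- min(n, i + w - 1L)
    if (k < np) hi <- min(hi, keep[k + 1] - 1L)
    hs_i[k] <- .window_valley(ml_gyro, i + 1L, hi, toward = "left")
  }
  tt <- function(i) ifelse(is.na(i), NA_real_, t0 + (i - 0.5) / fs_dec)
  structure(list(side = side,
                 mid_swing = tt(keep), toe_off = tt(to_i), heel_strike = tt(hs_i),
                 complete_cycle = !is.na(to_i) & !is.na(hs_i),
                 n_peaks = np, fs_dec = fs_dec),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> side=%s peaks=%d complete=%d\n",
              x$side, x$n_peaks, sum(x$complete_cycle)))
  invisible(x)
}

#' Automated signal-quality gate
#'
#' Surrogate for the visual triage of raw recordings: a side's event train
#' fails when fewer than half of the detected mid-swing peaks yield a
#' complete toe-off/mid-swing/heel-strike triplet, or when fewer than
#' 3 complete cycles were found at all.
#'
#' @param events a [detect_events()] result.
#' @param min_complete minimum number of complete cycles (default 3).
#' @param min_rate minimum complete/peaks ratio (default 0.5).
#' @return List with logical `pass` and character `reason`.
#' @export
quality_gate <- function(events, min_complete = 3L, min_rate = 0.5) {
  stopifnot(inherits(events, "gait_events"))
  nc <- sum(events$complete_cycle)
  if (nc < min_complete) {
    return(list(pass = FALSE,
                reason = sprintf("only %d complete cycles (< %d)", nc, min_complete)))
  }
  rate <- nc / max(events$n_peaks, 1L)
  if (rate < min_rate) {
    return(list(pass = FALSE,
                reason = sprintf("complete-cycle rate %.0f%% < %.0f%%",
                                 100 * rate, 100 * min_rate)))
  }
  list(pass = TRUE, reason = sprintf("%d/%d complete cycles", nc, events$n_peaks))
}

# slice [t1, t2] out of a recording; returns index range
.slice_idx <- function(rec, t1, t2) {
  which(rec$t >= t1 - 0.5 / rec$fs & rec$t <= t2 + 0.5 / rec$fs)
}

#' Delineate gait cycles from detected events
#'
#' Gait cycles span heel-strike to heel-strike; tandem cycles span toe-off
#' to toe-off (yielding one more usable cycle fragment per recording in
#' practice). Only pairs of consecutive complete event triplets delineate a
#' cycle, so cycles bridging an incomplete triplet are dropped, and cycles
#' of one side never overlap. Each cycle carries full-rate (256 Hz) slices
#' of the side's shank gyro, thigh gyro and trunk (L3 and sternum) accel,
#' together with band-passed mediolateral gyro slices for the variability
#' features.
#'
#' @param events a [detect_events()] result for one side.
#' @param test "gait" or "tandem".
#' @param recs named list of synchronized full-rate [imu_recording()]s for
#'   this test (needs `shank_<side>`, `thigh_<side>`, `L3`, `sternum`).
#' @param filt_spec [filter_spec()] applied (zero-phase, full rate) to the
#'   mediolateral gyro channels before slicing.
#' @return List of `gait_cycle` objects (possibly empty).
#' @export
delineate_cycles <- function(events, test = c("gait", "tandem"), recs,
                             filt_spec = filter_spec()) {
  stopifnot(inherits(events, "gait_events"))
  test <- match.arg(test)
  side <- events$side
  shank <- recs[[paste0("shank_", side)]]
  thigh <- recs[[paste0("thigh_", side)]]
  trunk <- recs[["L3"]]
  sternum <- recs[["sternum"]]
  stopifnot(inherits(shank, "imu_recording"), inherits(thigh, "imu_recording"),
            inherits(trunk, "imu_recording"))
  nc <- length(events$mid_swing)
  if (sum(events$complete_cycle) < 2) return(list())
  fs <- shank$fs
  shank_ml_f <- bandpass_zero_phase(shank$gyro[, 2], fs, filt_spec)
  thigh_ml_f <- bandpass_zero_phase(thigh$gyro[, 2], fs, filt_spec)
  bounds <- if (test == "gait") events$heel_strike else events$toe_off
  cycles <- list()
  for (k in seq_len(nc - 1)) {
    if (!(events$complete_cycle[k] && events$complete_cycle[k + 1])) next
    t1 <- bounds[k]; t2 <- bounds[k + 1]
    if (is.na(t1) || is.na(t2) || t2 <= t1) next
    idx <- .slice_idx(shank, t1, t2)
    if (length(idx) < 5) next
    cyc <- structure(list(
      test = test, side = side, start_s = t1, end_s = t2,
      cycle_duration_s = t2 - t1,
      # events governing this cycle's swing: the (k+1)-th triplet for gait
      # (HS_k -> TO -> MS -> HS_{k+1}), the k-th for tandem (TO_k -> ...)
      toe_off = if (test == "gait") events$toe_off[k + 1] else events$toe_off[k],
      mid_swing = if (test == "gait") events$mid_swing[k + 1] else events$mid_swing[k],
      heel_strike = if (test == "gait") events$heel_strike[k + 1] else events$heel_strike[k],
      fs = fs, t = shank$t[idx],
      shank_gyro = shank$gyro[idx, , drop = FALSE],
      thigh_gyro = thigh$gyro[idx, , drop = FALSE],
      thigh_accel = thigh$accel[idx, , drop = FALSE],
      shank_accel = shank$accel[idx, , drop = FALSE],
      trunk_accel = trunk$accel[.slice_idx(trunk, t1, t2), , drop = FALSE],
      trunk_gyro = trunk$gyro[.slice_idx(trunk, t1, t2), , drop = FALSE],
      shank_ml_filt = shank_ml_f[idx],
      thigh_ml_filt = thigh_ml_f[idx]),
      class = "gait_cycle")
    cycles[[length(cycles) + 1]] <- cyc
  }
  cycles
}

#' Segment one participant's recordings into gait cycles
#'
#' Runs the full per-side pipeline for both tests: decimation by
#' `dec_factor`, zero-phase band-pass at the decimated rate, event
#' detection, quality gating, and cycle delineation (heel-strike to
#' heel-strike for gait, toe-off to toe-off for tandem).
#'
#' @param recordings `$gait` / `$tandem` named lists of six
#'   [imu_recording()]s (as produced by [simulate_participant()]).
#' @param filt_spec a [filter_spec()].
#' @param dec_factor decimation factor (16: two extra bits for white noise,
#'   detection at 16 Hz).
#' @param min_prominence see [detect_events()].
#' @return List per test: `cycles` (both sides pooled), `events` (per
#'   side), `qc` (per side), `recs`.
#' @export
segment_participant <- function(recordings, filt_spec = filter_spec(),
                                dec_factor = 16L, min_prominence = NULL) {
  out <- list()
  for (test in names(recordings)) {
    recs <- recordings[[test]]
    cycles <- list(); events <- list(); qc <- list()
    for (side in c("L", "R")) {
      shank <- recs[[paste0("shank_", side)]]
      fs_dec <- shank$fs / dec_factor
      ml_dec <- decimate_denoise(shank$gyro[, 2], dec_factor)
      ml_f <- bandpass_zero_phase(ml_dec, fs_dec, filt_spec)
      ev <- detect_events(ml_f, fs_dec, min_prominence, side = side,
                          t0 = shank$t[1])
      q <- quality_gate(ev)
      events[[side]] <- ev
      qc[[side]] <- q
      if (q$pass) {
        cycles <- c(cycles, delineate_cycles(ev, test, recs, filt_spec))
      }
    }
    out[[test]] <- list(cycles = cycles, events = events, qc = qc, recs = recs)
  }
  out
}
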