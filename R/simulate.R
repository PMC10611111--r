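## Synthetic multi-sensor gait generator with known ground-truth events.
##
## The shank mediolateral angular-velocity cycle is a piecewise
## raised-cosine template: a dominant positive mid-swing lobe flanked by
## two negative valleys (toe-off before, heel-strike after) at -0.35x the
## lobe amplitude, echoing the canonical shank pattern used for IMU gait
## event detection. Cycle durations are lognormal (guaranteed positive),
## per-cycle shape is perturbed multiplicatively by the group's
## waveform_jitter, and thigh/trunk channels are smoothed, attenuated,
## phase-shifted mixtures of the shank signals so that trunk RMS and
## regularity features are plausible without claiming biomechanical
## fidelity.

# add a raised-cosine bump of the given half-width (s) and amplitude
.rc_add <- function(x, fs, center, halfwidth, amp) {
  n <- length(x)
  i1 <- max(1L, as.integer(floor((center - halfwidth) * fs)) + 1L)
  i2 <- min(n, as.integer(ceiling((center + halfwidth) * fs)) + 1L)
  if (i1 > i2) return(x)
  tt <- (seq(i1, i2) - 1) / fs
  x[i1:i2] <- x[i1:i2] + 0.5 * amp * (1 + cos(pi * (tt - center) / halfwidth))
  x
}

# integer-sample delay with zero padding (positive n delays the signal)
.shift <- function(x, n) {
  n <- as.integer(round(n))
  if (n == 0) return(x)
  if (n > 0) c(rep(0, n), x[seq_len(length(x) - n)])
  else c(x[seq(-n + 1, length(x))], rep(0, -n))
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# draw one side's cycle timing and shape parameters
.draw_side <- function(n_cycles, start0, dur_mean, dur_cv, amp, jit) {
  sdlog <- sqrt(log(1 + dur_cv^2))
  d <- rlnorm(n_cycles, meanlog = log(dur_mean) - sdlog^2 / 2, sdlog = sdlog)
  starts <- start0 + cumsum(c(0, d[-n_cycles]))
  u_to <- .clamp(0.60 + 0.10 * jit * rnorm(n_cycles), 0.52, 0.68)
  u_ms <- .clamp(0.80 + 0.10 * jit * rnorm(n_cycles), 0.72, 0.88)
  list(
    d = d, starts = starts,
    to = starts + u_to * d,
    ms = starts + u_ms * d,
    hs = starts + d,
    amp_ms = amp * pmax(0.2, 1 + jit * rnorm(n_cycles)),
    amp_vl = 0.35 * amp * pmax(0.2, 1 + jit * rnorm(n_cycles)),
    w_ms = 0.12 * d * .clamp(1 + 0.6 * jit * rnorm(n_cycles), 0.5, 1.6),
    w_vl = 0.08 * d * .clamp(1 + 0.6 * jit * rnorm(n_cycles), 0.5, 1.6)
  )
}

# clean (noise-free) shank mediolateral gyro from side parameters
.shank_ml_clean <- function(side, n, fs) {
  x <- numeric(n)
  for (k in seq_along(side$d)) {
    x <- .rc_add(x, fs, side$ms[k], side$w_ms[k], side$amp_ms[k])
    x <- .rc_add(x, fs, side$to[k], side$w_vl[k], -side$amp_vl[k])
    x <- .rc_add(x, fs, side$hs[k], side$w_vl[k], -side$amp_vl[k])
  }
  x
}

# piecewise per-cycle pitch (deg) and its analytic derivative (dps):
# theta(u) = (R_k / 2) * cos(2 pi u), held constant outside the cycles
.pitch_track <- function(side, hip_r, n, fs) {
  th <- numeric(n); dth <- numeric(n)
  t <- (seq_len(n) - 1) / fs
  th[] <- hip_r[1] / 2
  last <- side$starts[length(side$d)] + side$d[length(side$d)]
  th[t >= last] <- hip_r[length(hip_r)] / 2
  for (k in seq_along(side$d)) {
    s <- side$starts[k]; d <- side$d[k]; r <- hip_r[k]
    idx <- which(t >= s & t < s + d)
    u <- (t[idx] - s) / d
    th[idx] <- (r / 2) * cos(2 * pi * u)
    dth[idx] <- -(pi * r / d) * sin(2 * pi * u)
  }
  list(theta = th, dtheta = dth)
}

.noise <- function(n, sd) if (sd > 0) rnorm(n, 0, sd) else numeric(n)

# simulate one test (gait or tandem) for one participant
.simulate_test <- function(spec, gp, test, seed) {
  fs <- spec$fs
  mult <- if (test == "tandem") {
    list(dur = 1.3, amp = 0.6, jit = 1.5, hip = 0.7)
  } else list(dur = 1, amp = 1, jit = 1, hip = 1)
  n_cycles <- if (test == "tandem") spec$n_cycles_tandem else spec$n_cycles_gait
  dur <- gp$dur * mult$dur
  amp <- gp$amp * mult$amp
  jit <- gp$jit * mult$jit
  hip <- gp$hip * mult$hip
  lead_in <- 1.0

  .with_seed(seed, {
    sideR <- .draw_side(n_cycles, lead_in, dur, gp$cv, amp, jit)
    sideL <- .draw_side(n_cycles, lead_in + gp$asym * dur, dur, gp$cv, amp, jit)
    hipR <- pmax(hip * .clamp(1 + 0.6 * jit * rnorm(n_cycles), 0.3, 2), 1)
    hipL <- pmax(hip * .clamp(1 + 0.6 * jit * rnorm(n_cycles), 0.3, 2), 1)

    t_end <- max(sideR$hs[n_cycles], sideL$hs[n_cycles]) + 1.0
    n <- as.integer(ceiling(t_end * fs)) + 1L
    t <- (seq_len(n) - 1) / fs
    nsd_g <- spec$sensor_noise_sd[["gyro"]]
    nsd_a <- spec$sensor_noise_sd[["accel"]]

    shank <- list(); thigh <- list(); pitch <- list()
    clean_ml <- list()
    for (s in c("R", "L")) {
      side <- if (s == "R") sideR else sideL
      hip_r <- if (s == "R") hipR else hipL
      ml <- .shank_ml_clean(side, n, fs)
      clean_ml[[s]] <- ml
      gv <- 0.25 * .shift(ml, 0.03 * fs)
      gap <- 0.15 * .shift(ml, -0.04 * fs)
      acc_v <- rep(1, n)
      for (k in seq_along(side$d)) {
        acc_v <- .rc_add(acc_v, fs, side$hs[k], 0.05 * side$d[k],
                         0.08 * side$amp_ms[k] / max(amp, 1))
      }
      acc_ap <- 0.10 * ml / max(amp, 1)
      shank[[s]] <- imu_recording(
        paste0("shank_", s), test, t,
        accel = cbind(acc_v + .noise(n, nsd_a), .noise(n, nsd_a),
                      acc_ap + .noise(n, nsd_a)),
        gyro = cbind(gv + .noise(n, nsd_g), ml + .noise(n, nsd_g),
                     gap + .noise(n, nsd_g)),
        fs = fs)

      pt <- .pitch_track(side, hip_r, n, fs)
      pitch[[s]] <- pt
      th_ml <- pt$dtheta + 0.25 * .shift(.lowpass_zero_phase(ml, fs, 6), 0.04 * fs)
      th_rad <- pt$theta * pi / 180
      thigh[[s]] <- imu_recording(
        paste0("thigh_", s), test, t,
        accel = cbind(cos(th_rad) + .noise(n, nsd_a), .noise(n, nsd_a),
                      sin(th_rad) + .noise(n, nsd_a)),
        gyro = cbind(0.2 * .shift(th_ml, 0.03 * fs) + .noise(n, nsd_g),
                     th_ml + .noise(n, nsd_g),
                     0.12 * .shift(th_ml, -0.05 * fs) + .noise(n, nsd_g)),
        fs = fs)
    }

    # pelvis pitch: small (2 deg) oscillation locked to the right-leg phase
    pel <- .pitch_track(sideR, rep(2, n_cycles), n, fs)
    mix_ml <- .lowpass_zero_phase(clean_ml$L + clean_ml$R, fs, 4)
    env <- .lowpass_zero_phase((abs(clean_ml$L) + abs(clean_ml$R)) / max(amp, 1), fs, 4)
    dml <- .lowpass_zero_phase((clean_ml$L - clean_ml$R) / max(amp, 1), fs, 4)
    pel_rad <- pel$theta * pi / 180
    trunk_rec <- function(site, scale) {
      imu_recording(
        site, test, t,
        accel = cbind(cos(pel_rad) + scale * 0.15 * (env - mean(env)) + .noise(n, nsd_a),
                      scale * 0.08 * dml + .noise(n, nsd_a),
                      sin(pel_rad) + scale * 0.05 * (env - mean(env)) + .noise(n, nsd_a)),
        gyro = cbind(scale * 0.05 * mix_ml + .noise(n, nsd_g),
                     pel$dtheta + scale * 0.08 * mix_ml + .noise(n, nsd_g),
                     scale * 0.04 * mix_ml + .noise(n, nsd_g)),
        fs = fs)
    }
    recs <- list(
      sternum = trunk_rec("sternum", 0.8),
      L3 = trunk_rec("L3", 1.0),
      thigh_L = thigh$L, thigh_R = thigh$R,
      shank_L = shank$L, shank_R = shank$R)

    # ground truth, incl. pendulum stride length from the clean signals
    gt_side <- function(s) {
      side <- if (s == "R") sideR else sideL
      hip_r <- if (s == "R") hipR else hipL
      pt <- pitch[[s]]
      ml <- clean_ml[[s]]
      th_ml_clean <- pt$dtheta + 0.25 * .shift(.lowpass_zero_phase(ml, fs, 6), 0.04 * fs)
      stride <- hip_rng <- numeric(length(side$d))
      for (k in seq_along(side$d)) {
        iw <- which(t >= side$to[k] & t <= side$hs[k])
        dth_t <- sum(th_ml_clean[iw]) / fs * pi / 180
        dth_s <- sum(ml[iw]) / fs * pi / 180
        stride[k] <- 2 * spec$thigh_length_m * sin(abs(dth_t) / 2) +
          2 * spec$shank_length_m * sin(abs(dth_s) / 2)
        ic <- which(t >= side$starts[k] & t < side$starts[k] + side$d[k])
        hip_rng[k] <- diff(range(pt$theta[ic] - pel$theta[ic]))
      }
      list(toe_off = side$to, mid_swing = side$ms, heel_strike = side$hs,
           cycle_start = side$starts, cycle_duration = side$d,
           stride_length = stride, hip_range = hip_rng)
    }
    list(recordings = recs,
         ground_truth = list(L = gt_side("L"), R = gt_side("R")))
  })
}

#' Simulate one participant
#'
#' Generates the six IMU recordings (sternum, L3, both thighs, both shanks)
#' for both tests (gait and tandem gait) at 256 Hz, plus the ground truth:
#' per side, the true toe-off / mid-swing / heel-strike times, per-cycle
#' pendulum stride length and hip-angle range. Within each cycle
#' toe-off < mid-swing < heel-strike by construction. Tandem gait uses
#' 1.3x the cycle duration, 0.6x the amplitude and 1.5x the waveform
#' jitter of gait.
#'
#' @param spec a [cohort_spec()].
#' @param group one of "EOA", "DCD", "CTRL".
#' @param participant_id identifier string.
#' @param seed integer seed for this participant's private stream; derived
#'   from `spec$seed` when `NULL`.
#' @return List with elements `participant_id`, `group`, `recordings`
#'   (`$gait`, `$tandem`, each a named list of six [imu_recording()]s) and
#'   `ground_truth` (`$gait$L`, `$gait$R`, ...).
#' @export
simulate_participant <- function(spec, group, participant_id, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  group <- match.arg(group, .GROUPS)
  if (is.null(seed)) seed <- .sub_seed(spec$seed, participant_id)
  # participant-level random effects (their own stream)
  gp <- if (spec$participant_effects) {
    .with_seed(.sub_seed(seed, "effects"), list(
      dur = spec$cycle_duration_mean[[group]] * exp(rnorm(1, 0, 0.04)),
      cv = spec$cycle_duration_cv[[group]],
      amp = spec$amplitude_mean[[group]] * .clamp(rnorm(1, 1, 0.06), 0.7, 1.3),
      jit = spec$waveform_jitter[[group]] * .clamp(rnorm(1, 1, 0.08), 0.5, 1.5),
      hip = pmax(spec$hip_range_mean[[group]] + rnorm(1, 0, 2), 5),
      asym = .clamp(rnorm(1, 0.5, 0.02), 0.4, 0.6)
    ))
  } else {
    list(dur = spec$cycle_duration_mean[[group]],
         cv = spec$cycle_duration_cv[[group]],
         amp = spec$amplitude_mean[[group]],
         jit = spec$waveform_jitter[[group]],
         hip = spec$hip_range_mean[[group]],
         asym = 0.5)
  }
  recs <- list(); gt <- list()
  for (test in .TESTS) {
    sim <- .simulate_test(spec, gp, test, .sub_seed(seed, test))
    recs[[test]] <- sim$recordings
    gt[[test]] <- sim$ground_truth
  }
  list(participant_id = participant_id, group = group,
       recordings = recs, ground_truth = gt)
}

#' Simulate a full cohort
#'
#' One participant per requested slot, deterministic given `spec$seed`
#' (participant streams are derived by stable sub-seeding, so the same seed
#' reproduces bit-identical signals).
#'
#' @param spec a [cohort_spec()].
#' @return List with `participants` (list of [simulate_participant()]
#'   results), `manifest` (data.frame: participant_id, group, age) and
#'   `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  ids <- character(0); groups <- character(0)
  for (g in .GROUPS) {
    k <- spec$group_sizes[[g]]
    ids <- c(ids, sprintf("%s%02d", g, seq_len(k)))
    groups <- c(groups, rep(g, k))
  }
  participants <- vector("list", length(ids))
  ages <- numeric(length(ids))
  for (i in seq_along(ids)) {
    participants[[i]] <- simulate_participant(spec, groups[i], ids[i])
    ages[i] <- .with_seed(.sub_seed(.sub_seed(spec$seed, ids[i]), "age"),
                          round(runif(1, 6, 16)))
  }
  names(participants) <- ids
  manifest <- data.frame(participant_id = ids, group = groups, age = ages,
                         stringsAsFactors = FALSE)
  list(participants = participants, manifest = manifest, spec = spec)
}

#' Write a simulated cohort to disk
#'
#' One CSV per sensor per test (columns `t_s`, `ax_g`, `ay_g`, `az_g`,
#' `gx_dps`, `gy_dps`, `gz_dps`), a manifest CSV with file paths, and the
#' ground truth as JSON.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest data.frame with path columns.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- cohort$manifest
  for (p in cohort$participants) {
    for (test in names(p$recordings)) {
      for (site in names(p$recordings[[test]])) {
        r <- p$recordings[[test]][[site]]
        df <- data.frame(t_s = r$t,
                         ax_g = r$accel[, 1], ay_g = r$accel[, 2], az_g = r$accel[, 3],
                         gx_dps = r$gyro[, 1], gy_dps = r$gyro[, 2], gz_dps = r$gyro[, 3])
        f <- file.path(dir, sprintf("%s_%s_%s.csv", p$participant_id, test, site))
        write.csv(df, f, row.names = FALSE)
      }
    }
  }
  gt <- lapply(cohort$participants, function(p) p$ground_truth)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the manifest, signal CSVs and ground
#'   truth JSON.
#' @return Same structure as [simulate_cohort()] (without `spec`).
#' @export
read_cohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  participants <- lapply(seq_len(nrow(manifest)), function(i) {
    pid <- manifest$participant_id[i]
    recs <- list()
    for (test in .TESTS) {
      recs[[test]] <- lapply(stats::setNames(nm = .SITES), function(site) {
        df <- read.csv(file.path(dir, sprintf("%s_%s_%s.csv", pid, test, site)))
        imu_recording(site, test, df$t_s,
                      accel = as.matrix(df[, c("ax_g", "ay_g", "az_g")]),
                      gyro = as.matrix(df[, c("gx_dps", "gy_dps", "gz_dps")]),
                      fs = round(1 / median(diff(df$t_s))))
      })
    }
    list(participant_id = pid, group = manifest$group[i], recordings = recs,
         ground_truth = NULL)
  })
  names(participants) <- manifest$participant_id
  list(participants = participants, manifest = manifest)
}
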