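## The 36-feature catalogue: 24 gait (G_*) + 12 tandem-gait (TG_*)
## features per cycle, spanning temporal, spatial, angular-range,
## variability (DTW distance to the participant mean cycle), curvature,
## smoothness and trunk regularity families.

.GAIT_FEATURES <- c(
  "G_STRIDE_T", "G_STANCE_T", "G_SWING_T", "G_SWING_STANCE_RATIO",
  "G_CADENCE", "G_STRIDE_LEN", "G_STRIDE_VEL",
  "G_RNG_GYRO_ML_SHANK", "G_RNG_GYRO_ML_THIGH", "G_RHFE",
  "G_RNG_PITCH_SHANK", "G_RNG_PITCH_THIGH",
  "G_DIS_DTW_MEAN_SHANK", "G_DIS_DTW_MEAN_THIGH",
  "G_DEV_STRIDE_T", "G_DEV_STRIDE_LEN",
  "G_CURV_SHANK", "G_CURV_THIGH", "G_NJERK_SHANK",
  "G_STEP_REG", "G_STRIDE_REG", "G_SYM_REG",
  "G_RMS_ACC_V_TRUNK", "G_RMS_ACC_ML_TRUNK")

.TANDEM_FEATURES <- c(
  "TG_CYCLE_T", "TG_RNG_GYRO_ML_SHANK", "TG_RNG_GYRO_ML_THIGH",
  "TG_DIS_DTW_MEAN_SHANK", "TG_DIS_DTW_MEAN_THIGH",
  "TG_CURV_SHANK", "TG_CURV_THIGH", "TG_DEV_CYCLE_T", "TG_NJERK_SHANK",
  "TG_RNG_PITCH_TRUNK", "TG_RMS_ACC_V_TRUNK", "TG_RMS_ACC_ML_TRUNK")

#' The canonical 36-feature catalogue
#'
#' @return Character vector of the 24 gait + 12 tandem feature names, in
#'   canonical column order.
#' @export
feature_catalog <- function() c(.GAIT_FEATURES, .TANDEM_FEATURES)

#' Feature dictionary
#'
#' @return data.frame with `name`, `test`, `unit`, `description` for each
#'   of the 36 features.
#' @export
feature_dictionary <- function() {
  g <- function(name, unit, description)
    data.frame(name = name, test = ifelse(grepl("^TG_", name), "tandem", "gait"),
               unit = unit, description = description)
  rbind(
    g("G_STRIDE_T", "s", "stride time (heel-strike to heel-strike)"),
    g("G_STANCE_T", "s", "stance time (heel-strike to same-side toe-off)"),
    g("G_SWING_T", "s", "swing time (toe-off to heel-strike)"),
    g("G_SWING_STANCE_RATIO", "-", "swing time / stance time"),
    g("G_CADENCE", "steps/min", "120 / stride time"),
    g("G_STRIDE_LEN", "m", "double-pendulum stride length from integrated thigh+shank mediolateral gyro over swing"),
    g("G_STRIDE_VEL", "m/s", "stride length / stride time"),
    g("G_RNG_GYRO_ML_SHANK", "dps", "range of band-passed shank mediolateral angular velocity"),
    g("G_RNG_GYRO_ML_THIGH", "dps", "range of band-passed thigh mediolateral angular velocity"),
    g("G_RHFE", "deg", "range of hip flexion-extension angle (thigh pitch minus pelvis pitch, complementary filter)"),
    g("G_RNG_PITCH_SHANK", "deg", "range of shank pitch (complementary filter)"),
    g("G_RNG_PITCH_THIGH", "deg", "range of thigh pitch (complementary filter)"),
    g("G_DIS_DTW_MEAN_SHANK", "dps", "DTW distance of the shank cycle to the participant mean cycle"),
    g("G_DIS_DTW_MEAN_THIGH", "dps", "DTW distance of the thigh cycle to the participant mean cycle"),
    g("G_DEV_STRIDE_T", "s", "absolute deviation of stride time from the participant mean"),
    g("G_DEV_STRIDE_LEN", "m", "absolute deviation of stride length from the participant mean"),
    g("G_CURV_SHANK", "1/dps", "median local curvature of the 3D shank angular-velocity trajectory"),
    g("G_CURV_THIGH", "1/dps", "median local curvature of the 3D thigh angular-velocity trajectory"),
    g("G_NJERK_SHANK", "-", "duration- and amplitude-normalized jerk of shank acceleration magnitude"),
    g("G_STEP_REG", "-", "trunk vertical-acceleration autocorrelation at step lag"),
    g("G_STRIDE_REG", "-", "trunk vertical-acceleration autocorrelation at stride lag"),
    g("G_SYM_REG", "-", "step regularity / stride regularity"),
    g("G_RMS_ACC_V_TRUNK", "g", "RMS of demeaned trunk vertical acceleration within the cycle"),
    g("G_RMS_ACC_ML_TRUNK", "g", "RMS of demeaned trunk mediolateral acceleration within the cycle"),
    g("TG_CYCLE_T", "s", "tandem cycle time (toe-off to toe-off)"),
    g("TG_RNG_GYRO_ML_SHANK", "dps", "range of band-passed shank mediolateral angular velocity"),
    g("TG_RNG_GYRO_ML_THIGH", "dps", "range of band-passed thigh mediolateral angular velocity"),
    g("TG_DIS_DTW_MEAN_SHANK", "dps", "DTW distance of the shank cycle to the participant mean cycle"),
    g("TG_DIS_DTW_MEAN_THIGH", "dps", "DTW distance of the thigh cycle to the participant mean cycle"),
    g("TG_CURV_SHANK", "1/dps", "median local curvature of the 3D shank angular-velocity trajectory"),
    g("TG_CURV_THIGH", "1/dps", "median local curvature of the 3D thigh angular-velocity trajectory"),
    g("TG_DEV_CYCLE_T", "s", "absolute deviation of cycle time from the participant mean"),
    g("TG_NJERK_SHANK", "-", "duration- and amplitude-normalized jerk of shank acceleration magnitude"),
    g("TG_RNG_PITCH_TRUNK", "deg", "range of trunk pitch (complementary filter)"),
    g("TG_RMS_ACC_V_TRUNK", "g", "RMS of demeaned trunk vertical acceleration within the cycle"),
    g("TG_RMS_ACC_ML_TRUNK", "g", "RMS of demeaned trunk mediolateral acceleration within the cycle"))
}

# complementary filter: fuse mediolateral gyro integration with
# accelerometer inclination (atan2 of anterior-posterior vs vertical)
.comp_pitch <- function(gyro_ml, accel_v, accel_ap, fs, alpha = 0.98) {
  th_acc <- atan2(accel_ap, accel_v) * 180 / pi
  n <- length(gyro_ml)
  th <- numeric(n)
  th[1] <- th_acc[1]
  dt <- 1 / fs
  for (i in 2:n) {
    th[i] <- alpha * (th[i - 1] + gyro_ml[i] * dt) + (1 - alpha) * th_acc[i]
  }
  th
}

#' Hip flexion-extension range of one cycle
#'
#' Thigh pitch and pelvis pitch are each estimated by a complementary
#' filter fusing mediolateral gyro integration with accelerometer
#' inclination; the hip angle is their difference and the feature is its
#' max - min over the cycle (degrees). Defines `G_RHFE`.
#'
#' @param thigh_cycle `gait_cycle` carrying the thigh channels.
#' @param trunk_cycle `gait_cycle` carrying the trunk (pelvis) channels;
#'   defaults to the same cycle. Must be time-aligned within one sample.
#' @param alpha complementary-filter constant (0.98 at 256 Hz).
#' @return Range in degrees.
#' @export
hip_flexion_extension_range <- function(thigh_cycle, trunk_cycle = thigh_cycle,
                                        alpha = 0.98) {
  if (abs(thigh_cycle$start_s - trunk_cycle$start_s) > 1 / thigh_cycle$fs) {
    stop("thigh and trunk cycles are misaligned")
  }
  fs <- thigh_cycle$fs
  th_t <- .comp_pitch(thigh_cycle$thigh_gyro[, 2], thigh_cycle$thigh_accel[, 1],
                      thigh_cycle$thigh_accel[, 3], fs, alpha)
  n <- min(length(th_t), nrow(trunk_cycle$trunk_accel), nrow(trunk_cycle$trunk_gyro))
  th_p <- .comp_pitch(trunk_cycle$trunk_gyro[seq_len(n), 2],
                      trunk_cycle$trunk_accel[seq_len(n), 1],
                      trunk_cycle$trunk_accel[seq_len(n), 3], fs, alpha)
  diff(range(th_t[seq_len(n)] - th_p))
}

#' Local curvature of the 3D angular-velocity trajectory
#'
#' Treats the gyro vector over time as a space curve w(t) and evaluates
#' kappa = ||w' x w''|| / ||w'||^3 with central differences; the feature is
#' the median over samples where ||w'|| exceeds 1% of its cycle maximum
#' (robust to the near-stationary stance samples). Defines
#' `{G,TG}_CURV_{SHANK,THIGH}`. All-constant cycles return 0.
#'
#' @param cycle a `gait_cycle`.
#' @param sensor "shank" or "thigh".
#' @return Median curvature (1/dps).
#' @export
curvature_feature <- function(cycle, sensor = c("shank", "thigh")) {
  sensor <- match.arg(sensor)
  w <- if (sensor == "shank") cycle$shank_gyro else cycle$thigh_gyro
  .curvature(w, cycle$fs)
}

.curvature <- function(w, fs) {
  n <- nrow(w)
  if (n < 5) stop("cycle too short for curvature (need >= 5 samples)")
  i <- 2:(n - 1)
  d1 <- (w[i + 1, , drop = FALSE] - w[i - 1, , drop = FALSE]) * (fs / 2)
  d2 <- (w[i + 1, , drop = FALSE] - 2 * w[i, , drop = FALSE] +
           w[i - 1, , drop = FALSE]) * fs^2
  cross <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
                 d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
                 d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  speed <- sqrt(rowSums(d1^2))
  vmax <- max(speed)
  if (vmax <= 0) return(0)
  keep <- speed > 0.01 * vmax
  if (!any(keep)) return(0)
  kappa <- sqrt(rowSums(cross^2))[keep] / speed[keep]^3
  median(kappa)
}

# duration- and amplitude-normalized jerk of an acceleration magnitude:
# sqrt(T * integral((da/dt)^2 dt)) / range(a), dimensionless
.njerk <- function(x, fs) {
  n <- length(x)
  if (n < 3) return(0)
  rng <- diff(range(x))
  if (rng <= 0) return(0)
  j <- diff(x) * fs
  sqrt((n / fs) * sum(j^2) / fs) / rng
}

#' Spatiotemporal gait features of one cycle
#'
#' Stride, stance and swing times come from the cycle's event triplet;
#' stride length uses the double-pendulum chord model: thigh and shank
#' rotation angles over swing (integrated mediolateral gyro) applied to
#' the configured segment lengths,
#' `2 L_t sin(|dtheta_t|/2) + 2 L_s sin(|dtheta_s|/2)`.
#'
#' @param cycle a gait `gait_cycle`.
#' @param thigh_length_m,shank_length_m segment lengths (m).
#' @return Named list: stride_t, stance_t, swing_t, swing_stance_ratio,
#'   cadence (steps/min), stride_len (m), stride_vel (m/s).
#' @export
spatiotemporal_features <- function(cycle, thigh_length_m = 0.40,
                                    shank_length_m = 0.40) {
  stride_t <- cycle$cycle_duration_s
  stance_t <- cycle$toe_off - cycle$start_s
  swing_t <- cycle$heel_strike - cycle$toe_off
  iw <- which(cycle$t >= cycle$toe_off & cycle$t <= cycle$heel_strike)
  if (length(iw) < 2) iw <- seq_along(cycle$t)
  dth_t <- sum(cycle$thigh_gyro[iw, 2]) / cycle$fs * pi / 180
  dth_s <- sum(cycle$shank_gyro[iw, 2]) / cycle$fs * pi / 180
  stride_len <- 2 * thigh_length_m * sin(min(abs(dth_t), pi) / 2) +
    2 * shank_length_m * sin(min(abs(dth_s), pi) / 2)
  list(stride_t = stride_t, stance_t = stance_t, swing_t = swing_t,
       swing_stance_ratio = swing_t / stance_t,
       cadence = 120 / stride_t,
       stride_len = stride_len,
       stride_vel = stride_len / stride_t)
}

# biased autocorrelation of x at (a window around) lag L, in samples
.acf_at <- function(x, lag, tol = 0.1) {
  n <- length(x)
  x <- x - mean(x)
  denom <- sum(x^2)
  if (denom <= 0) return(NA_real_)
  lags <- unique(pmax(1L, round(lag * seq(1 - tol, 1 + tol, length.out = 11))))
  lags <- lags[lags < n - 1]
  if (!length(lags)) return(NA_real_)
  max(vapply(lags, function(L)
    sum(x[1:(n - L)] * x[(L + 1):n]) / denom, numeric(1)))
}

#' Trunk RMS and gait-regularity features
#'
#' Within-cycle RMS of the demeaned trunk vertical and mediolateral
#' acceleration, plus step and stride regularity: the biased
#' autocorrelation of the test-long trunk vertical acceleration evaluated
#' at the participant's step and stride lags (maximum over a +/-10% lag
#' window). Symmetry is step regularity / stride regularity.
#'
#' @param cycle a `gait_cycle`.
#' @param trunk_v,trunk_ml full-test trunk vertical / mediolateral
#'   acceleration channels.
#' @param fs sampling rate of the full-test channels.
#' @param step_lag_s,stride_lag_s participant step and stride periods (s).
#' @return Named list: rms_v, rms_ml, step_reg, stride_reg, sym_reg.
#' @export
trunk_and_regularity_features <- function(cycle, trunk_v, trunk_ml, fs,
                                          step_lag_s, stride_lag_s) {
  va <- cycle$trunk_accel[, 1]
  ml <- cycle$trunk_accel[, 2]
  rms <- function(x) sqrt(mean((x - mean(x))^2))
  if (length(trunk_v) < 2 * round(stride_lag_s * fs)) {
    return(list(rms_v = rms(va), rms_ml = rms(ml),
                step_reg = NA_real_, stride_reg = NA_real_, sym_reg = NA_real_))
  }
  step_reg <- .acf_at(trunk_v, round(step_lag_s * fs))
  stride_reg <- .acf_at(trunk_v, round(stride_lag_s * fs))
  sym <- if (is.na(step_reg) || is.na(stride_reg) || stride_reg == 0)
    NA_real_ else step_reg / stride_reg
  list(rms_v = rms(va), rms_ml = rms(ml),
       step_reg = step_reg, stride_reg = stride_reg, sym_reg = sym)
}

# participant-level context shared by all of one participant's rows
.participant_context <- function(participant_id, group, segmented,
                                 config = list()) {
  cfg <- utils::modifyList(list(alpha = 0.98, thigh_length_m = 0.40,
                                shank_length_m = 0.40, n_resample = 100L),
                           config)
  ctx <- list(participant_id = participant_id, group = group, config = cfg)
  for (test in c("gait", "tandem")) {
    seg <- segmented[[test]]
    cyc <- seg$cycles
    if (!length(cyc)) next
    ctx[[test]] <- list(
      mean_shank = mean_cycle(cyc, "shank_ml", cfg$n_resample),
      mean_thigh = mean_cycle(cyc, "thigh_ml", cfg$n_resample))
    trunk <- seg$recs$L3
    ctx[[test]]$trunk_v <- trunk$accel[, 1]
    ctx[[test]]$trunk_ml <- trunk$accel[, 2]
    ctx[[test]]$fs <- trunk$fs
    # lags: stride from same-side heel-strikes, step from both sides merged
    hs_all <- sort(unlist(lapply(seg$events, function(e)
      e$heel_strike[!is.na(e$heel_strike)])))
    stride_lag <- median(unlist(lapply(seg$events, function(e) {
      h <- e$heel_strike[!is.na(e$heel_strike)]
      if (length(h) >= 2) diff(h) else numeric(0)
    })))
    step_lag <- if (length(hs_all) >= 3) median(diff(hs_all)) else stride_lag / 2
    ctx[[test]]$stride_lag_s <- stride_lag
    ctx[[test]]$step_lag_s <- step_lag
    durs <- vapply(cyc, function(cy) cy$cycle_duration_s, numeric(1))
    ctx[[test]]$mean_cycle_t <- mean(durs)
    if (test == "gait") {
      sl <- vapply(cyc, function(cy)
        spatiotemporal_features(cy, cfg$thigh_length_m, cfg$shank_length_m)$stride_len,
        numeric(1))
      ctx$gait$mean_stride_len <- mean(sl)
    }
  }
  ctx
}

.gait_cycle_features <- function(cycle, ctx) {
  cfg <- ctx$config
  st <- spatiotemporal_features(cycle, cfg$thigh_length_m, cfg$shank_length_m)
  tr <- trunk_and_regularity_features(cycle, ctx$gait$trunk_v, ctx$gait$trunk_ml,
                                      ctx$gait$fs, ctx$gait$step_lag_s,
                                      ctx$gait$stride_lag_s)
  pitch_rng <- function(gyro, accel) {
    th <- .comp_pitch(gyro[, 2], accel[, 1], accel[, 3], cycle$fs, cfg$alpha)
    diff(range(th))
  }
  c(G_STRIDE_T = st$stride_t, G_STANCE_T = st$stance_t, G_SWING_T = st$swing_t,
    G_SWING_STANCE_RATIO = st$swing_stance_ratio, G_CADENCE = st$cadence,
    G_STRIDE_LEN = st$stride_len, G_STRIDE_VEL = st$stride_vel,
    G_RNG_GYRO_ML_SHANK = diff(range(cycle$shank_ml_filt)),
    G_RNG_GYRO_ML_THIGH = diff(range(cycle$thigh_ml_filt)),
    G_RHFE = hip_flexion_extension_range(cycle, alpha = cfg$alpha),
    G_RNG_PITCH_SHANK = pitch_rng(cycle$shank_gyro, cycle$shank_accel),
    G_RNG_PITCH_THIGH = pitch_rng(cycle$thigh_gyro, cycle$thigh_accel),
    G_DIS_DTW_MEAN_SHANK = dtw_to_mean(cycle, ctx$gait$mean_shank),
    G_DIS_DTW_MEAN_THIGH = dtw_to_mean(cycle, ctx$gait$mean_thigh),
    G_DEV_STRIDE_T = abs(st$stride_t - ctx$gait$mean_cycle_t),
    G_DEV_STRIDE_LEN = abs(st$stride_len - ctx$gait$mean_stride_len),
    G_CURV_SHANK = curvature_feature(cycle, "shank"),
    G_CURV_THIGH = curvature_feature(cycle, "thigh"),
    G_NJERK_SHANK = .njerk(sqrt(rowSums(cycle$shank_accel^2)), cycle$fs),
    G_STEP_REG = tr$step_reg, G_STRIDE_REG = tr$stride_reg,
    G_SYM_REG = tr$sym_reg,
    G_RMS_ACC_V_TRUNK = tr$rms_v, G_RMS_ACC_ML_TRUNK = tr$rms_ml)
}

.tandem_cycle_features <- function(cycle, ctx) {
  cfg <- ctx$config
  tr <- trunk_and_regularity_features(cycle, ctx$tandem$trunk_v,
                                      ctx$tandem$trunk_ml, ctx$tandem$fs,
                                      ctx$tandem$step_lag_s,
                                      ctx$tandem$stride_lag_s)
  n <- min(nrow(cycle$trunk_gyro), nrow(cycle$trunk_accel))
  th_trunk <- .comp_pitch(cycle$trunk_gyro[seq_len(n), 2],
                          cycle$trunk_accel[seq_len(n), 1],
                          cycle$trunk_accel[seq_len(n), 3],
                          cycle$fs, cfg$alpha)
  c(TG_CYCLE_T = cycle$cycle_duration_s,
    TG_RNG_GYRO_ML_SHANK = diff(range(cycle$shank_ml_filt)),
    TG_RNG_GYRO_ML_THIGH = diff(range(cycle$thigh_ml_filt)),
    TG_DIS_DTW_MEAN_SHANK = dtw_to_mean(cycle, ctx$tandem$mean_shank),
    TG_DIS_DTW_MEAN_THIGH = dtw_to_mean(cycle, ctx$tandem$mean_thigh),
    TG_CURV_SHANK = curvature_feature(cycle, "shank"),
    TG_CURV_THIGH = curvature_feature(cycle, "thigh"),
    TG_DEV_CYCLE_T = abs(cycle$cycle_duration_s - ctx$tandem$mean_cycle_t),
    TG_NJERK_SHANK = .njerk(sqrt(rowSums(cycle$shank_accel^2)), cycle$fs),
    TG_RNG_PITCH_TRUNK = diff(range(th_trunk)),
    TG_RMS_ACC_V_TRUNK = tr$rms_v, TG_RMS_ACC_ML_TRUNK = tr$rms_ml)
}

#' Build one "combined movement" feature row
#'
#' One row pairs the 24 features of one complete gait cycle with the 12
#' features of one tandem-gait cycle of the same participant.
#'
#' @param gait_cycle,tandem_cycle `gait_cycle` objects from the same
#'   participant's two tests.
#' @param context participant context from [extract_features()] (or the
#'   internal constructor), carrying the mean cycles, trunk channels,
#'   participant means and configuration.
#' @return Named numeric vector of the 36 catalogue features.
#' @export
build_feature_row <- function(gait_cycle, tandem_cycle, context) {
  if (gait_cycle$test != "gait" || tandem_cycle$test != "tandem") {
    stop("build_feature_row needs one gait and one tandem cycle")
  }
  if (!is.null(context$cycle_owner)) {
    og <- context$cycle_owner(gait_cycle); ot <- context$cycle_owner(tandem_cycle)
    if (!identical(og, ot)) stop("cycles belong to different participants")
  }
  row <- c(.gait_cycle_features(gait_cycle, context),
           .tandem_cycle_features(tandem_cycle, context))
  row <- row[feature_catalog()]
  if (any(!is.finite(row))) {
    stop("row rejected: non-finite features: ",
         paste(names(row)[!is.finite(row)], collapse = ", "))
  }
  row
}

#' Extract per-cycle feature tables for one participant
#'
#' Computes every gait cycle's 24 gait features and every tandem cycle's
#' 12 tandem features once; [assemble_table()] then samples cycle pairs to
#' build the participant's rows.
#'
#' @param participant_id,group identifiers carried into the tables.
#' @param segmented result of [segment_participant()].
#' @param config optional list overriding `alpha`, `thigh_length_m`,
#'   `shank_length_m`, `n_resample`.
#' @return List: `participant_id`, `group`, `gait` (matrix cycles x 24),
#'   `tandem` (matrix cycles x 12), `context`.
#' @export
extract_features <- function(participant_id, group, segmented, config = list()) {
  ctx <- .participant_context(participant_id, group, segmented, config)
  gait_cycles <- segmented$gait$cycles
  tandem_cycles <- segmented$tandem$cycles
  gait <- if (length(gait_cycles)) {
    t(vapply(gait_cycles, .gait_cycle_features, numeric(24), ctx = ctx))
  } else matrix(numeric(0), 0, 24, dimnames = list(NULL, .GAIT_FEATURES))
  tandem <- if (length(tandem_cycles)) {
    t(vapply(tandem_cycles, .tandem_cycle_features, numeric(12), ctx = ctx))
  } else matrix(numeric(0), 0, 12, dimnames = list(NULL, .TANDEM_FEATURES))
  list(participant_id = participant_id, group = group,
       gait = gait, tandem = tandem, context = ctx)
}
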