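## IMU recording container and device-level preparation: axis
## standardization to (vertical, mediolateral, anterior-posterior) and
## cropping all devices to a shared time window.

.SITES <- c("sternum", "L3", "thigh_L", "thigh_R", "shank_L", "shank_R")
.TESTS <- c("gait", "tandem")

#' Construct an IMU recording
#'
#' One sensor site, one test: timestamped tri-axial acceleration (g) and
#' angular velocity (dps), optionally magnetic field (gauss), sampled
#' uniformly. After standardization, axis 1 is vertical, axis 2
#' mediolateral and axis 3 anterior-posterior.
#'
#' @param site one of sternum, L3, thigh_L, thigh_R, shank_L, shank_R.
#' @param test "gait" or "tandem".
#' @param t numeric vector of timestamps in seconds, uniformly spaced.
#' @param accel,gyro n x 3 numeric matrices (g; dps).
#' @param mag optional n x 3 matrix (gauss).
#' @param fs sampling rate in Hz (nominal 256).
#' @param axes_standard logical flag: axes already in the standard order.
#' @return Object of class `imu_recording`.
#' @export
imu_recording <- function(site, test, t, accel, gyro, mag = NULL, fs = 256,
                          axes_standard = TRUE) {
  site <- match.arg(site, .SITES)
  test <- match.arg(test, .TESTS)
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  n <- length(t)
  stopifnot(nrow(accel) == n, nrow(gyro) == n,
            ncol(accel) == 3, ncol(gyro) == 3)
  if (n >= 2) {
    dt <- diff(t)
    if (any(dt <= 0)) stop("timestamps must be strictly increasing")
    if (max(abs(dt - 1 / fs)) > 1e-6) {
      stop("timestamps not uniform at fs = ", fs, " Hz")
    }
  }
  structure(list(site = site, test = test, t = as.numeric(t), fs = fs,
                 accel = accel, gyro = gyro, mag = mag,
                 axes_standard = isTRUE(axes_standard)),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> site=%s test=%s fs=%g Hz n=%d span=[%.3f, %.3f] s\n",
              x$site, x$test, x$fs, length(x$t),
              if (length(x$t)) x$t[1] else NA, if (length(x$t)) x$t[length(x$t)] else NA))
  invisible(x)
}

# validate a signed axis permutation like c(2, -1, 3)
.check_axis_mapping <- function(mapping) {
  if (length(mapping) != 3 || any(mapping == 0) ||
      !setequal(abs(mapping), 1:3)) {
    stop("mapping must be a signed permutation of axes 1:3, e.g. c(2, -1, 3)")
  }
  as.integer(mapping)
}

.apply_mapping <- function(m, mapping) {
  out <- m[, abs(mapping), drop = FALSE]
  sweep(out, 2, sign(mapping), `*`)
}

#' Standardize sensor axes
#'
#' Reorders and sign-flips the three channels of every signal so that axis 1
#' is vertical, axis 2 mediolateral and axis 3 anterior-posterior.
#' `mapping[k] = j` means output axis `k` takes input axis `|j|`, negated if
#' `j < 0`. A warning is issued when the vertical accelerometer mean is not
#' positive (gravity should read about +1 g in quiet stance).
#'
#' @param rec an [imu_recording()].
#' @param mapping signed permutation of 1:3; the identity `c(1, 2, 3)`
#'   leaves the recording unchanged.
#' @return The recording with standardized axes.
#' @export
standardize_axes <- function(rec, mapping = c(1L, 2L, 3L)) {
  stopifnot(inherits(rec, "imu_recording"))
  mapping <- .check_axis_mapping(mapping)
  rec$accel <- .apply_mapping(rec$accel, mapping)
  rec$gyro <- .apply_mapping(rec$gyro, mapping)
  if (!is.null(rec$mag)) rec$mag <- .apply_mapping(rec$mag, mapping)
  rec$axes_standard <- TRUE
  if (nrow(rec$accel) > 0 && mean(rec$accel[, 1]) <= 0) {
    warning("vertical accelerometer mean is not positive after ",
            "standardization; check the axis mapping (gravity check)")
  }
  rec
}

#' Synchronize recordings to a common time window
#'
#' Crops every recording to `[start, end]` on its own sample grid (nearest
#' sample, no resampling): the devices share a hardware-reset time base, so
#' sub-sample alignment is not required.
#'
#' @param recs list of [imu_recording()] objects.
#' @param start,end window bounds in seconds; must lie within every
#'   recording's span.
#' @return List of cropped recordings, in the input order.
#' @export
synchronize_recordings <- function(recs, start, end) {
  stopifnot(is.list(recs), length(recs) >= 1)
  if (!is.finite(start) || !is.finite(end) || end <= start) {
    stop("invalid window: need start < end")
  }
  lapply(recs, function(r) {
    stopifnot(inherits(r, "imu_recording"))
    span <- range(r$t)
    tol <- 0.5 / r$fs
    if (start < span[1] - tol || end > span[2] + tol) {
      stop(sprintf("window [%.3f, %.3f] outside recording span of sensor %s (%s)",
                   start, end, r$site, r$test))
    }
    keep <- which(r$t >= start - tol & r$t <= end + tol)
    r$t <- r$t[keep]
    r$accel <- r$accel[keep, , drop = FALSE]
    r$gyro <- r$gyro[keep, , drop = FALSE]
    if (!is.null(r$mag)) r$mag <- r$mag[keep, , drop = FALSE]
    r
  })
}
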