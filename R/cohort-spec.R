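## Cohort specification for the synthetic IMU generator.

.GROUPS <- c("EOA", "DCD", "CTRL")

.named_by_group <- function(x, what) {
  if (length(x) == 1L) x <- rep(x, 3L)
  if (is.null(names(x))) names(x) <- .GROUPS
  if (!setequal(names(x), .GROUPS)) stop(what, " must be named EOA/DCD/CTRL")
  x[.GROUPS]
}

#' Synthetic cohort specification
#'
#' Declares the generative model for a synthetic multi-sensor gait cohort.
#' Defaults emulate the study population the pipeline targets: 18 EOA,
#' 13 DCD and 29 CTRL participants, with cycle-to-cycle waveform
#' variability ordered EOA > DCD > CTRL (the clinical expectation that
#' ataxic gait is the most irregular) and hip flexion-extension excursion
#' graded the same way. Where no published value exists (signal amplitudes,
#' noise levels), defaults are plausibility choices for paediatric gait at
#' 256 Hz and are exposed here.
#'
#' @param group_sizes named integer vector, participants per class.
#' @param cycle_duration_mean named numeric, mean gait-cycle duration (s)
#'   per group. Tandem cycles are 1.3x longer.
#' @param cycle_duration_cv named numeric, coefficient of variation of the
#'   (lognormal) cycle duration per group.
#' @param amplitude_mean named numeric, mid-swing shank mediolateral
#'   angular-velocity peak (dps) per group. Tandem amplitude is 0.6x.
#' @param waveform_jitter named numeric, per-cycle multiplicative shape
#'   noise per group; must be ordered EOA >= DCD >= CTRL. Tandem jitter is
#'   1.5x (tandem gait is the more variability-sensitive test).
#' @param hip_range_mean named numeric, per-cycle hip flexion-extension
#'   excursion (degrees) per group.
#' @param sensor_noise_sd named numeric `c(gyro = , accel = )`: additive
#'   white-noise SD per gyroscope channel (dps) and accelerometer channel (g).
#' @param n_cycles_gait,n_cycles_tandem cycles generated per participant
#'   per test (events per side).
#' @param thigh_length_m,shank_length_m segment lengths used for the
#'   pendulum stride-length bookkeeping.
#' @param participant_effects logical: draw small per-participant random
#'   effects on duration, amplitude, jitter, hip range and step asymmetry
#'   (default). Disable for fully degenerate worlds in which every cycle
#'   must repeat the template exactly.
#' @param seed integer RNG seed; participant streams are derived from it.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(EOA = 18L, DCD = 13L, CTRL = 29L),
                        cycle_duration_mean = c(EOA = 1.15, DCD = 1.10, CTRL = 1.05),
                        cycle_duration_cv = c(EOA = 0.09, DCD = 0.07, CTRL = 0.05),
                        amplitude_mean = c(EOA = 230, DCD = 245, CTRL = 260),
                        waveform_jitter = c(EOA = 0.24, DCD = 0.16, CTRL = 0.08),
                        hip_range_mean = c(EOA = 46, DCD = 40, CTRL = 34),
                        sensor_noise_sd = c(gyro = 6, accel = 0.02),
                        n_cycles_gait = 12L,
                        n_cycles_tandem = 10L,
                        thigh_length_m = 0.40,
                        shank_length_m = 0.40,
                        participant_effects = TRUE,
                        seed = 20231012L) {
  group_sizes <- .named_by_group(group_sizes, "group_sizes")
  cycle_duration_mean <- .named_by_group(cycle_duration_mean, "cycle_duration_mean")
  cycle_duration_cv <- .named_by_group(cycle_duration_cv, "cycle_duration_cv")
  amplitude_mean <- .named_by_group(amplitude_mean, "amplitude_mean")
  waveform_jitter <- .named_by_group(waveform_jitter, "waveform_jitter")
  hip_range_mean <- .named_by_group(hip_range_mean, "hip_range_mean")
  if (any(group_sizes < 1)) stop("invalid spec: all group counts must be >= 1")
  if (any(cycle_duration_mean <= 0)) stop("invalid spec: cycle_duration_mean must be > 0")
  if (any(cycle_duration_cv < 0) || any(waveform_jitter < 0) ||
      any(sensor_noise_sd < 0)) {
    stop("invalid spec: SDs and jitter must be >= 0")
  }
  if (!(waveform_jitter["EOA"] >= waveform_jitter["DCD"] &&
        waveform_jitter["DCD"] >= waveform_jitter["CTRL"])) {
    stop("invalid spec: waveform_jitter must be ordered EOA >= DCD >= CTRL")
  }
  if (!all(c("gyro", "accel") %in% names(sensor_noise_sd))) {
    stop("sensor_noise_sd needs components 'gyro' and 'accel'")
  }
  if (n_cycles_gait < 2 || n_cycles_tandem < 2) {
    stop("invalid spec: need at least 2 cycles per test")
  }
  structure(list(
    group_sizes = as.integer(group_sizes) |> stats::setNames(.GROUPS),
    cycle_duration_mean = cycle_duration_mean,
    cycle_duration_cv = cycle_duration_cv,
    amplitude_mean = amplitude_mean,
    waveform_jitter = waveform_jitter,
    hip_range_mean = hip_range_mean,
    sensor_noise_sd = sensor_noise_sd,
    n_cycles_gait = as.integer(n_cycles_gait),
    n_cycles_tandem = as.integer(n_cycles_tandem),
    thigh_length_m = thigh_length_m,
    shank_length_m = shank_length_m,
    participant_effects = isTRUE(participant_effects),
    fs = 256,
    seed = as.integer(seed)), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>", sum(x$group_sizes), "participants (",
      paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes), collapse = ", "),
      ") fs =", x$fs, "Hz\n")
  invisible(x)
}

# evaluate code under a temporary seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# stable 31-bit sub-seed from a base seed and a string key
.sub_seed <- function(base, key) {
  h <- as.numeric(base) %% 2147483647
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}
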