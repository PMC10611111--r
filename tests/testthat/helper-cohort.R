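# Shared fixtures, built once per test run and cached. Everything is
# generated in code; no binary data files are used.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  .fixture_cache[[key]]
}

# a small cohort for unit tests: 2 participants per group
small_spec <- function(...) {
  cohort_spec(group_sizes = c(EOA = 2L, DCD = 2L, CTRL = 2L), seed = 99L, ...)
}

small_cohort <- function() {
  cached_fixture("small_cohort", simulate_cohort(small_spec()))
}

small_features <- function() {
  cached_fixture("small_features",
                 cohort_features(small_cohort(), run_config(seed = 99L)))
}

# the default-size cohort (60 participants) used by the acceptance tests
default_cohort <- function() {
  cached_fixture("default_cohort", simulate_cohort(cohort_spec()))
}

# per-participant segmentation of the default cohort (events + cycles)
default_segmented <- function() {
  cached_fixture("default_segmented", {
    lapply(default_cohort()$participants,
           function(p) segment_participant(p$recordings))
  })
}

default_features <- function() {
  cached_fixture("default_features", {
    cohort <- default_cohort()
    seg <- default_segmented()
    lapply(names(seg), function(id)
      extract_features(id, cohort$participants[[id]]$group, seg[[id]]))
  })
}

default_table <- function() {
  cached_fixture("default_table",
                 assemble_table(default_features(), 10L, seed = 42L))
}

# one mid-sized participant with segmentation, for feature-level tests
one_participant <- function() {
  cached_fixture("one_participant", {
    p <- simulate_participant(cohort_spec(), "CTRL", "CTRL01")
    seg <- segment_participant(p$recordings)
    list(p = p, seg = seg, fe = extract_features("CTRL01", "CTRL", seg))
  })
}

# noise-free, jitter-free, constant-duration degenerate participant:
# cycles are exact repetitions of the template (1.0 s = 256 samples)
degenerate_participant <- function() {
  cached_fixture("degenerate_participant", {
    spec <- cohort_spec(
      cycle_duration_mean = c(EOA = 1, DCD = 1, CTRL = 1),
      cycle_duration_cv = c(EOA = 0, DCD = 0, CTRL = 0),
      waveform_jitter = c(EOA = 0, DCD = 0, CTRL = 0),
      sensor_noise_sd = c(gyro = 0, accel = 0),
      participant_effects = FALSE,
      seed = 5L)
    p <- simulate_participant(spec, "CTRL", "D01")
    seg <- segment_participant(p$recordings)
    list(spec = spec, p = p, seg = seg)
  })
}

# a hand-made gait_cycle for unit tests of single-cycle features
make_cycle <- function(n = 256L, fs = 256, test = "gait", side = "R",
                       start_s = 0, thigh_gyro = NULL, thigh_accel = NULL,
                       trunk_gyro = NULL, trunk_accel = NULL,
                       shank_gyro = NULL, shank_accel = NULL,
                       toe_off = NULL, mid_swing = NULL, heel_strike = NULL) {
  zeros <- matrix(0, n, 3)
  grav <- cbind(rep(1, n), 0, 0)
  t <- start_s + (seq_len(n) - 1) / fs
  end_s <- start_s + n / fs
  structure(list(
    test = test, side = side, start_s = start_s, end_s = end_s,
    cycle_duration_s = end_s - start_s,
    toe_off = if (is.null(toe_off)) start_s + 0.6 * (end_s - start_s) else toe_off,
    mid_swing = if (is.null(mid_swing)) start_s + 0.8 * (end_s - start_s) else mid_swing,
    heel_strike = if (is.null(heel_strike)) end_s else heel_strike,
    fs = fs, t = t,
    shank_gyro = if (is.null(shank_gyro)) zeros else shank_gyro,
    thigh_gyro = if (is.null(thigh_gyro)) zeros else thigh_gyro,
    thigh_accel = if (is.null(thigh_accel)) grav else thigh_accel,
    shank_accel = if (is.null(shank_accel)) grav else shank_accel,
    trunk_accel = if (is.null(trunk_accel)) grav else trunk_accel,
    trunk_gyro = if (is.null(trunk_gyro)) zeros else trunk_gyro,
    shank_ml_filt = if (is.null(shank_gyro)) numeric(n) else shank_gyro[, 2],
    thigh_ml_filt = if (is.null(thigh_gyro)) numeric(n) else thigh_gyro[, 2]),
    class = "gait_cycle")
}

# well-separated synthetic feature tables for classifier unit tests:
# class means differ on the first `n_informative` features
separable_features <- function(n_per_group = 4L, n_rows = 10L, sep = 6,
                               n_informative = 3L, seed = 1L) {
  groups <- c("EOA", "DCD", "CTRL")
  catalog <- feature_catalog()
  out <- list()
  set.seed(seed)
  for (gi in seq_along(groups)) {
    for (i in seq_len(n_per_group)) {
      id <- sprintf("%s%02d", groups[gi], i)
      base <- rep(0, 36)
      base[seq_len(n_informative)] <- gi * sep
      gait <- matrix(rnorm(12 * 24), 12, 24,
                     dimnames = list(NULL, catalog[1:24]))
      gait <- sweep(gait, 2, base[1:24], `+`)
      tandem <- matrix(rnorm(12 * 12), 12, 12,
                       dimnames = list(NULL, catalog[25:36]))
      tandem <- sweep(tandem, 2, base[25:36], `+`)
      out[[id]] <- list(participant_id = id, group = groups[gi],
                        gait = gait, tandem = tandem, context = NULL)
    }
  }
  out
}
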