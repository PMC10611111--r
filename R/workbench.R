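## Orchestration: configuration, pipeline stages and a small CLI.

#' Pipeline run configuration
#'
#' Aggregates every stage's tunable parameters with defaults matching the
#' protocol constants: 256 Hz sampling, 0.5-5 Hz fourth-order zero-phase
#' band-pass, decimation factor 16, 0.5 s valley-search windows, 10 rows
#' per participant, 300 trees, 100 iterations.
#'
#' @param out_dir output directory for file-producing stages.
#' @param seed master seed (generator and classifier ladders derive from it).
#' @param cohort a [cohort_spec()]; rebuilt with `seed` when `NULL`.
#' @param band,filter_order band-pass parameters.
#' @param dec_factor decimation factor for event detection.
#' @param min_prominence peak prominence (NULL = adaptive rule).
#' @param n_resample DTW reference length.
#' @param n_rows_per_participant combined-movement rows per participant.
#' @param n_trees,n_iterations,adasyn_k classifier protocol parameters.
#' @param thigh_length_m,shank_length_m pendulum segment lengths.
#' @param alpha complementary-filter constant.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir = "gaitcoord_out", seed = 1L, cohort = NULL,
                       band = c(0.5, 5), filter_order = 4L, dec_factor = 16L,
                       min_prominence = NULL, n_resample = 100L,
                       n_rows_per_participant = 10L, n_trees = 300L,
                       n_iterations = 100L, adasyn_k = 5L,
                       thigh_length_m = 0.40, shank_length_m = 0.40,
                       alpha = 0.98) {
  if (is.null(cohort)) cohort <- cohort_spec(seed = seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
                 band = band, filter_order = as.integer(filter_order),
                 dec_factor = as.integer(dec_factor),
                 min_prominence = min_prominence,
                 n_resample = as.integer(n_resample),
                 n_rows_per_participant = as.integer(n_rows_per_participant),
                 n_trees = as.integer(n_trees),
                 n_iterations = as.integer(n_iterations),
                 adasyn_k = as.integer(adasyn_k),
                 thigh_length_m = thigh_length_m,
                 shank_length_m = shank_length_m, alpha = alpha),
            class = "run_config")
}

.cfg_filter <- function(config) filter_spec(config$band, config$filter_order)

.cfg_feature <- function(config) {
  list(alpha = config$alpha, thigh_length_m = config$thigh_length_m,
       shank_length_m = config$shank_length_m, n_resample = config$n_resample)
}

#' Segment and extract features for a whole cohort
#'
#' Runs segmentation, quality gating and per-cycle feature extraction for
#' every participant. Participants whose recordings fail the quality gate
#' on both sides of a test (hence yield no usable cycles) are dropped at
#' table-assembly time with a logged reason.
#'
#' @param cohort result of [simulate_cohort()] or [read_cohort()].
#' @param config a [run_config()].
#' @return List of [extract_features()] results, one per participant.
#' @export
cohort_features <- function(cohort, config = run_config()) {
  fspec <- .cfg_filter(config)
  fcfg <- .cfg_feature(config)
  lapply(cohort$participants, function(p) {
    seg <- segment_participant(p$recordings, fspec, config$dec_factor,
                               config$min_prominence)
    extract_features(p$participant_id, p$group, seg, fcfg)
  })
}

#' Run the whole pipeline in memory
#'
#' Simulate (or accept) a cohort, segment, extract, assemble the
#' 10-rows-per-participant table and run the classification protocol.
#'
#' @param config a [run_config()].
#' @param cohort optional pre-built cohort (simulated from
#'   `config$cohort` when `NULL`).
#' @return List: `cohort`, `features`, `assembled`, `run`
#'   (a [run_protocol()] result), `metrics` (a [metrics_report()] of the
#'   mean confusion matrix).
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL) {
  if (is.null(cohort)) cohort <- simulate_cohort(config$cohort)
  feats <- cohort_features(cohort, config)
  at <- assemble_table(feats, config$n_rows_per_participant,
                       seed = .sub_seed(config$seed, "pairing"))
  cfg <- classifier_config(n_trees = config$n_trees,
                           adasyn_k = config$adasyn_k,
                           n_iterations = config$n_iterations,
                           n_rows_per_participant = config$n_rows_per_participant,
                           master_seed = config$seed)
  run <- run_protocol(at, cfg)
  sizes <- table(factor(run$actual, .GROUPS))
  cm <- confusion_from_percentages(run$confusion_mean, as.numeric(sizes))
  list(cohort = cohort, features = feats, assembled = at, run = run,
       metrics = metrics_report(cm))
}

#' Packaged reference confusion matrix
#'
#' Row percentages and class sizes (18 EOA / 13 DCD / 29 CTRL) of the
#' reference clinical cohort, packaged for the metrics regression tests.
#'
#' @return A `confusion_matrix` (fractional counts).
#' @export
reference_confusion <- function() {
  f <- system.file("extdata", "reference_confusion.csv", package = "gaitcoord")
  df <- read.csv(f, check.names = FALSE)
  m <- as.matrix(df[, c("EOA", "DCD", "CTRL")])
  rownames(m) <- df$class
  confusion_from_percentages(m, df$size)
}

.write_run_files <- function(res, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  at <- res$assembled; run <- res$run
  write.csv(at$table, file.path(out_dir, "features.csv"), row.names = FALSE)
  jsonlite::write_json(feature_dictionary(),
                       file.path(out_dir, "feature_dictionary.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  pred <- data.frame(iteration = rep(seq_len(nrow(run$predictions)),
                                     each = ncol(run$predictions)),
                     participant_id = rep(colnames(run$predictions),
                                          nrow(run$predictions)),
                     predicted = as.vector(t(run$predictions)))
  write.csv(pred, file.path(out_dir, "predictions.csv"), row.names = FALSE)
  write.csv(data.frame(participant_id = rownames(run$probabilities),
                       actual = unname(run$actual), run$probabilities),
            file.path(out_dir, "probabilities.csv"), row.names = FALSE)
  cm <- data.frame(class = rownames(run$confusion_mean),
                   run$confusion_mean, check.names = FALSE)
  write.csv(cm, file.path(out_dir, "confusion_mean.csv"), row.names = FALSE)
  write.csv(data.frame(class = rownames(run$confusion_sd), run$confusion_sd,
                       check.names = FALSE),
            file.path(out_dir, "confusion_sd.csv"), row.names = FALSE)
  write.csv(feature_importance(run),
            file.path(out_dir, "importance.csv"), row.names = FALSE)
  meta <- list(seed = config$seed, n_trees = config$n_trees,
               n_iterations = config$n_iterations,
               adasyn_k = config$adasyn_k, band = config$band,
               filter_order = config$filter_order,
               dec_factor = config$dec_factor,
               iteration_seeds = run$seeds,
               excluded = res$assembled$excluded,
               package_version = as.character(utils::packageVersion("gaitcoord")))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Command-line interface
#'
#' Subcommands: `simulate` (write a synthetic cohort), `all` (full
#' pipeline: simulate, segment, extract, classify, write every output
#' file) and `evaluate` (metrics report from a confusion CSV, defaulting
#' to the packaged reference matrix). Flags are `--key=value` pairs
#' overriding [run_config()] defaults, e.g.
#' `gaitcoord all --seed=7 --n_iterations=10 --out_dir=out`.
#'
#' @param args character vector of CLI arguments.
#' @return Invisibly, the stage's main result.
#' @export
gaitcoord_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: gaitcoord <simulate|all|evaluate> [--key=value ...]")
    return(invisible(NULL))
  }
  cmd <- args[1]
  kv <- list()
  for (a in args[-1]) {
    m <- regmatches(a, regexec("^--([^=]+)=(.*)$", a))[[1]]
    if (length(m) != 3) stop("bad flag (want --key=value): ", a)
    val <- utils::type.convert(m[3], as.is = TRUE)
    kv[[m[2]]] <- val
  }
  base <- run_config()
  known <- c(names(base), "confusion_csv")
  bad <- setdiff(names(kv), known)
  if (length(bad)) stop("unknown option(s): ", paste(bad, collapse = ", "))
  config <- do.call(run_config, kv[names(kv) %in% setdiff(names(base), "cohort")])
  switch(cmd,
    simulate = {
      cohort <- simulate_cohort(config$cohort)
      write_cohort(cohort, file.path(config$out_dir, "cohort"))
      message("cohort written to ", file.path(config$out_dir, "cohort"))
      invisible(cohort)
    },
    all = {
      res <- run_pipeline(config)
      .write_run_files(res, config$out_dir, config)
      print(res$metrics)
      message("outputs written to ", config$out_dir)
      invisible(res)
    },
    evaluate = {
      cm <- if (!is.null(kv$confusion_csv)) {
        df <- read.csv(kv$confusion_csv, check.names = FALSE)
        m <- as.matrix(df[, c("EOA", "DCD", "CTRL")])
        rownames(m) <- df$class
        confusion_from_percentages(m, df$size)
      } else reference_confusion()
      rep <- metrics_report(cm)
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(list(per_class = rep$per_class,
                                combined = rep$combined,
                                overall_accuracy = rep$overall_accuracy),
                           file.path(config$out_dir, "metrics.json"),
                           dataframe = "rows", auto_unbox = TRUE, digits = NA)
      print(rep)
      invisible(rep)
    },
    stop("unknown command: ", cmd))
}
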