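test_that("assemble_table builds 10 rows per participant", {
  at <- assemble_table(small_features(), 10L, seed = 7L)
  expect_equal(nrow(at$table), 60)
  expect_equal(ncol(at$table), 38)  # id + group + 36 features
  expect_true(all(table(at$table$participant_id) == 10))
  expect_length(at$with_replacement, 0)  # >= 10 cycles everywhere
  expect_true(all(is.finite(as.matrix(at$table[, at$feature_names]))))
  # deterministic given seed
  at2 <- assemble_table(small_features(), 10L, seed = 7L)
  expect_identical(at$table, at2$table)
})

test_that("assemble_table falls back to replacement and logs exclusions", {
  feats <- small_features()
  few <- feats[[1]]
  few$tandem <- few$tandem[1:4, , drop = FALSE]
  none <- feats[[2]]
  none$gait <- none$gait[0, , drop = FALSE]
  at <- assemble_table(list(few, none, feats[[3]]), 10L, seed = 1L)
  expect_true(few$participant_id %in% at$with_replacement)
  expect_equal(at$excluded$participant_id, none$participant_id)
  expect_match(at$excluded$reason, "gait")
  expect_equal(nrow(at$table), 20)
})

test_that("ADASYN balances minority classes per the density rule", {
  set.seed(1)
  # balanced input: nothing synthesized
  xb <- matrix(rnorm(60 * 4), 60, 4)
  yb <- rep(c("A", "B", "C"), each = 20)
  outb <- adasyn_oversample(xb, yb, 5L)
  expect_identical(outb$x, xb)
  # 290 vs 130: minority brought to the majority count (within the +/-10% contract)
  x2 <- rbind(matrix(rnorm(290 * 3), 290, 3),
              matrix(rnorm(130 * 3, mean = 1), 130, 3))
  y2 <- rep(c("maj", "min"), c(290, 130))
  out2 <- adasyn_oversample(x2, y2, 5L)
  n_min <- sum(out2$labels == "min")
  expect_gte(n_min, 261)
  expect_lte(n_min, 319)
  # synthetic rows are flagged with a minority-class origin row
  syn_idx <- which(!is.na(out2$origin))
  expect_true(all(syn_idx > 420))
  expect_true(all(y2[out2$origin[syn_idx]] == "min"))
  expect_true(all(is.finite(out2$x[syn_idx, ])))
  expect_error(adasyn_oversample(xb, rep("A", 60), 5L), "2 classes")
})

test_that("ADASYN gives no offspring to minority samples in pure neighbourhoods", {
  # minority: a tight, pure cluster at the origin + one sample amid the majority
  set.seed(2)
  min_cluster <- matrix(rnorm(6 * 2, sd = 0.05), 6, 2)
  min_border <- matrix(c(10, 10), 1, 2)
  maj <- matrix(rnorm(20 * 2, mean = 10, sd = 0.5), 20, 2)
  x <- rbind(min_cluster, min_border, maj)
  y <- rep(c("min", "maj"), c(7, 20))
  out <- adasyn_oversample(x, y, 5L)
  origins <- out$origin[!is.na(out$origin)]
  # every synthetic sample stems from the border sample (index 7)
  expect_true(all(origins == 7))
  expect_equal(sum(out$labels == "min"), 20)
})

test_that("majority vote is strict and ties break uniformly at random", {
  expect_equal(gaitcoord:::.vote(c(6, 4, 0)), 1)
  expect_equal(gaitcoord:::.vote(c(0, 4, 6)), 3)
  set.seed(3)
  draws <- replicate(1000, gaitcoord:::.vote(c(5, 5, 0)))
  expect_true(all(draws %in% 1:2))
  expect_equal(mean(draws == 1), 0.5, tolerance = 0.05)
})

test_that("LOOCV is perfect on a separable cohort and guards leakage", {
  feats <- separable_features(n_per_group = 4L, sep = 8)
  at <- assemble_table(feats, 10L, seed = 2L)
  it <- loocv_iteration(at, classifier_config(n_trees = 100L), 11L)
  expect_equal(unname(it$predicted), unname(it$actual))
  expect_equal(sum(it$importance), 1, tolerance = 1e-9)
  # planted-signal recovery: the 3 informative features dominate
  top5 <- names(sort(it$importance, decreasing = TRUE))[1:5]
  expect_true(all(feature_catalog()[1:3] %in% top5))
})

test_that("run_protocol: determinism, one-hot probabilities, normalization", {
  feats <- separable_features(n_per_group = 3L, sep = 5, seed = 4L)
  at <- assemble_table(feats, 10L, seed = 5L)
  cfg <- classifier_config(n_trees = 60L, n_iterations = 1L, master_seed = 9L)
  r1 <- run_protocol(at, cfg)
  r2 <- run_protocol(at, cfg)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$importance_mean, r2$importance_mean)
  # single iteration: probabilities are one-hot
  expect_true(all(r1$probabilities %in% c(0, 1)))
  expect_true(all(abs(rowSums(r1$probabilities) - 1) < 1e-9))
  cfg3 <- classifier_config(n_trees = 60L, n_iterations = 3L, master_seed = 9L)
  r3 <- run_protocol(at, cfg3)
  expect_true(all(abs(rowSums(r3$probabilities) - 1) < 1e-9))
  expect_equal(sum(r3$importance_mean), 1, tolerance = 1e-9)
  # confusion rows are percentages of each actual class
  expect_true(all(abs(rowSums(r3$confusion_mean) - 100) < 1e-6))
})

test_that("duplicated features split their importance", {
  # mtry = p so every node sees both copies: under random feature
  # subsampling (mtry 6) a duplicate raises the availability of the
  # informative signal and inflates the pair's total credit instead
  feats <- separable_features(n_per_group = 4L, sep = 6, seed = 6L,
                              n_informative = 1L)
  # duplicate the single informative feature into feature 2
  for (i in seq_along(feats)) {
    feats[[i]]$gait[, 2] <- feats[[i]]$gait[, 1]
  }
  at <- assemble_table(feats, 10L, seed = 3L)
  it <- loocv_iteration(at, classifier_config(n_trees = 200L, mtry = 36L), 21L)
  imp_dup <- it$importance[1] + it$importance[2]
  # compare with the same data where feature 2 is pure noise
  feats2 <- separable_features(n_per_group = 4L, sep = 6, seed = 6L,
                               n_informative = 1L)
  at2 <- assemble_table(feats2, 10L, seed = 3L)
  it2 <- loocv_iteration(at2, classifier_config(n_trees = 200L, mtry = 36L), 21L)
  expect_equal(imp_dup, it2$importance[1], tolerance = 0.25)
  # and the duplicated halves are individually substantial
  expect_gt(min(it$importance[1:2]) / imp_dup, 0.2)
})
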