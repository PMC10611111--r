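## Classification protocol: feature-table assembly (10 combined-movement
## rows per participant), per-fold ADASYN balancing, leave-one-participant-
## out cross-validation with a 300-tree Gini random forest, majority
## voting, repeated iterations, probabilities and MDI importances.

#' Classifier configuration
#'
#' @param n_trees trees in the random forest (300).
#' @param adasyn_k ADASYN neighbourhood size (5).
#' @param n_iterations protocol repetitions (100).
#' @param mtry features per split; `NULL` uses the square-root rule
#'   (sqrt(36) = 6).
#' @param n_rows_per_participant combined-movement rows per participant (10).
#' @param master_seed seed of the seed ladder (master -> iteration -> fold).
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(n_trees = 300L, adasyn_k = 5L,
                              n_iterations = 100L, mtry = NULL,
                              n_rows_per_participant = 10L,
                              master_seed = 1L) {
  stopifnot(n_trees >= 1, n_iterations >= 1, adasyn_k >= 1)
  structure(list(n_trees = as.integer(n_trees), adasyn_k = as.integer(adasyn_k),
                 n_iterations = as.integer(n_iterations),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 n_rows_per_participant = as.integer(n_rows_per_participant),
                 master_seed = as.integer(master_seed)),
            class = "classifier_config")
}

#' Assemble the combined-movement feature table
#'
#' Each participant contributes `n_rows` rows, each pairing one randomly
#' chosen complete gait cycle with one randomly chosen tandem cycle.
#' Cycles are drawn without replacement when at least `n_rows` are
#' available, with replacement otherwise (flagged). Participants lacking
#' usable cycles in either test are excluded with a logged reason. The
#' pairing is fixed once per dataset (deterministic given `seed`);
#' iteration-level randomness is confined to the classifier.
#'
#' @param features_by_participant list of [extract_features()] results.
#' @param n_rows rows per participant (10).
#' @param seed RNG seed for the pairing.
#' @return Object of class `assembled_table`: `$table` (data.frame with
#'   participant_id, group + 36 features), `$excluded` (data.frame),
#'   `$with_replacement` (character vector of flagged participants).
#' @export
assemble_table <- function(features_by_participant, n_rows = 10L, seed = 1L) {
  rows <- list(); excluded <- list(); flagged <- character(0)
  .with_seed(seed, {
    for (fp in features_by_participant) {
      ng <- nrow(fp$gait); nt <- nrow(fp$tandem)
      if (ng < 1 || nt < 1) {
        excluded[[length(excluded) + 1]] <- data.frame(
          participant_id = fp$participant_id,
          reason = sprintf("no usable %s cycles",
                           if (ng < 1) "gait" else "tandem"))
        next
      }
      pick <- function(n) {
        if (n >= n_rows) sample.int(n, n_rows)
        else sample.int(n, n_rows, replace = TRUE)
      }
      if (ng < n_rows || nt < n_rows) flagged <- c(flagged, fp$participant_id)
      gi <- pick(ng); ti <- pick(nt)
      vals <- cbind(fp$gait[gi, , drop = FALSE], fp$tandem[ti, , drop = FALSE])
      bad <- !apply(is.finite(vals), 1, all)
      if (any(bad)) {
        # re-draw from finite cycles only; reject participant if impossible
        okg <- which(apply(is.finite(fp$gait), 1, all))
        okt <- which(apply(is.finite(fp$tandem), 1, all))
        if (!length(okg) || !length(okt)) {
          excluded[[length(excluded) + 1]] <- data.frame(
            participant_id = fp$participant_id, reason = "non-finite features")
          next
        }
        gi <- okg[pick(length(okg))]; ti <- okt[pick(length(okt))]
        vals <- cbind(fp$gait[gi, , drop = FALSE], fp$tandem[ti, , drop = FALSE])
      }
      df <- data.frame(participant_id = fp$participant_id, group = fp$group,
                       vals, check.names = FALSE)
      rows[[length(rows) + 1]] <- df
    }
  })
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(list(table = table,
                 excluded = if (length(excluded)) do.call(rbind, excluded)
                 else data.frame(participant_id = character(0), reason = character(0)),
                 with_replacement = flagged,
                 feature_names = feature_catalog()),
            class = "assembled_table")
}

#' @export
print.assembled_table <- function(x, ...) {
  cat(sprintf("<assembled_table> %d rows, %d participants, %d excluded\n",
              nrow(x$table), length(unique(x$table$participant_id)),
              nrow(x$excluded)))
  invisible(x)
}

#' ADASYN minority oversampling
#'
#' Adaptive synthetic oversampling after He et al.: every class smaller
#' than the majority receives `majority - count` synthetic samples,
#' allocated across its members proportionally to the fraction of
#' non-same-class neighbours among each member's `k` nearest neighbours in
#' the full training set (members surrounded only by their own class get
#' no offspring). Each synthetic sample lies uniformly on the segment
#' between a minority sample and one of its `k` nearest same-class
#' neighbours. When every member's neighbourhood is pure, the allocation
#' falls back to uniform so the balance contract still holds. `k` is
#' reduced to `class size - 1` for very small classes.
#'
#' @param x numeric matrix of training rows.
#' @param labels class label per row.
#' @param k neighbourhood size.
#' @return List: `x` (augmented matrix), `labels`, `origin` (index of the
#'   seeding training row for synthetic rows, `NA` for originals).
#' @export
adasyn_oversample <- function(x, labels, k = 5L) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  counts <- table(labels)
  if (length(counts) < 2) stop("ADASYN needs at least 2 classes")
  target <- max(counts)
  new_x <- list(); new_y <- character(0); origin <- integer(0)
  for (cl in names(counts)[counts < target]) {
    idx <- which(labels == cl)
    G <- target - length(idx)
    if (G == 0) next
    kk <- min(k, nrow(x) - 1L)
    nn <- FNN::get.knnx(x, x[idx, , drop = FALSE], k = kk + 1L)$nn.index
    r <- vapply(seq_along(idx), function(i) {
      nb <- setdiff(nn[i, ], idx[i])[seq_len(kk)]
      mean(labels[nb] != cl)
    }, numeric(1))
    w <- if (sum(r) > 0) r / sum(r) else rep(1 / length(idx), length(idx))
    # largest-remainder allocation so the class is balanced exactly
    g <- floor(w * G)
    rem <- G - sum(g)
    if (rem > 0) {
      frac <- w * G - g
      g[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
        g[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
    }
    # same-class neighbours for interpolation
    kc <- min(k, length(idx) - 1L)
    nnc <- if (kc >= 1) {
      FNN::get.knnx(x[idx, , drop = FALSE], x[idx, , drop = FALSE],
                    k = kc + 1L)$nn.index
    } else NULL
    for (i in seq_along(idx)) {
      if (g[i] == 0) next
      for (s in seq_len(g[i])) {
        if (is.null(nnc)) {
          xz <- x[idx[i], ]  # singleton class: duplicate
        } else {
          cand <- setdiff(nnc[i, ], i)[seq_len(kc)]
          z <- idx[cand[floor(runif(1) * kc) + 1L]]
          lam <- runif(1)
          xz <- x[idx[i], ] + lam * (x[z, ] - x[idx[i], ])
        }
        new_x[[length(new_x) + 1]] <- xz
        new_y <- c(new_y, cl)
        origin <- c(origin, idx[i])
      }
    }
  }
  if (length(new_x)) {
    x_aug <- rbind(x, do.call(rbind, new_x))
    list(x = x_aug, labels = c(labels, new_y),
         origin = c(rep(NA_integer_, length(labels)), origin))
  } else {
    list(x = x, labels = labels, origin = rep(NA_integer_, length(labels)))
  }
}

# argmax with uniform random tie-break
.vote <- function(counts) {
  m <- which(counts == max(counts))
  if (length(m) == 1) m else m[floor(runif(1) * length(m)) + 1L]
}

#' One leave-one-participant-out iteration
#'
#' For each participant: train the forest on all other participants' rows
#' (ADASYN-balanced), predict each held-out row, and aggregate the row
#' predictions by majority vote (ties broken uniformly at random). The
#' held-out participant's rows never enter training, pre- or post-ADASYN
#' (asserted via row provenance).
#'
#' @param at an [assemble_table()] result.
#' @param cfg a [classifier_config()].
#' @param iteration_seed seed for this iteration (fold seeds derive from it).
#' @return List: `predicted` (named character per participant), `actual`,
#'   `importance` (36-vector, mean over folds, sums to 1).
#' @export
loocv_iteration <- function(at, cfg = classifier_config(), iteration_seed = 1L) {
  tab <- at$table
  feats <- at$feature_names
  pids <- unique(tab$participant_id)
  if (length(pids) < 3 || length(unique(tab$group)) < 2) {
    stop("need >= 3 participants spanning >= 2 classes")
  }
  X <- as.matrix(tab[, feats])
  if (any(!is.finite(X))) stop("feature table contains non-finite values")
  y <- tab$group
  K <- length(.GROUPS)
  mtry <- if (is.null(cfg$mtry)) max(1L, as.integer(floor(sqrt(ncol(X))))) else cfg$mtry
  predicted <- setNames(character(length(pids)), pids)
  actual <- setNames(tab$group[match(pids, tab$participant_id)], pids)
  imp <- matrix(0, length(pids), ncol(X), dimnames = list(pids, feats))
  for (p in pids) {
    hold <- tab$participant_id == p
    train_pid <- tab$participant_id[!hold]
    stopifnot(!p %in% train_pid)  # leakage guard
    fold_seed <- .sub_seed(iteration_seed, p)
    res <- .with_seed(fold_seed, {
      ad <- adasyn_oversample(X[!hold, , drop = FALSE], y[!hold], cfg$adasyn_k)
      stopifnot(!any(train_pid[ad$origin[!is.na(ad$origin)]] == p)) # provenance
      yi <- match(ad$labels, .GROUPS) - 1L
      fit <- .rf_fit_predict_cpp(ad$x, yi, K, X[hold, , drop = FALSE],
                                 cfg$n_trees, mtry)
      row_pred <- apply(fit$votes, 1, .vote)
      part_counts <- tabulate(row_pred, K)
      list(pred = .GROUPS[.vote(part_counts)], importance = fit$importance)
    })
    predicted[p] <- res$pred
    imp[p, ] <- res$importance
  }
  list(predicted = predicted, actual = actual, importance = colMeans(imp))
}

#' Run the full classification protocol
#'
#' `n_iterations` independent leave-one-participant-out iterations (seeds
#' derived from the master seed). Per-participant class probabilities are
#' the fraction of iterations assigning each class; the confusion matrix
#' (rows = actual) is averaged over iterations and expressed in row
#' percentages; importances are averaged and normalized to sum 1.
#'
#' @param at an [assemble_table()] result.
#' @param cfg a [classifier_config()].
#' @return Object of class `run_result`: `$predictions` (iteration x
#'   participant), `$probabilities` (participant x 3, rows sum to 1),
#'   `$confusion_mean`, `$confusion_sd` (3 x 3, %), `$importance_mean`,
#'   `$importance_sd`, `$actual`, `$config`, `$seeds`.
#' @export
run_protocol <- function(at, cfg = classifier_config()) {
  pids <- unique(at$table$participant_id)
  n_it <- cfg$n_iterations
  preds <- matrix(NA_character_, n_it, length(pids),
                  dimnames = list(NULL, pids))
  imps <- matrix(NA_real_, n_it, 36)
  cms <- array(NA_real_, c(n_it, 3, 3))
  seeds <- vapply(seq_len(n_it), function(i)
    .sub_seed(cfg$master_seed, paste0("iteration", i)), integer(1))
  actual <- NULL
  for (i in seq_len(n_it)) {
    it <- loocv_iteration(at, cfg, seeds[i])
    preds[i, ] <- it$predicted[pids]
    imps[i, ] <- it$importance
    actual <- it$actual[pids]
    cm <- table(factor(actual, .GROUPS), factor(it$predicted[pids], .GROUPS))
    cms[i, , ] <- 100 * sweep(unclass(cm), 1, pmax(rowSums(cm), 1), `/`)
  }
  probs <- t(vapply(pids, function(p)
    colMeans(outer(preds[, p], .GROUPS, `==`)), numeric(3)))
  colnames(probs) <- .GROUPS
  imp_mean <- colMeans(imps)
  imp_mean <- imp_mean / sum(imp_mean)
  dn <- list(.GROUPS, .GROUPS)
  structure(list(
    predictions = preds,
    probabilities = probs,
    actual = actual,
    confusion_mean = matrix(apply(cms, c(2, 3), mean), 3, 3, dimnames = dn),
    confusion_sd = matrix(apply(cms, c(2, 3), sd), 3, 3, dimnames = dn),
    importance_mean = setNames(imp_mean, at$feature_names),
    importance_sd = setNames(apply(imps, 2, sd), at$feature_names),
    config = cfg, seeds = seeds), class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  acc <- mean(x$predictions[nrow(x$predictions), ] == x$actual)
  cat(sprintf("<run_result> %d iterations x %d participants; last-iteration accuracy %.1f%%\n",
              nrow(x$predictions), ncol(x$predictions), 100 * acc))
  cat("mean confusion matrix (%):\n")
  print(round(x$confusion_mean, 1))
  invisible(x)
}

#' Mean feature importances of a protocol run
#'
#' Mean-decrease-impurity importances, normalized to sum 1, averaged over
#' all folds and iterations.
#'
#' @param run a [run_protocol()] result.
#' @return data.frame `feature`, `importance_mean`, `importance_sd`,
#'   sorted decreasing.
#' @export
feature_importance <- function(run) {
  stopifnot(inherits(run, "run_result"))
  df <- data.frame(feature = names(run$importance_mean),
                   importance_mean = unname(run$importance_mean),
                   importance_sd = unname(run$importance_sd))
  df[order(-df$importance_mean), , drop = FALSE]
}
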