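SPATIAL_FEATURES <- c("sp_left_x", "sp_left_y", "sp_right_x", "sp_right_y")
TEMPORAL_FEATURES <- c("st_left_x", "st_left_y", "st_right_x", "st_right_y")

#' Assemble per-trial feature vectors from embeddings
#'
#' Joins the four per-eye/per-kind embedding tables into one row per
#' subject/trial with 8 features: the permuted-control ("spatial")
#' coordinates `sp_left_x, sp_left_y, sp_right_x, sp_right_y` and the
#' original ("spatial + temporal") coordinates `st_left_x, st_left_y,
#' st_right_x, st_right_y`. Trials missing any eye/kind embedding are
#' dropped; the number dropped is reported via `message()` and attached
#' as attribute `n_dropped`.
#'
#' @param embeddings A list of embedding data.frames (from
#'   [tsne_embed()]/[nmds_embed()], each covering one eye and kind), or
#'   one row-bound data.frame with columns `subject_id, group, trial_id,
#'   eye, kind, dim1, dim2`.
#' @return Data.frame with columns `subject_id, group, trial_id` and the
#'   8 feature columns.
#' @export
assemble_features <- function(embeddings) {
  if (is.data.frame(embeddings)) emb <- embeddings
  else emb <- do.call(rbind, lapply(embeddings, function(e)
    e[c("subject_id", "group", "trial_id", "eye", "kind", "dim1", "dim2")]))
  emb$slot <- paste(ifelse(emb$kind == "permuted", "sp", "st"),
                    emb$eye, sep = "_")
  key <- interaction(emb$subject_id, emb$trial_id, drop = TRUE)
  slots <- c("sp_left", "sp_right", "st_left", "st_right")
  rows <- lapply(split(seq_len(nrow(emb)), key), function(k) {
    have <- emb$slot[k]
    if (!all(slots %in% have)) return(NULL)
    k <- k[match(slots, have)]
    c(as.list(emb[k[1], c("subject_id", "group", "trial_id")]),
      as.list(stats::setNames(
        as.vector(t(as.matrix(emb[k, c("dim1", "dim2")]))),
        c(SPATIAL_FEATURES, TEMPORAL_FEATURES))))
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0)
    stop("no trial has all four eye/kind embeddings", call. = FALSE)
  if (dropped > 0)
    message("dropping ", dropped, " trial(s) with incomplete embeddings")
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  if (any(!is.finite(as.matrix(out[c(SPATIAL_FEATURES, TEMPORAL_FEATURES)]))))
    stop("non-finite feature values", call. = FALSE)
  attr(out, "n_dropped") <- dropped
  out
}

#' Subject-grouped, class-balanced 2-fold split
#'
#' Randomly assigns *subjects* (never individual trials) to two folds so
#' that, within each class, the subject counts of the folds differ by at
#' most one. Grouping by subject prevents leakage of subject identity
#' across folds.
#'
#' @param rows Feature data.frame (needs `subject_id` and `group`).
#' @param seed Integer seed.
#' @return List with character vectors `fold1` and `fold2` of subject ids.
#' @export
grouped_balanced_split <- function(rows, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  subj <- unique(rows[c("subject_id", "group")])
  if (anyDuplicated(subj$subject_id))
    stop("a subject appears with more than one group label", call. = FALSE)
  fold1 <- character(0); fold2 <- character(0)
  for (g in unique(subj$group)) {
    ids <- subj$subject_id[subj$group == g]
    if (length(ids) < 2)
      stop("class '", g, "' has fewer than 2 subjects", call. = FALSE)
    ids <- sample(ids)
    n1 <- if (length(ids) %% 2 == 0) length(ids) / 2
          else sample(c(floor(length(ids) / 2), ceiling(length(ids) / 2)), 1)
    fold1 <- c(fold1, ids[seq_len(n1)])
    fold2 <- c(fold2, ids[-seq_len(n1)])
  }
  list(fold1 = fold1, fold2 = fold2)
}

feature_columns <- function(feature_set) {
  switch(feature_set,
         spatial = SPATIAL_FEATURES,
         full = c(SPATIAL_FEATURES, TEMPORAL_FEATURES),
         stop("unknown feature set '", feature_set, "'", call. = FALSE))
}

#' Train a gradient-boosted tree classifier on trial features
#'
#' Binary gradient-boosted decision trees (xgboost, logistic objective)
#' with at most 50 boosting rounds and maximum depth 6. Class priors are
#' equalized at 0.5 by weighting each class inversely to its frequency in
#' the training rows.
#'
#' @param rows Feature data.frame (see [assemble_features()]).
#' @param feature_set `"spatial"` (4 permuted-control coordinates) or
#'   `"full"` (all 8 coordinates).
#' @param nrounds,max_depth Boosting rounds and tree depth caps.
#' @return List of class `gaze_classifier` with the fitted booster, the
#'   feature columns and the positive-class label.
#' @export
train_classifier <- function(rows, feature_set = c("full", "spatial"),
                             nrounds = 50, max_depth = 6) {
  feature_set <- match.arg(feature_set)
  cols <- feature_columns(feature_set)
  classes <- sort(unique(rows$group))
  if (length(classes) != 2)
    stop("training rows must contain exactly two classes", call. = FALSE)
  y <- as.integer(rows$group == classes[2])
  w <- ifelse(y == 1, nrow(rows) / (2 * sum(y == 1)),
              nrow(rows) / (2 * sum(y == 0)))
  dtrain <- xgboost::xgb.DMatrix(as.matrix(rows[cols]), label = y, weight = w,
                                 nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = 0.3, nthread = 1, seed = 1),
    data = dtrain, nrounds = nrounds, verbose = 0)
  structure(list(booster = booster, features = cols,
                 classes = classes),
            class = "gaze_classifier")
}

#' @export
predict.gaze_classifier <- function(object, newdata, ...) {
  dm <- xgboost::xgb.DMatrix(as.matrix(newdata[object$features]), nthread = 1)
  p <- stats::predict(object$booster, dm)
  object$classes[(p > 0.5) + 1L]
}

classifier_accuracy <- function(model, rows) {
  mean(predict(model, rows) == rows$group)
}

confusion_update <- function(conf, model, rows) {
  pred <- predict(model, rows)
  for (a in rownames(conf)) for (p in colnames(conf))
    conf[a, p] <- conf[a, p] + sum(rows$group == a & pred == p)
  conf
}

#' 5x2 cross-validated paired t-test between feature sets
#'
#' Dietterich's 5x2cv comparison of the spatial-only classifier against
#' the spatial + temporal classifier. Five times, the subjects are split
#' into two grouped, class-balanced folds; both models are trained on one
#' fold and evaluated on the other (both directions). With fold-wise
#' accuracy differences `d = acc_spatial - acc_full`, the statistic is
#' `t = d_1^(1) / sqrt(mean(s_i^2))` with `s_i^2` the per-iteration
#' variance of the two fold differences, referred to a t distribution
#' with 5 degrees of freedom (two-sided). A negative t means the
#' spatial + temporal model is more accurate. `numerator = "mean"`
#' replaces the first-difference numerator by the mean of all ten
#' differences (a common variant).
#'
#' @param rows Feature data.frame.
#' @param seed Integer seed driving the five fold splits.
#' @param numerator `"first"` (Dietterich's original) or `"mean"`.
#' @param nrounds,max_depth Passed to [train_classifier()].
#' @return List of class `cv_comparison`: `acc_spatial`, `acc_full` (mean
#'   accuracy across the 10 fold evaluations), `t_stat`, `df = 5`,
#'   `p_value`, `fold_log` (per-iteration/fold accuracies), and
#'   aggregated `confusion` matrices per model.
#' @export
five_by_two_cv <- function(rows, seed = 1, numerator = c("first", "mean"),
                           nrounds = 50, max_depth = 6) {
  numerator <- match.arg(numerator)
  classes <- sort(unique(rows$group))
  conf <- matrix(0L, 2, 2, dimnames = list(actual = classes,
                                           predicted = classes))
  confusion <- list(spatial = conf, full = conf)
  fold_log <- NULL
  d <- matrix(NA_real_, 5, 2)
  set.seed(seed)
  split_seeds <- sample.int(.Machine$integer.max, 5)
  for (i in 1:5) {
    folds <- grouped_balanced_split(rows, seed = split_seeds[i])
    for (j in 1:2) {
      train_ids <- if (j == 1) folds$fold1 else folds$fold2
      test_ids <- if (j == 1) folds$fold2 else folds$fold1
      tr <- rows[rows$subject_id %in% train_ids, , drop = FALSE]
      te <- rows[rows$subject_id %in% test_ids, , drop = FALSE]
      m_sp <- train_classifier(tr, "spatial", nrounds, max_depth)
      m_fu <- train_classifier(tr, "full", nrounds, max_depth)
      acc_sp <- classifier_accuracy(m_sp, te)
      acc_fu <- classifier_accuracy(m_fu, te)
      confusion$spatial <- confusion_update(confusion$spatial, m_sp, te)
      confusion$full <- confusion_update(confusion$full, m_fu, te)
      d[i, j] <- acc_sp - acc_fu
      fold_log <- rbind(fold_log, data.frame(
        iteration = i, fold = j, acc_spatial = acc_sp, acc_full = acc_fu))
    }
  }
  dbar <- rowMeans(d)
  s2 <- (d[, 1] - dbar)^2 + (d[, 2] - dbar)^2
  denom <- sqrt(mean(s2))
  num <- if (numerator == "first") d[1, 1] else mean(d)
  if (denom == 0) {
    t_stat <- if (num == 0) 0 else sign(num) * Inf
    p <- if (num == 0) 1 else 0
  } else {
    t_stat <- num / denom
    p <- 2 * stats::pt(-abs(t_stat), df = 5)
  }
  structure(list(
    acc_spatial = mean(fold_log$acc_spatial),
    acc_full = mean(fold_log$acc_full),
    t_stat = t_stat, df = 5L, p_value = p,
    numerator = numerator, fold_log = fold_log,
    confusion = confusion, seed = seed
  ), class = "cv_comparison")
}

#' @export
print.cv_comparison <- function(x, ...) {
  cat(sprintf(paste0(
    "5x2cv classifier comparison (spatial vs spatial + temporal)\n",
    "  mean accuracy: spatial = %.1f%%, spatial + temporal = %.1f%%\n",
    "  t(%d) = %.3f, p = %.4g  (numerator: %s difference)\n"),
    100 * x$acc_spatial, 100 * x$acc_full, x$df, x$t_stat, x$p_value,
    x$numerator))
  invisible(x)
}

#' Subject-level label-permutation test of classifier accuracy
#'
#' Verifies that a classifier's grouped 2-fold cross-validated accuracy
#' exceeds chance: group labels are permuted across *subjects* (keeping
#' each subject's trials together, to respect the grouped-fold structure)
#' `k` times, the cross-validation is re-run on each permuted labelling,
#' and `p = (#\{perm >= observed\} + 1) / (k + 1)`.
#'
#' @param rows Feature data.frame.
#' @param feature_set `"spatial"` or `"full"`.
#' @param k Number of label permutations (default 1000; warning below
#'   100).
#' @param seed Integer seed.
#' @param nrounds,max_depth Passed to [train_classifier()].
#' @return List with `observed` accuracy, `p_value`, `k` and the
#'   permutation accuracies.
#' @export
label_permutation_test <- function(rows, feature_set = c("full", "spatial"),
                                   k = 1000, seed = 1, nrounds = 50,
                                   max_depth = 6) {
  feature_set <- match.arg(feature_set)
  if (k < 100) warning("fewer than 100 label permutations; p-value is coarse")
  cv_acc <- function(r, split_seed) {
    folds <- grouped_balanced_split(r, seed = split_seed)
    accs <- vapply(1:2, function(j) {
      tr <- r[r$subject_id %in% (if (j == 1) folds$fold1 else folds$fold2), ]
      te <- r[r$subject_id %in% (if (j == 1) folds$fold2 else folds$fold1), ]
      classifier_accuracy(train_classifier(tr, feature_set, nrounds,
                                           max_depth), te)
    }, numeric(1))
    mean(accs)
  }
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, k + 1)
  observed <- cv_acc(rows, seeds[1])
  subj <- unique(rows[c("subject_id", "group")])
  perm_acc <- vapply(seq_len(k), function(i) {
    set.seed(seeds[i + 1])
    relabel <- stats::setNames(sample(subj$group), subj$subject_id)
    r <- rows
    r$group <- unname(relabel[r$subject_id])
    cv_acc(r, seeds[i + 1])
  }, numeric(1))
  list(observed = observed,
       p_value = (sum(perm_acc >= observed) + 1) / (k + 1),
       k = as.integer(k), feature_set = feature_set,
       permutation_accuracies = perm_acc, seed = seed)
}
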