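feature_names <- c("sp_left_x", "sp_left_y", "sp_right_x", "sp_right_y",
                   "st_left_x", "st_left_y", "st_right_x", "st_right_y")

make_features <- function(nsub = 6, ntrials = 8, shift_spatial = 0,
                          shift_temporal = 0, seed = 1) {
  set.seed(seed)
  rows <- expand.grid(subject = 1:(2 * nsub), trial = 1:ntrials)
  grp <- ifelse(rows$subject <= nsub, "A", "B")
  X <- matrix(rnorm(nrow(rows) * 8), ncol = 8,
              dimnames = list(NULL, feature_names))
  delta <- ifelse(grp == "B", 1, 0)
  X[, 1:4] <- X[, 1:4] + delta * shift_spatial
  X[, 5:8] <- X[, 5:8] + delta * shift_temporal
  cbind(data.frame(subject_id = sprintf("s%02d", rows$subject), group = grp,
                   trial_id = sprintf("t%02d", rows$trial),
                   stringsAsFactors = FALSE),
        as.data.frame(X))
}

embedding_row <- function(subject, trial, eye, kind, x, y, group = "A") {
  data.frame(subject_id = subject, group = group, trial_id = trial,
             eye = eye, kind = kind, dim1 = x, dim2 = y,
             stringsAsFactors = FALSE)
}

test_that("feature assembly joins the four embeddings in a fixed layout", {
  emb <- rbind(
    embedding_row("s1", "t1", "left", "permuted", 1, 2),
    embedding_row("s1", "t1", "right", "permuted", 3, 4),
    embedding_row("s1", "t1", "left", "original", 5, 6),
    embedding_row("s1", "t1", "right", "original", 7, 8))
  f <- suppressMessages(assemble_features(emb))
  expect_equal(nrow(f), 1)
  expect_equal(unlist(f[feature_names], use.names = FALSE), 1:8)
  # a trial missing one eye/kind is dropped (and counted)
  emb2 <- rbind(emb, embedding_row("s1", "t2", "left", "original", 0, 0))
  f2 <- suppressMessages(assemble_features(emb2))
  expect_equal(nrow(f2), 1)
  expect_equal(attr(f2, "n_dropped"), 1)
  expect_error(suppressMessages(
    assemble_features(emb2[5, , drop = FALSE])), "no trial")
})

test_that("fold splits are grouped by subject and balanced per class", {
  f44 <- make_features(nsub = 4, ntrials = 2)
  sp <- grouped_balanced_split(f44, seed = 3)
  expect_length(intersect(sp$fold1, sp$fold2), 0)
  expect_setequal(c(sp$fold1, sp$fold2), unique(f44$subject_id))
  for (fold in sp) {
    g <- unique(f44[f44$subject_id %in% fold, c("subject_id", "group")])
    expect_equal(unname(table(g$group)["A"]), 2)
    expect_equal(unname(table(g$group)["B"]), 2)
  }
  f55 <- make_features(nsub = 5, ntrials = 2)
  for (s in 1:5) {
    sp5 <- grouped_balanced_split(f55, seed = s)
    for (fold in sp5) {
      g <- unique(f55[f55$subject_id %in% fold, c("subject_id", "group")])
      expect_true(all(table(g$group) %in% 2:3))
    }
  }
  one <- make_features(nsub = 1, ntrials = 2)
  expect_error(grouped_balanced_split(one, seed = 1), "fewer than 2")
})

test_that("the boosted classifier separates separable features", {
  f <- make_features(nsub = 6, ntrials = 10, shift_spatial = 4, seed = 5)
  m <- train_classifier(f, "spatial")
  expect_gte(mean(predict(m, f) == f$group), 0.95)
  m8 <- train_classifier(f, "full")
  expect_gte(mean(predict(m8, f) == f$group), 0.95)
  # determinism
  m2 <- train_classifier(f, "spatial")
  expect_identical(predict(m, f), predict(m2, f))
  single <- f[f$group == "A", ]
  expect_error(train_classifier(single, "full"), "two classes")
})

test_that("5x2cv is degenerate-safe and seeded", {
  # temporal block duplicates the (separable) spatial block: both models
  # are perfect, all fold differences are zero
  f <- make_features(nsub = 4, ntrials = 6, shift_spatial = 6, seed = 7)
  f[feature_names[5:8]] <- f[feature_names[1:4]]
  cv <- five_by_two_cv(f, seed = 11)
  expect_equal(cv$t_stat, 0)
  expect_equal(cv$p_value, 1)
  expect_equal(cv$df, 5L)
  expect_equal(cv$fold_log$acc_spatial, cv$fold_log$acc_full)
  expect_equal(sum(cv$confusion$spatial), 10 * nrow(f) / 2)
  cv2 <- five_by_two_cv(f, seed = 11)
  expect_identical(cv$fold_log, cv2$fold_log)
})

test_that("5x2cv favors the full model when only the temporal block is informative", {
  f <- make_features(nsub = 8, ntrials = 12, shift_temporal = 3, seed = 13)
  cv <- five_by_two_cv(f, seed = 17)
  expect_gt(cv$acc_full, cv$acc_spatial)
  expect_lt(cv$t_stat, 0)
  expect_lt(cv$p_value, 0.05)
  # chance-level spatial model: accuracy near 0.5
  expect_lt(abs(cv$acc_spatial - 0.5), 0.12)
})

test_that("pure-noise features leave both models at chance", {
  accs <- vapply(1:3, function(s) {
    f <- make_features(nsub = 6, ntrials = 10, seed = 100 + s)
    cv <- five_by_two_cv(f, seed = s)
    c(cv$acc_spatial, cv$acc_full)
  }, numeric(2))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("renaming subjects consistently does not change the comparison", {
  f <- make_features(nsub = 5, ntrials = 8, shift_temporal = 2, seed = 19)
  cv1 <- five_by_two_cv(f, seed = 23)
  f2 <- f
  f2$subject_id <- chartr("s", "x", f$subject_id)
  cv2 <- five_by_two_cv(f2, seed = 23)
  expect_equal(cv1$t_stat, cv2$t_stat)
  expect_equal(cv1$acc_spatial, cv2$acc_spatial)
  expect_equal(cv1$acc_full, cv2$acc_full)
})

test_that("the label-permutation test calibrates against subject relabeling", {
  f <- make_features(nsub = 6, ntrials = 10, shift_temporal = 4, seed = 29)
  r <- suppressWarnings(
    label_permutation_test(f, "full", k = 49, seed = 31))
  expect_equal(r$p_value, 1 / 50)             # beats all permutations
  r2 <- suppressWarnings(
    label_permutation_test(f, "full", k = 49, seed = 31))
  expect_identical(r$permutation_accuracies, r2$permutation_accuracies)
  noise <- make_features(nsub = 6, ntrials = 10, seed = 37)
  rn <- suppressWarnings(
    label_permutation_test(noise, "full", k = 49, seed = 41))
  expect_gt(rn$p_value, 0.05)
  expect_warning(label_permutation_test(f, "full", k = 20, seed = 1), "100")
})
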