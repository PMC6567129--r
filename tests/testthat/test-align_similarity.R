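test_that("pairwise AOI distances average per pair across layouts", {
  lm <- schematic_face_landmarks()
  ly1 <- build_layout(lm, image_id = "a")
  d1 <- average_pair_distances(ly1)
  expect_equal(unname(diag(d1)), rep(0, 76))
  expect_equal(unname(d1[1, 2]),
               sqrt(diff(ly1$points$x[1:2])^2 + diff(ly1$points$y[1:2])^2))
  lm2 <- lm; lm2$x <- lm2$x + 10   # rigid shift: same pair distances
  ly2 <- build_layout(lm2, image_id = "b")
  d12 <- average_pair_distances(list(ly1, ly2))
  # frame points shift too, so all pair distances are preserved exactly
  expect_equal(d12, d1, tolerance = 1e-12)
  # genuine averaging: stretch one layout by 2 -> mean = 1.5 x original
  lm3 <- lm
  lm3$x <- 2 * lm3$x; lm3$y <- 2 * lm3$y
  ly3 <- build_layout(lm3, image_id = "c", frame_margin = NULL)
  d13 <- average_pair_distances(list(ly1, ly3))
  expect_equal(unname(d13[1, 5]), unname(1.5 * d1[1, 5]), tolerance = 1e-9)
})

test_that("substitution scores hit the +1 / -1 anchors and the toy values", {
  # A1, A2 same group at distance 2; B in another group at 4 and 5
  d <- matrix(c(0, 2, 4,
                2, 0, 5,
                4, 5, 0), 3, 3, byrow = TRUE)
  s <- build_substitution_matrix(d, groups = c("g1", "g1", "g2"))
  expect_equal(unname(s[1, 2]), 1)        # closest same-group pair
  expect_equal(unname(s[1, 3]), -0.8)     # -4/5
  expect_equal(unname(s[2, 3]), -1)       # most distant cross-group pair
  expect_equal(unname(diag(s)), rep(1, 3))
  expect_true(isSymmetric(unname(unclass(s))))
  expect_error(
    build_substitution_matrix(matrix(c(0, 0, 3, 0, 0, 3, 3, 3, 0), 3),
                              groups = c("g1", "g1", "g2")),
    "zero distance")
})

test_that("substitution scores are monotone in distance within each branch", {
  set.seed(31)
  lm <- schematic_face_landmarks()
  lm$x <- lm$x + rnorm(68, sd = 4); lm$y <- lm$y + rnorm(68, sd = 4)
  ly <- build_layout(lm, image_id = "m")
  d <- average_pair_distances(ly)
  for (form in c("reciprocal", "linear")) {
    s <- build_substitution_matrix(d, form = form)
    g <- attr(s, "groups")
    same <- outer(g, g, "==") & !diag(76)
    expect_equal(max(s[same]), 1)
    expect_equal(min(s[!same & !diag(76)]), -1)
    expect_true(all(s >= -1 & s <= 1))
    # same-group: larger distance, no larger score (strict off the clip)
    iu <- which(same & upper.tri(s), arr.ind = TRUE)
    o <- order(d[iu])
    expect_true(all(diff(s[iu][o]) <= 1e-12))
    cu <- which(!same & upper.tri(s), arr.ind = TRUE)
    oc <- order(d[cu])
    expect_true(all(diff(s[cu][oc]) <= 1e-12))
  }
})

test_that("alignment scores match exhaustive enumeration on toy cases", {
  s3 <- matrix(c(1, -1, 0, -1, 1, 0, 0, 0, 1), 3, 3)
  sub <- make_sub(s3, gap = 0)
  L <- 7
  expect_equal(nw_score(rep(1L, L), rep(1L, L), sub), L)  # identity
  expect_equal(nw_score(c(1L, 2L), c(2L, 1L), sub), 1)    # gap one out
  sub05 <- make_sub(matrix(c(1, 0.5, 0.5, 1), 2), gap = 0)
  expect_equal(nw_score(1L, 2L, sub05), 0.5)              # sub beats 2 gaps
  subg <- make_sub(matrix(c(1, -0.9, -0.9, 1), 2), gap = -0.2)
  # substitution (-0.9) loses to two gaps (-0.4)
  expect_equal(nw_score(1L, 2L, subg), -0.4)
  expect_error(nw_score(c(1L, 4L), 1L, sub05), "alphabet")
})

test_that("the dynamic program equals brute-force alignment enumeration", {
  set.seed(41)
  for (gap in c(0, -0.4)) {
    scores <- random_scores(3)
    sub <- make_sub(scores, gap = gap)
    short <- all_strings(1:3, 3)
    for (a in short) for (b in short)
      expect_equal(nw_score(a, b, sub),
                   align_enumerate(a, b, scores, gap))
    for (rep in 1:60) {
      a <- sample(1:3, sample(4:6, 1), replace = TRUE)
      b <- sample(1:3, sample(4:6, 1), replace = TRUE)
      expect_equal(nw_score(a, b, sub),
                   align_enumerate(a, b, scores, gap))
    }
  }
})

test_that("alignment score is symmetric and self-similarity is 1", {
  set.seed(51)
  sub <- make_sub(random_scores(4), gap = -0.1)
  for (i in 1:25) {
    a <- sample(1:4, sample(1:8, 1), replace = TRUE)
    b <- sample(1:4, sample(1:8, 1), replace = TRUE)
    expect_equal(nw_score(a, b, sub), nw_score(b, a, sub))
    expect_equal(normalized_similarity(a, b, sub),
                 normalized_similarity(b, a, sub))
  }
  sub0 <- make_sub(random_scores(4), gap = 0)
  a <- sample(1:4, 10, replace = TRUE)
  expect_equal(normalized_similarity(a, a, sub0), 1)
})

test_that("normalization divides by the longer string's length", {
  sub <- make_sub(matrix(1, 1, 1), gap = 0)
  a <- rep(1L, 30); b <- rep(1L, 40)
  # all-match score is 30 (shorter length); divisor must be 40
  expect_equal(normalized_similarity(a, b, sub), 30 / 40)
  expect_equal(nw_score(a, b, sub) / 40, normalized_similarity(a, b, sub))
})

test_that("the similarity matrix is symmetric and matches per-pair scores", {
  set.seed(61)
  sub <- make_sub(random_scores(3), gap = 0)
  sp <- make_scanpaths(list(c(1L, 2L, 3L), c(3L, 2L), c(1L, 1L, 2L, 3L),
                            c(2L, 2L, 2L)))
  S <- similarity_matrix(sp, sub)
  expect_equal(dim(S), c(4, 4))
  expect_true(isSymmetric(unname(unclass(S))))
  for (i in 1:4) for (j in 1:4)
    expect_equal(unname(S[i, j]),
                 normalized_similarity(sp$codes[[i]], sp$codes[[j]], sub))
  ident <- make_scanpaths(list(c(1L, 2L), c(1L, 2L)))
  S2 <- similarity_matrix(ident, make_sub(diag(2) * 2 - 1, gap = 0))
  expect_equal(matrix(as.numeric(S2), 2, 2), matrix(1, 2, 2))
  empty <- make_scanpaths(list(integer(0), c(1L, 2L)))
  expect_error(similarity_matrix(empty, sub), "non-empty")
})

test_that("Levenshtein distance matches known edit counts", {
  expect_equal(levenshtein("abc", "abc"), 0L)
  expect_equal(levenshtein("abc", "abd"), 1L)
  expect_equal(levenshtein("", "abc"), 3L)
  expect_equal(levenshtein(c(1L, 2L, 3L), c(1L, 3L)), 1L)
  sp <- make_scanpaths(list(c(1L, 2L, 3L), c(1L, 3L), c(2L, 2L)))
  M <- levenshtein_matrix(sp)
  expect_equal(unname(M[1, 2]), 1)
  expect_equal(unname(M[2, 3]), 2)
  expect_true(isSymmetric(unname(unclass(M))))
})
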