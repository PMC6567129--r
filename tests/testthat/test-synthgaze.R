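test_that("the schematic face layout is a fixed 76-point template", {
  ly1 <- schematic_face_layout()
  ly2 <- schematic_face_layout()
  expect_identical(ly1$points, ly2$points)
  expect_equal(nrow(ly1$points), 76)
  expect_equal(sum(ly1$points$group == "frame"), 8)
  expect_setequal(unique(ly1$points$group),
                  c("outline", "mouth", "nose", "eyes", "eyebrows", "frame"))
  # screen coordinates: eyes above (smaller y than) the mouth
  pts <- ly1$points
  expect_lt(mean(pts$y[pts$group == "eyes"]),
            mean(pts$y[pts$group == "mouth"]))
  expect_lt(mean(pts$y[pts$group == "eyebrows"]),
            mean(pts$y[pts$group == "eyes"]))
})

test_that("scenario chains are row-stochastic with the stated structure", {
  for (eff in c("null", "spatial", "temporal")) {
    ch <- scenario_chains(sim_scenario(effect = eff, effect_size = 1))
    expect_equal(unname(rowSums(ch$A)), rep(1, 6), tolerance = 1e-12)
    expect_equal(unname(rowSums(ch$B)), rep(1, 6), tolerance = 1e-12)
    expect_true(all(ch$A >= 0) && all(ch$B >= 0))
  }
  expect_identical(scenario_chains(sim_scenario(effect = "null"))$B,
                   scenario_chains(sim_scenario(effect = "null"))$A)
})

test_that("the temporal scenario reverses flow but keeps visit frequencies", {
  for (e in c(0.5, 1)) {
    ch <- scenario_chains(sim_scenario(effect = "temporal", effect_size = e))
    expect_equal(unname(ch$pi_A), unname(ch$pi_B), tolerance = 1e-9)
    if (e == 1) {
      # group A flows eyes -> nose -> mouth; group B the reverse
      expect_gt(ch$A["eyes", "nose"], ch$A["nose", "eyes"])
      expect_gt(ch$B["nose", "eyes"], ch$B["eyes", "nose"])
      expect_gt(ch$B["mouth", "nose"], ch$B["nose", "mouth"])
    }
  }
})

test_that("the spatial scenario shifts stationary mass from eyes to mouth", {
  ch <- scenario_chains(sim_scenario(effect = "spatial", effect_size = 1))
  expect_lt(ch$pi_B["eyes"], ch$pi_A["eyes"])
  expect_gt(ch$pi_B["mouth"], ch$pi_A["mouth"])
})

test_that("simulated studies round-trip through the file readers", {
  st <- tiny_study(seed = 3, nsub = 2, ntrials = 2)
  dir <- tempfile()
  write_study(st, dir)
  fx <- read_fixations(file.path(dir, "fixations.csv"))
  lm <- read_landmarks(file.path(dir, "landmarks.csv"))
  expect_equal(nrow(fx), nrow(st$fixations))
  expect_equal(length(unique(paste(fx$subject_id, fx$trial_id))), 8)
  expect_equal(nrow(lm), 68 * 2)
  expect_true(file.exists(file.path(dir, "truth.json")))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$scenario$effect, "null")
})

test_that("trial generation respects the stopping rule", {
  st <- tiny_study(seed = 5, nsub = 2, ntrials = 3)
  fx <- st$fixations
  key <- paste(fx$subject_id, fx$trial_id, fx$eye)
  for (k in split(seq_len(nrow(fx)), key)) {
    total <- sum(fx$duration_ms[k])
    before_last <- total - fx$duration_ms[k[length(k)]]
    expect_lt(before_last, 2000)   # generation stopped at the crossing dwell
    expect_gte(total, 2000)        # ... which completes the trial
  }
})

test_that("studies are byte-identical under a fixed seed", {
  s1 <- tiny_study(seed = 11)
  s2 <- tiny_study(seed = 11)
  expect_identical(s1$fixations, s2$fixations)
  expect_identical(s1$landmarks, s2$landmarks)
  d1 <- tempfile(); d2 <- tempfile()
  write_study(s1, d1); write_study(s2, d2)
  for (f in c("fixations.csv", "landmarks.csv", "truth.json"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  s3 <- tiny_study(seed = 12)
  expect_false(identical(s1$fixations, s3$fixations))
})

test_that("temporal scenario: matched visit frequencies, different transitions", {
  # Long simulation of both groups' chains via simulated trials; the AOI
  # group visit counts must agree across groups (chi-square p > 0.01)
  # while first-order transition counts differ sharply.
  sc <- sim_scenario(effect = "temporal", effect_size = 1, seed = 17)
  ch <- scenario_chains(sc)
  ly <- schematic_face_layout()
  set.seed(17)
  states_of <- function(group) {
    out <- character(0)
    while (length(out) < 10000) {
      fx <- simulate_trial(sc, group, ly, ch)
      fx <- fx[fx$eye == "left", ]
      nearest <- apply(outer(fx$x, ly$points$x, "-")^2 +
                       outer(fx$y, ly$points$y, "-")^2, 1, which.min)
      out <- c(out, ly$points$group[nearest])
    }
    out[1:10000]
  }
  sA <- states_of("A"); sB <- states_of("B")
  grps <- unique(ly$points$group)
  visit <- rbind(table(factor(sA, grps)), table(factor(sB, grps)))
  expect_gt(suppressWarnings(chisq.test(visit))$p.value, 0.01)
  trans <- function(s) table(factor(paste(head(s, -1), tail(s, -1)),
                                    levels = as.vector(outer(grps, grps,
                                                             paste))))
  tt <- rbind(trans(sA), trans(sB))
  tt <- tt[, colSums(tt) > 0]
  expect_lt(suppressWarnings(chisq.test(tt))$p.value, 1e-6)
})
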