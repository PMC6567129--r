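AOI_GROUPS <- c("outline", "mouth", "nose", "eyes", "eyebrows", "frame")

#' Simulation scenario for synthetic gaze studies
#'
#' Bundles the parameters of a synthetic two-group eye-tracking study:
#' 2-second facial-image exposures whose fixations follow a first-order
#' Markov chain over the six AOI semantic groups. The group difference is
#' controlled by `effect`:
#' \describe{
#'   \item{null}{both groups share one transition matrix;}
#'   \item{temporal}{group B's chain is the interpolation `(1 - e) P_A +
#'     e rev(P_A)` with the time-reversed chain `rev(P_A)` — at
#'     `effect_size = 1` group A cycles eyes -> nose -> mouth while group
#'     B cycles mouth -> nose -> eyes, and the two chains have *exactly*
#'     the same stationary AOI distribution (visit frequencies), so the
#'     difference is purely temporal;}
#'   \item{spatial}{group B's transition rows are reweighted to move
#'     stationary mass from the eyes to the mouth, leaving the transition
#'     order otherwise matched.}
#' }
#'
#' @param n_subjects_per_group Subjects per group (default 20).
#' @param trials_per_subject Trials (image exposures) per subject
#'   (default 30).
#' @param trial_duration_ms Exposure duration, default 2000 ms.
#' @param effect `"null"`, `"spatial"` or `"temporal"`.
#' @param effect_size Effect strength in \[0, 1\].
#' @param dwell_mean_ms Mean fixation duration (gamma), default 300 ms.
#' @param dwell_shape Gamma shape of fixation durations, default 4.
#' @param jitter_px SD of Gaussian position jitter around the fixated AOI
#'   point, default 10 px.
#' @param n_images Number of distinct facial images (layout variants),
#'   default 6.
#' @param landmark_jitter_px SD of per-image landmark perturbation,
#'   default 3 px.
#' @param width,height Screen size in px (default 1280 x 720).
#' @param group_labels Two group labels, default `c("A", "B")`.
#' @param seed Master seed of the study.
#' @return List of class `sim_scenario`.
#' @export
sim_scenario <- function(n_subjects_per_group = 20, trials_per_subject = 30,
                         trial_duration_ms = 2000,
                         effect = c("null", "spatial", "temporal"),
                         effect_size = 1, dwell_mean_ms = 300,
                         dwell_shape = 4, jitter_px = 10, n_images = 6,
                         landmark_jitter_px = 3, width = 1280, height = 720,
                         group_labels = c("A", "B"), seed = 1) {
  effect <- match.arg(effect)
  stopifnot(n_subjects_per_group >= 1, trials_per_subject >= 1,
            trial_duration_ms > 0, effect_size >= 0, effect_size <= 1,
            dwell_mean_ms > 0, dwell_shape > 0, jitter_px >= 0,
            n_images >= 1, length(group_labels) == 2)
  structure(as.list(environment()), class = "sim_scenario")
}

# Baseline chain over the six AOI groups, with a pronounced
# eyes -> nose -> mouth -> eyes cycle (rows = from, cols = to).
base_transition_matrix <- function() {
  P <- matrix(c(
    # outline mouth nose eyes eyebrows frame
      0.15,  0.20, 0.20, 0.30, 0.10,   0.05,  # outline
      0.07,  0.20, 0.10, 0.60, 0.02,   0.01,  # mouth
      0.07,  0.60, 0.15, 0.10, 0.05,   0.03,  # nose
      0.04,  0.05, 0.60, 0.20, 0.10,   0.01,  # eyes
      0.07,  0.15, 0.25, 0.40, 0.10,   0.03,  # eyebrows
      0.30,  0.15, 0.15, 0.25, 0.05,   0.10   # frame
  ), nrow = 6, byrow = TRUE, dimnames = list(AOI_GROUPS, AOI_GROUPS))
  P
}

#' Stationary distribution of a transition matrix
#' @param P Row-stochastic matrix.
#' @return Probability vector pi with `pi %*% P = pi`.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  stats::setNames(v / sum(v), rownames(P))
}

reverse_chain <- function(P) {
  pi <- stationary_distribution(P)
  R <- t(P * pi) / pi   # R[i, j] = pi_j P[j, i] / pi_i
  dimnames(R) <- dimnames(P)
  R
}

#' Group-wise transition matrices of a scenario
#'
#' @param scenario A `sim_scenario`.
#' @return List with matrices `A`, `B` and their stationary vectors
#'   `pi_A`, `pi_B`.
#' @export
scenario_chains <- function(scenario) {
  P_A <- base_transition_matrix()
  e <- scenario$effect_size
  P_B <- switch(scenario$effect,
    null = P_A,
    temporal = (1 - e) * P_A + e * reverse_chain(P_A),
    spatial = {
      w <- c(outline = 1, mouth = 1 + e, nose = 1, eyes = 1 - 0.6 * e,
             eyebrows = 1, frame = 1)
      Pb <- sweep(P_A, 2, w[colnames(P_A)], "*")
      Pb / rowSums(Pb)
    })
  list(A = P_A, B = P_B,
       pi_A = stationary_distribution(P_A),
       pi_B = stationary_distribution(P_B))
}

#' Deterministic schematic face AOI layout
#'
#' Places 68 landmark points (17 face-outline, 10 eyebrow, 9 nose, 12
#' eye, 20 mouth points, the usual facial-landmark convention) at
#' plausible relative positions on a screen of the given size, centered,
#' plus the 8 exterior frame points. Screen coordinates: origin top-left,
#' y increases downward, so the eyes lie *above* the mouth at smaller y.
#' The layout is a fixed deterministic template: two calls with the same
#' dimensions are identical.
#'
#' @param width,height Screen size in pixels.
#' @param image_id Identifier of the produced layout.
#' @return An `aoi_layout` (76 points).
#' @export
schematic_face_layout <- function(width = 1280, height = 720,
                                  image_id = "schematic") {
  build_layout(schematic_face_landmarks(width, height), image_id = image_id)
}

#' @rdname schematic_face_layout
#' @return `schematic_face_landmarks()` returns the 68-landmark
#'   data.frame (`point_id` 0..67, `group`, `x`, `y`) without frame
#'   points, i.e. the shape of an upstream landmark-detector output.
#' @export
schematic_face_landmarks <- function(width = 1280, height = 720) {
  cx <- width / 2; cy <- height / 2
  s <- min(width, height) / 720          # scale relative to a 720p screen
  a <- 190 * s; b <- 250 * s             # face half-width / half-height
  th <- seq(0, pi, length.out = 17)
  outline <- cbind(cx - a * cos(th), cy + 0.95 * b * sin(th) + 0.05 * b)
  brow_l <- cbind(cx - seq(150, 50, length.out = 5) * s,
                  cy - (120 + c(0, 12, 16, 12, 0)) * s)
  brow_r <- cbind(cx + seq(50, 150, length.out = 5) * s,
                  cy - (120 + c(0, 12, 16, 12, 0)) * s)
  nose <- rbind(cbind(cx, cy + seq(-80, 10, length.out = 4) * s),
                cbind(cx + seq(-40, 40, length.out = 5) * s, cy + 40 * s))
  eye_hex <- function(ex) {
    ang <- seq(0, 2 * pi, length.out = 7)[-7]
    cbind(ex + 35 * s * cos(ang), cy - 70 * s + 15 * s * sin(ang))
  }
  mouth_out <- {
    ang <- seq(0, 2 * pi, length.out = 13)[-13]
    cbind(cx + 70 * s * cos(ang), cy + 140 * s + 30 * s * sin(ang))
  }
  mouth_in <- {
    ang <- seq(0, 2 * pi, length.out = 9)[-9]
    cbind(cx + 45 * s * cos(ang), cy + 140 * s + 12 * s * sin(ang))
  }
  pts <- rbind(outline, brow_l, brow_r, nose, eye_hex(cx - 90 * s),
               eye_hex(cx + 90 * s), mouth_out, mouth_in)
  data.frame(
    point_id = 0:67,
    group = rep(c("outline", "eyebrows", "nose", "eyes", "mouth"),
                times = c(17, 10, 9, 12, 20)),
    x = pts[, 1], y = pts[, 2], stringsAsFactors = FALSE)
}

#' Simulate the fixation sequence of one trial
#'
#' Draws a Markov chain over the six AOI groups (started from the group's
#' stationary distribution), gamma-distributed dwell times, and fixation
#' positions at a uniformly chosen member point of the visited group plus
#' Gaussian jitter. Generation stops once cumulative dwell time reaches
#' the trial duration (the crossing fixation is kept). Two eye streams
#' share the AOI sequence and dwells; each eye's x position is displaced
#' a few pixels towards its own side plus small per-eye noise.
#'
#' Uses the current R RNG state; seed at the study level (see
#' [simulate_study()]).
#'
#' @param scenario A `sim_scenario`.
#' @param group `"A"` or `"B"` (which group's chain to use).
#' @param layout The trial image's `aoi_layout`.
#' @param chains Optional precomputed [scenario_chains()] result.
#' @return Data.frame of fixations for both eyes (without subject/trial
#'   identifiers).
#' @export
simulate_trial <- function(scenario, group = c("A", "B"), layout,
                           chains = scenario_chains(scenario)) {
  group <- match.arg(group)
  P <- if (group == "A") chains$A else chains$B
  pi0 <- if (group == "A") chains$pi_A else chains$pi_B
  states <- character(0); dwell <- numeric(0); total <- 0
  st <- sample(AOI_GROUPS, 1, prob = pi0)
  while (total < scenario$trial_duration_ms) {
    dw <- stats::rgamma(1, shape = scenario$dwell_shape,
                        scale = scenario$dwell_mean_ms / scenario$dwell_shape)
    states <- c(states, st); dwell <- c(dwell, dw); total <- total + dw
    st <- sample(AOI_GROUPS, 1, prob = P[st, ])
  }
  n <- length(states)
  px <- py <- numeric(n)
  for (i in seq_len(n)) {
    members <- which(layout$points$group == states[i])
    k <- members[sample.int(length(members), 1)]
    px[i] <- layout$points$x[k] + stats::rnorm(1, sd = scenario$jitter_px)
    py[i] <- layout$points$y[k] + stats::rnorm(1, sd = scenario$jitter_px)
  }
  start <- cumsum(c(0, dwell[-n]))
  eye_off <- 3
  rbind(
    data.frame(eye = "left", start_ms = start, duration_ms = dwell,
               x = px - eye_off + stats::rnorm(n, sd = 1), y = py,
               stringsAsFactors = FALSE),
    data.frame(eye = "right", start_ms = start, duration_ms = dwell,
               x = px + eye_off + stats::rnorm(n, sd = 1), y = py,
               stringsAsFactors = FALSE)
  )
}

#' Simulate a complete two-group gaze study
#'
#' Generates landmark tables for `n_images` perturbed variants of the
#' schematic face, and fixation sequences for every subject and trial, in
#' exactly the tabular input formats consumed by [read_fixations()] /
#' [read_landmarks()]. Deterministic given `scenario$seed`.
#'
#' @param scenario A `sim_scenario`.
#' @return List of class `sim_study`: `fixations` (data.frame),
#'   `landmarks` (data.frame), and `truth` (scenario parameters plus the
#'   group transition matrices and stationary distributions).
#' @export
simulate_study <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  chains <- scenario_chains(scenario)
  base <- schematic_face_landmarks(scenario$width, scenario$height)
  image_ids <- sprintf("img%02d", seq_len(scenario$n_images))
  landmarks <- do.call(rbind, lapply(seq_len(scenario$n_images), function(i) {
    lm <- base
    lm$x <- lm$x + stats::rnorm(nrow(lm), sd = scenario$landmark_jitter_px)
    lm$y <- lm$y + stats::rnorm(nrow(lm), sd = scenario$landmark_jitter_px)
    cbind(data.frame(image_id = image_ids[i], stringsAsFactors = FALSE), lm)
  }))
  layouts <- build_layouts(landmarks)
  groups <- scenario$group_labels
  fixations <- list()
  for (g in 1:2) {
    for (s in seq_len(scenario$n_subjects_per_group)) {
      subject <- sprintf("%s%02d", c("A", "B")[g], s)
      for (tr in seq_len(scenario$trials_per_subject)) {
        img <- image_ids[(tr - 1) %% scenario$n_images + 1]
        fx <- simulate_trial(scenario, c("A", "B")[g], layouts[[img]],
                             chains)
        fixations[[length(fixations) + 1]] <- cbind(
          data.frame(subject_id = subject, group = groups[g],
                     trial_id = sprintf("t%03d", tr), image_id = img,
                     stringsAsFactors = FALSE),
          fx)
      }
    }
  }
  fixations <- do.call(rbind, fixations)[FIXATION_COLUMNS]
  truth <- list(
    scenario = unclass(scenario),
    transition_A = chains$A, transition_B = chains$B,
    stationary_A = chains$pi_A, stationary_B = chains$pi_B)
  structure(list(fixations = fixations, landmarks = landmarks,
                 truth = truth),
            class = "sim_study")
}

#' Write a simulated study to disk
#'
#' Writes `fixations.csv`, `landmarks.csv` and `truth.json` into `dir`
#' (created if needed), matching the package's input file formats.
#'
#' @param study A `sim_study` from [simulate_study()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$fixations, file.path(dir, "fixations.csv"),
                   row.names = FALSE, quote = TRUE)
  utils::write.csv(study$landmarks, file.path(dir, "landmarks.csv"),
                   row.names = FALSE, quote = TRUE)
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
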